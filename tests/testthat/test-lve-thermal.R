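# LVE-region detection and denaturation-temperature estimators.

# brute-force oracle: exhaustively scan all contiguous runs of >= 3 points
# and return the longest satisfying the median-tolerance rule
lve_bruteforce <- function(amp, gp, rel_tol) {
  best <- NULL
  n <- length(gp)
  for (i in seq_len(n - 2L)) for (j in (i + 2L):n) {
    med <- median(gp[i:j])
    if (all(abs(gp[i:j] - med) <= rel_tol * med) &&
        (is.null(best) || (j - i) > (best[2] - best[1]))) best <- c(i, j)
  }
  best
}

test_that("a fully flat modulus gives an LVE region spanning the sweep", {
  amp <- 10^seq(-3, 0, length.out = 15)
  sw <- amplitude_sweep(amp, rep(100, 15), rep(20, 15), 23, 1)
  r <- detect_lve_region(sw, 0.05)
  expect_equal(r$amplitude_lower, amp[1])
  expect_equal(r$amplitude_upper, amp[15])
  expect_equal(r$plateau_g_prime, 100)
  expect_equal(r$n_points_in_region, 15L)
})

test_that("plateau-then-decay boundary matches the exhaustive run scan", {
  amp <- 10^seq(-3, 0.5, length.out = 30)
  gp <- 500 * pmin(1, (amp / 0.1)^(-0.6))
  sw <- amplitude_sweep(amp, gp, gp / 5, 23, 1)
  r <- detect_lve_region(sw, 0.05)
  oracle <- lve_bruteforce(amp, gp, 0.05)
  expect_equal(r$indices[1], oracle[1])
  expect_equal(r$indices[length(r$indices)], oracle[2])
  # boundary sits at the plateau edge (within one grid step)
  expect_lt(abs(log10(r$amplitude_upper) - log10(0.1)),
            diff(log10(amp[1:2])) * 1.5 + 1e-9)
})

test_that("a strictly monotone sweep with >5% steps has no LVE region", {
  amp <- 10^seq(-2, 0, length.out = 10)
  gp <- 100 * 1.2^(seq_len(10))
  sw <- amplitude_sweep(amp, gp, gp / 5, 23, 1)
  expect_error(detect_lve_region(sw, 0.05), "no LVE region")
})

test_that("LVE detection is invariant under rescaling all moduli", {
  set.seed(11)
  amp <- 10^seq(-3, 0.3, length.out = 25)
  gp <- 300 * pmin(1, (amp / 0.05)^(-0.4)) * exp(rnorm(25, 0, 0.01))
  sw1 <- amplitude_sweep(amp, gp, gp / 4, 23, 1)
  sw2 <- amplitude_sweep(amp, gp * 1e3, gp * 1e3 / 4, 23, 1)
  r1 <- detect_lve_region(sw1)
  r2 <- detect_lve_region(sw2)
  expect_equal(r1$indices, r2$indices)
  expect_equal(r2$plateau_g_prime, r1$plateau_g_prime * 1e3)
})

test_that("viscosity-drop Td matches closed forms for sigmoid and linear decay", {
  temp <- seq(23, 45, by = 0.25)
  eta_sig <- 1000 / (1 + exp((temp - 38) / 0.5))
  td <- detect_td_viscosity(temperature_sweep(temp, eta_sig, rep(0.3, length(temp))))
  expect_lt(abs(td - 38.0), 0.05)

  # half-value of the linear decay is 40.0 from the first sample alone; the
  # mean-of-first-3 initial-value convention lowers the threshold slightly
  # and shifts the closed form to exactly 23 + 34*(1 - (1 - 0.25/34)/2)
  eta_lin <- 1000 * (1 - (temp - 23) / 34)
  td2 <- detect_td_viscosity(temperature_sweep(temp, eta_lin, rep(0.3, length(temp))))
  expect_equal(td2, 40.125, tolerance = 1e-9)
  expect_lt(abs(td2 - 40.0), 0.15)
})

test_that("monotonically increasing viscosity yields an absent Td with diagnostic", {
  temp <- seq(23, 45, by = 1)
  ts <- temperature_sweep(temp, 100 * exp(0.05 * (temp - 23)), rep(0.3, length(temp)))
  td <- detect_td_viscosity(ts)
  expect_true(is.na(td))
  expect_match(attr(td, "diagnostic"), "never fell")
})

test_that("sigmoid Td error stays below one grid step for coarse grids", {
  for (npts in c(10, 15, 25, 60)) {
    temp <- seq(30, 46, length.out = npts)
    eta <- 1000 / (1 + exp((temp - 38) / 0.8))
    td <- detect_td_viscosity(temperature_sweep(temp, eta, rep(0.3, npts)))
    expect_lt(abs(td - 38), diff(temp[1:2]))
  }
})

test_that("tan-delta peak is found, refined, and boundary maxima are rejected", {
  temp <- seq(23, 45, by = 0.25)
  td_curve <- 0.3 + 0.7 * exp(-(temp - 37.2)^2 / (2 * 1.5^2))
  ts <- temperature_sweep(temp, rep(100, length(temp)), td_curve)
  expect_lt(abs(detect_td_tandelta(ts) - 37.2), 0.25 / 2)

  # two peaks: the global one wins, as confirmed by the exhaustive argmax
  two <- 0.3 + 0.5 * exp(-(temp - 30)^2 / 2) + 0.7 * exp(-(temp - 38)^2 / 2)
  ts2 <- temperature_sweep(temp, rep(100, length(temp)), two)
  sm <- stats::filter(two, rep(1 / 3, 3)); sm[is.na(sm)] <- two[is.na(sm)]
  expect_lt(abs(detect_td_tandelta(ts2) - temp[which.max(sm)]), 0.25)

  rising <- 0.2 + 0.02 * (temp - 23)
  ts3 <- temperature_sweep(temp, rep(100, length(temp)), rising)
  td3 <- detect_td_tandelta(ts3)
  expect_true(is.na(td3))
  expect_match(attr(td3, "diagnostic"), "not bracketed")
})

test_that("both Td signatures planted at one transition agree within 1.5 degC", {
  for (seed in 1:5) {
    s <- synthetic_scenario(noise_sigma = 0.02, seed = seed)
    ts <- generate_temperature_sweep(s)
    res <- detect_denaturation(ts$sweep)
    expect_lt(abs(res$td_viscosity - s$td_true), 0.5)
    expect_lt(abs(res$td_tandelta - s$td_true), 0.5)
    expect_lt(res$method_agreement, 1.5)
  }
})
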
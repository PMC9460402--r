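# Maxwell forward models and the regularized spectrum inversion.

test_that("single-mode moduli obey the closed-form limits", {
  ms <- maxwell_spectrum(1000, 0.1)
  at1 <- forward_moduli_discrete(ms, 10)       # omega*lambda = 1
  expect_equal(at1$g_prime, 500, tolerance = 1e-12)
  expect_equal(at1$g_double_prime, 500, tolerance = 1e-12)
  term <- forward_moduli_discrete(ms, 0.1)     # omega*lambda = 0.01
  expect_equal(term$g_double_prime / term$g_prime, 100, tolerance = 1e-12)
})

test_that("discrete moduli are additive over modes", {
  set.seed(3)
  G <- runif(5, 10, 1000); lam <- 10^runif(5, -3, 2)
  omega <- log_grid(1e-3, 1e3, 4)
  full <- forward_moduli_discrete(maxwell_spectrum(G, lam), omega)
  ord <- order(lam)
  sum_p <- sum_pp <- 0
  for (i in 1:5) {
    m <- forward_moduli_discrete(maxwell_spectrum(G[ord][i], lam[ord][i]), omega)
    sum_p <- sum_p + m$g_prime; sum_pp <- sum_pp + m$g_double_prime
  }
  expect_equal(full$g_prime, sum_p, tolerance = 1e-14)
  expect_equal(full$g_double_prime, sum_pp, tolerance = 1e-14)
})

test_that("the relaxation modulus obeys its limits and quadrature converges", {
  ms <- maxwell_spectrum(1000, 0.1)
  expect_equal(relaxation_modulus(ms, 0.1)$modulus, 1000 * exp(-1))
  expect_equal(relaxation_modulus(ms, 1e-9)$modulus, 1000, tolerance = 1e-6)

  # narrow log-normal H around lambda0 behaves as a single mode
  lg <- log_grid(1e-3, 1e1, 80)
  H <- dnorm(log(lg), log(0.1), 0.02)
  H <- H / sum(H * rheomwd:::trapz_log_weights(lg)) * 1000
  cs <- continuous_spectrum(lg, H)
  t <- c(0.03, 0.1, 0.3)
  g_cont <- relaxation_modulus(cs, t)$modulus
  g_disc <- relaxation_modulus(ms, t)$modulus
  expect_lt(max(abs(g_cont / g_disc - 1)), 0.005)
})

test_that("continuous moduli match the discrete kernel and refine stably", {
  lg <- log_grid(1e-3, 1e1, 20)
  H <- dnorm(log(lg), log(0.1), 0.05)
  H <- H / sum(H * rheomwd:::trapz_log_weights(lg)) * 1000
  omega <- c(0.1, 10, 1000)
  mc <- forward_moduli_continuous(continuous_spectrum(lg, H), omega)
  md <- forward_moduli_discrete(maxwell_spectrum(1000, 0.1), omega)
  expect_lt(max(abs(mc$g_prime / md$g_prime - 1)), 0.01)
  expect_lt(max(abs(mc$g_double_prime / md$g_double_prime - 1)), 0.01)

  # zero spectrum gives zero moduli
  z <- forward_moduli_continuous(continuous_spectrum(lg, rep(0, length(lg))), omega)
  expect_equal(z$g_prime, rep(0, 3))

  # doubling grid density changes smooth-H results by < 0.1%
  lg1 <- log_grid(1e-3, 1e2, 10); lg2 <- log_grid(1e-3, 1e2, 20)
  mk <- function(lg) {
    H <- 500 * dnorm(log(lg), log(0.5), 0.8)
    forward_moduli_continuous(continuous_spectrum(lg, H), c(0.05, 1, 20))
  }
  m1 <- mk(lg1); m2 <- mk(lg2)
  expect_lt(max(abs(m1$g_prime / m2$g_prime - 1)), 1e-3)
  expect_lt(max(abs(m1$g_double_prime / m2$g_double_prime - 1)), 1e-3)
})

test_that("G'' of a single mode peaks at omega = 1/lambda", {
  lam <- 0.37
  grid <- log_grid(1e-2 / lam, 1e2 / lam, 200)
  gpp <- forward_moduli_discrete(maxwell_spectrum(100, lam), grid)$g_double_prime
  i <- which.max(gpp)
  expect_lt(abs(log10(grid[i]) - log10(1 / lam)), log10(grid[2] / grid[1]) + 1e-12)
})

test_that("a two-peak spectrum is recovered with faithful refit", {
  lg <- log_grid(1e-3, 1e2, 10)
  H <- 500 * dnorm(log(lg), log(0.05), 0.4) + 300 * dnorm(log(lg), log(5), 0.4)
  mm <- forward_moduli_continuous(continuous_spectrum(lg, H), log_grid(1e-3, 1e3, 8))
  mc <- master_from(log_grid(1e-3, 1e3, 8), mm$g_prime, mm$g_double_prime)
  rec <- invert_relaxation_spectrum(mc, lambda_grid = lg)
  d <- attr(rec, "diagnostics")
  expect_lt(d$refit_rms_log10, log10(1.01))      # refit within 1%
  tops <- which(diff(sign(diff(rec$H))) == -2) + 1
  tops <- tops[order(-rec$H[tops])][1:2]
  step <- log10(lg[2] / lg[1])
  expect_lt(min(abs(log10(lg[tops]) - log10(0.05))), step / 2 + 1e-9)
  expect_lt(min(abs(log10(lg[tops]) - log10(5))), step / 2 + 1e-9)
})

test_that("a single-mode source concentrates the recovered spectrum", {
  om <- log_grid(1e-2, 1e3, 8)
  m <- forward_moduli_discrete(maxwell_spectrum(1000, 0.1), om)
  rec <- invert_relaxation_spectrum(master_from(om, m$g_prime, m$g_double_prime))
  wq <- rheomwd:::trapz_log_weights(rec$lambda_grid)
  mass <- rec$H * wq
  near <- abs(log10(rec$lambda_grid) - log10(0.1)) <= 0.5
  expect_gte(sum(mass[near]) / sum(mass), 0.9)
})

test_that("zero moduli invert to the zero spectrum", {
  om <- log_grid(1e-2, 1e2, 5)
  rec <- invert_relaxation_spectrum(master_from(om, rep(0, length(om)),
                                                rep(0, length(om))))
  expect_equal(rec$H, rep(0, length(rec$H)))
})

test_that("forward-inverse consistency holds at the data's noise level", {
  lg <- log_grid(1e-3, 1e2, 10)
  H <- 400 * dnorm(log(lg), log(0.3), 0.7)
  om <- log_grid(1e-3, 1e3, 8)
  m0 <- forward_moduli_continuous(continuous_spectrum(lg, H), om)
  for (sigma in c(0, 0.02, 0.05)) {
    set.seed(101)
    gp <- m0$g_prime * exp(rnorm(length(om), 0, sigma))
    gpp <- m0$g_double_prime * exp(rnorm(length(om), 0, sigma))
    rec <- invert_relaxation_spectrum(master_from(om, gp, gpp), lambda_grid = lg)
    fwd <- forward_moduli_continuous(rec, om)
    rms_ln <- sqrt(mean(c(log(fwd$g_prime / gp), log(fwd$g_double_prime / gpp))^2))
    expect_lt(rms_ln, 1.5 * sigma + 0.01)
  }
})

test_that("the spectrum is invariant under joint rescaling of omega and lambda", {
  lg <- log_grid(1e-3, 1e2, 10)
  H <- 400 * dnorm(log(lg), log(0.3), 0.7)
  om <- log_grid(1e-3, 1e3, 8)
  m0 <- forward_moduli_continuous(continuous_spectrum(lg, H), om)
  rec1 <- invert_relaxation_spectrum(master_from(om, m0$g_prime, m0$g_double_prime),
                                     lambda_grid = lg)
  cc <- 100
  rec2 <- invert_relaxation_spectrum(master_from(om * cc, m0$g_prime, m0$g_double_prime),
                                     lambda_grid = lg / cc)
  expect_equal(rec2$H, rec1$H, tolerance = 1e-9)
})

test_that("tan-delta from forward moduli equals G''/G' by construction", {
  ms <- maxwell_spectrum(c(800, 150), c(0.01, 5))
  om <- log_grid(1e-2, 1e2, 5)
  m <- forward_moduli_discrete(ms, om)
  expect_equal(tan_delta_of(ms, om), m$g_double_prime / m$g_prime)
})
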
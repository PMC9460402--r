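# Double-reptation transform, parametric inversion, moment reporting.

test_that("the reptation kernel obeys its defining identities", {
  p <- reptation_params()
  M <- 5e5
  expect_equal(reptation_kernel(M, 0, p), 1)
  lam_d <- p$K * M^p$alpha
  expect_equal(reptation_kernel(M, lam_d, p), exp(-1))
  # alpha = 3.4 scaling identity: F(2M, 2^3.4 t) = F(M, t)
  t <- 0.37
  expect_equal(reptation_kernel(2 * M, 2^3.4 * t, p),
               reptation_kernel(M, t, p), tolerance = 1e-12)
  expect_error(reptation_kernel(p$Me / 2, 1, p), "unentangled")
})

test_that("a monodisperse distribution collapses the mixing rule for any beta", {
  M0 <- 5e5
  dist <- delta_mixture(M0, 1)
  t <- log_grid(1e-3, 1e2, 4)
  for (beta in c(1, 2, 3.5)) {
    p <- reptation_params(beta = beta)
    gr <- forward_reptation(dist, t, p)
    expect_equal(gr$modulus, p$G_N * reptation_kernel(M0, t, p),
                 tolerance = 1e-12)
  }
})

test_that("a binary blend at beta = 2 matches its closed form", {
  M <- c(2e5, 8e5); w <- c(0.4, 0.6)
  p <- reptation_params(beta = 2)
  dist <- delta_mixture(M, w)
  t <- log_grid(1e-3, 1e2, 5)
  lam <- p$K * M^p$alpha
  closed <- p$G_N * (w[1] * exp(-t / (2 * lam[1])) +
                     w[2] * exp(-t / (2 * lam[2])))^2
  gr <- forward_reptation(dist, t, p)
  expect_lt(max(abs(gr$modulus / closed - 1)), 1e-3)
})

test_that("quadrature of a smooth distribution is refinement-stable", {
  p <- reptation_params()
  comp <- data.frame(weight = 1, location = 4.8e5, width = 0.8)
  t <- log_grid(1e-2, 1e2, 4)
  g <- lapply(c(10, 100), function(ppd) {
    mg <- log_grid(p$Me * 1.05, 1e9, ppd)
    forward_reptation(rheomwd:::lognormal_mixture_truncated(comp, mg), t, p)$modulus
  })
  expect_lt(max(abs(g[[1]] / g[[2]] - 1)), 1e-3)
})

test_that("G_r is monotone nonincreasing and obeys the kernel sandwich", {
  p <- reptation_params()
  dist <- collagen_truth()
  mg <- dist$mass_grid[dist$mass_grid > p$Me * 1.01]
  de <- rheomwd:::lognormal_mixture_truncated(dist$components, mg)
  t <- log_grid(1e-4, 1e3, 10)
  gr <- forward_reptation(de, t, p)$modulus
  expect_true(all(diff(gr) <= 1e-12 * gr[-length(gr)]))
  up <- p$G_N * pmin(1, exp(-t / (p$K * max(mg)^p$alpha)))
  lo <- p$G_N * exp(-t / (p$K * min(mg)^p$alpha))
  expect_true(all(gr <= up * (1 + 1e-12)))
  expect_true(all(gr >= lo * (1 - 1e-12)))
})

test_that("a log-normal truth is recovered from its noiseless target", {
  p <- reptation_params()
  truth <- collagen_truth()
  dist <- invert_mwd(collagen_target(p), p, family = "lognormal_1")
  expect_lt(abs(dist$Mw / truth$Mw - 1), 0.05)
  expect_lt(abs(dist$PDI / truth$PDI - 1), 0.10)
  # normalization preserved after inversion
  wq <- rheomwd:::trapz_log_weights(dist$mass_grid)
  expect_lt(abs(sum(dist$w * wq) - 1), 1e-6)
})

test_that("a monodisperse target drives the fitted width to zero", {
  p <- reptation_params()
  M0 <- 6e5
  t <- log_grid(1e-2, 1e2, 10)
  target <- relaxation_curve(t, p$G_N * reptation_kernel(M0, t, p))
  dist <- invert_mwd(target, p, family = "lognormal_1")
  expect_lt(dist$PDI, 1.05)
  expect_gte(dist$PDI, 1)
})

test_that("a target shorter than the parameter count is rejected", {
  p <- reptation_params()
  t <- c(0.1, 1, 10)
  target <- relaxation_curve(t, p$G_N * reptation_kernel(6e5, t, p))
  expect_error(invert_mwd(target, p, family = "lognormal_mix_3"), "usable points")
})

test_that("the reptation window restriction discards sub-entanglement times", {
  p <- reptation_params()
  tau_e <- p$K * p$Me^p$alpha
  lg_hi <- log_grid(tau_e * 10, tau_e * 1e5, 10)
  spec_hi <- continuous_spectrum(lg_hi, rep(100, length(lg_hi)))
  tgt_hi <- spectrum_to_relaxation_target(spec_hi, p)
  expect_gte(min(tgt_hi$time), min(lg_hi) * (1 - 1e-9))

  lg_mix <- log_grid(tau_e / 100, tau_e * 1e4, 10)
  spec_mix <- continuous_spectrum(lg_mix, rep(100, length(lg_mix)))
  tgt_mix <- spectrum_to_relaxation_target(spec_mix, p)
  expect_gte(min(tgt_mix$time), tau_e * (1 - 1e-9))

  lg_lo <- log_grid(tau_e / 1e4, tau_e / 10, 10)
  spec_lo <- continuous_spectrum(lg_lo, rep(100, length(lg_lo)))
  expect_error(spectrum_to_relaxation_target(spec_lo, p), "sub-entanglement")
})

test_that("moment summaries reproduce hand arithmetic and closed forms", {
  # two-point blend: 0.5 at 1e5, 0.5 at 5e5
  dist <- delta_mixture(c(1e5, 5e5), c(0.5, 0.5))
  expect_equal(dist$Mw, 3e5, tolerance = 1e-6)
  expect_equal(dist$Mn, 1e5 / 0.6, tolerance = 1e-6)
  s <- summarize_distribution(dist)
  expect_equal(s$PDI, 1.8)

  # log-normal with log-width sigma^2 = ln 2 has PDI exactly 2
  ln <- lognormal_mixture_distribution(
    data.frame(weight = 1, location = 1e5, width = sqrt(log(2))))
  expect_equal(ln$PDI, 2, tolerance = 1e-12)
})

test_that("PDI is at least 1, with equality only in the degenerate limit", {
  for (w in c(1e-4, 0.3, 0.8)) {
    d <- lognormal_mixture_distribution(
      data.frame(weight = 1, location = 5e5, width = w))
    expect_gte(d$PDI, 1)
    if (w < 1e-3) expect_lt(d$PDI - 1, 1e-3)
  }
})

test_that("beta sensitivity: monodisperse is invariant, polydisperse is not", {
  M0 <- 5e5
  t <- log_grid(1e-2, 1e2, 5)
  mono <- delta_mixture(M0, 1)
  g2 <- forward_reptation(mono, t, reptation_params(beta = 2))$modulus
  g3 <- forward_reptation(mono, t, reptation_params(beta = 3))$modulus
  expect_equal(g2, g3, tolerance = 1e-10)

  poly <- collagen_truth()
  mg <- poly$mass_grid[poly$mass_grid > 5e4 * 1.01]
  pe <- rheomwd:::lognormal_mixture_truncated(poly$components, mg)
  p2 <- forward_reptation(pe, t, reptation_params(beta = 2))$modulus
  p3 <- forward_reptation(pe, t, reptation_params(beta = 3))$modulus
  expect_gt(max(abs(p2 / p3 - 1)), 0.01)
})
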
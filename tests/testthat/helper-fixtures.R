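# Shared fixtures built in code: small sweeps, reference spectra and the
# canonical synthetic scenarios used across the suite.

# single-mode Maxwell sweep sampled on a log grid
single_mode_sweep <- function(G = 1000, lambda = 0.1, omega = log_grid(0.1, 1000, 8),
                              temperature = 28) {
  m <- forward_moduli_discrete(maxwell_spectrum(G, lambda), omega)
  frequency_sweep(omega, m$g_prime, m$g_double_prime, temperature)
}

# three-mode reference spectrum used by the fitting tests
three_mode_spec <- function() {
  maxwell_spectrum(G = c(800, 400, 150), lambda = c(0.01, 0.3, 5))
}

three_mode_sweep <- function(omega = log_grid(1e-2, 1e3, 5), temperature = 28,
                             noise_sigma = 0, seed = NULL) {
  m <- forward_moduli_discrete(three_mode_spec(), omega)
  gp <- m$g_prime; gpp <- m$g_double_prime
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    gp <- gp * exp(rnorm(length(omega), 0, noise_sigma))
    gpp <- gpp * exp(rnorm(length(omega), 0, noise_sigma))
  }
  frequency_sweep(omega, gp, gpp, temperature)
}

# construct a fit_result directly from known Maxwell parameters (bypasses
# the fitting stage; used to test the crossover root-finder in isolation)
fit_from_modes <- function(G, lambda, omega_range = c(0.1, 1000),
                           temperature = 28) {
  structure(list(
    sweep_ref = list(sample_id = "analytic", temperature = temperature),
    model = "maxwell_modes", params = list(G = G, lambda = lambda),
    n_modes_or_degree = length(G), flagged_indices = integer(),
    rms_log_residual = 0,
    fitted_curves = data.frame(), omega_range = omega_range,
    retained_indices = integer(), data = list()
  ), class = "fit_result")
}

# weight distribution with all mass in isolated grid cells ("delta comb"):
# cell masses M0 (vector) with weights w0; exact under the trapezoid rule
delta_mixture <- function(M0, w0, spread = 1e-3) {
  stopifnot(length(M0) == length(w0))
  grids <- lapply(M0, function(m) m * c(1 - spread, 1, 1 + spread))
  mg <- sort(unlist(grids))
  w <- numeric(length(mg))
  for (i in seq_along(M0)) {
    j <- which.min(abs(mg - M0[i]))
    dl <- trapz_weight_at(mg, j)
    w[j] <- w0[i] / dl
  }
  wq <- rheomwd:::trapz_log_weights(mg)
  mw_distribution(mg, w / sum(w * wq))
}

trapz_weight_at <- function(x, j) rheomwd:::trapz_log_weights(x)[j]

# master-curve container from bare moduli arrays
master_from <- function(omega, g_prime, g_double_prime, tref = 28) {
  structure(list(omega = omega, g_prime = g_prime,
                 g_double_prime = g_double_prime,
                 source_temperature_per_point = rep(tref, length(omega)),
                 reference_temperature = tref),
            class = "master_curve")
}

# canonical truth distribution at the collagen scale: Mw 6.8e5, PDI 2
collagen_truth <- function() {
  lognormal_mixture_distribution(
    data.frame(weight = 1, location = 6.8e5 / sqrt(2), width = sqrt(log(2))))
}

# reptation-window relaxation target from the truth distribution
collagen_target <- function(p = reptation_params(), noise_sigma = 0, seed = NULL) {
  truth <- collagen_truth()
  mg <- truth$mass_grid[truth$mass_grid > p$Me * 1.01]
  de <- rheomwd:::lognormal_mixture_truncated(truth$components, mg)
  gr <- forward_reptation(de, log_grid(1e-3, 1e3, 10), p)
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    gr <- relaxation_curve(gr$time,
                           gr$modulus * exp(rnorm(length(gr$time), 0, noise_sigma)))
  }
  gr
}
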
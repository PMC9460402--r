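# Synthetic-data generator: fully specified stand-in for rheometer sweeps,
# with a ground-truth manifest for every quantity any pipeline stage
# estimates. The forward chain runs truth w(M) -> double-reptation G_r(t)
# -> dense Maxwell spectrum -> dynamic moduli on shifted frequency windows,
# plus multiplicative log-normal noise and configurable corruption.

#' Define a synthetic measurement scenario
#'
#' Defaults describe the study conditions emulated throughout the package:
#' a single log-normal weight distribution at the collagen scale (Mw =
#' 6.8e5 g/mol, PDI = 2), three test temperatures bracketing a 28 degC
#' reference with shift factors of half a decade per step, a denaturation
#' transition at 38.1 degC, a strain-amplitude LVE boundary at 0.1, and 2%
#' multiplicative noise.
#'
#' @param truth_components data.frame `(weight, location, width)` of the
#'   ground-truth log-normal mixture (location = median mass g/mol, width =
#'   sd of ln M).
#' @param reptation a [reptation_params()].
#' @param temperatures test temperatures, degC, unique.
#' @param true_log10_aT horizontal shift per temperature (0 at the
#'   reference).
#' @param reference_temperature degC.
#' @param td_true denaturation temperature planted in temperature sweeps.
#' @param lve_upper_true amplitude boundary of the plateau in amplitude
#'   sweeps.
#' @param noise_sigma sd of the multiplicative log-normal noise on moduli
#'   (sd of `ln G`).
#' @param corruption list `(mode, n_points)`: `"none"`, `"near_td_tail"`
#'   (last `n_points` of each frequency sweep replaced by a collapsing tail,
#'   the near-denaturation artifact) or `"gel_like"` (frequency-independent
#'   elastic floor added to `G'`, so the curves run parallel with `G' > G''`
#'   and never cross).
#' @param omega_window frequency window, rad/s, `c(min, max)`.
#' @param points_per_decade sweep density.
#' @param seed integer; the only source of randomness.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(
    truth_components = data.frame(weight = 1,
                                  location = 6.8e5 / sqrt(2),
                                  width = sqrt(log(2))),
    reptation = reptation_params(),
    temperatures = c(23, 28, 32),
    true_log10_aT = c(0.5, 0, -0.5),
    reference_temperature = 28,
    td_true = 38.1,
    lve_upper_true = 0.1,
    noise_sigma = 0.02,
    corruption = list(mode = "none", n_points = 3L),
    omega_window = c(1e-2, 1e2),
    points_per_decade = 5,
    seed = 1L) {
  if (anyDuplicated(temperatures)) stop_validation("temperatures must be unique")
  if (length(true_log10_aT) != length(temperatures))
    stop_validation("one shift per temperature required")
  if (noise_sigma < 0) stop_validation("noise_sigma must be >= 0")
  if (!corruption$mode %in% c("none", "near_td_tail", "gel_like"))
    stop_validation("unknown corruption mode '%s'", corruption$mode)
  n_sweep <- ceiling(log10(omega_window[2] / omega_window[1]) * points_per_decade) + 1L
  if (corruption$mode == "near_td_tail" && corruption$n_points > 0.5 * n_sweep)
    stop_validation("corruption fraction > 0.5: unusable by construction")
  structure(list(truth_components = truth_components, reptation = reptation,
                 temperatures = temperatures, true_log10_aT = true_log10_aT,
                 reference_temperature = reference_temperature,
                 td_true = td_true, lve_upper_true = lve_upper_true,
                 noise_sigma = noise_sigma, corruption = corruption,
                 omega_window = omega_window,
                 points_per_decade = points_per_decade,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# truth distribution and its analytic moments
scenario_truth_distribution <- function(s) {
  lognormal_mixture_distribution(s$truth_components)
}

# reference-temperature moduli functions derived from the truth w(M):
# G_r(t) by the mixing rule, re-expressed as a dense Maxwell spectrum
scenario_reference_spectrum <- function(s) {
  p <- s$reptation
  dist <- scenario_truth_distribution(s)
  # restrict grid to the entangled domain
  mg <- dist$mass_grid[dist$mass_grid > p$Me * 1.01]
  dist_e <- lognormal_mixture_truncated(dist$components, mg)
  tau_e <- p$K * p$Me^p$alpha
  lam_max <- p$K * max(mg)^p$alpha
  tgrid <- log_grid(tau_e / 10, lam_max * 10, 10)
  gr <- forward_reptation(dist_e, tgrid, p)
  # keep only the decaying window that carries spectral information
  keep <- gr$modulus > p$G_N * 1e-7
  gr <- relaxation_curve(gr$time[keep], gr$modulus[keep])
  fit_maxwell_to_relaxation(gr)
}

#' Generate multi-temperature frequency sweeps with a truth manifest
#'
#' For each temperature the reference-curve moduli are evaluated at the
#' reduced frequency `aT * omega` on the scenario's frequency window,
#' multiplicative log-normal noise is applied, and the configured
#' corruption is imposed. The manifest records every downstream truth.
#'
#' @param s a [synthetic_scenario()].
#' @return List with `sweeps` (list of [frequency_sweep()]) and `manifest`
#'   (truth Mw/Mn/PDI, shift factors, corrupted indices per temperature,
#'   reference spectrum, scenario parameters).
#' @export
generate_frequency_sweeps <- function(s) {
  stopifnot(inherits(s, "synthetic_scenario"))
  set.seed(s$seed)
  spec_ref <- scenario_reference_spectrum(s)
  dist <- scenario_truth_distribution(s)
  omega <- log_grid(s$omega_window[1], s$omega_window[2], s$points_per_decade)
  n <- length(omega)
  sweeps <- vector("list", length(s$temperatures))
  corrupted <- vector("list", length(s$temperatures))
  for (i in seq_along(s$temperatures)) {
    aT <- 10^s$true_log10_aT[i]
    m <- forward_moduli_discrete(spec_ref, omega * aT)
    gp <- m$g_prime; gpp <- m$g_double_prime
    if (s$noise_sigma > 0) {
      gp <- gp * exp(stats::rnorm(n, 0, s$noise_sigma))
      gpp <- gpp * exp(stats::rnorm(n, 0, s$noise_sigma))
    }
    idx <- integer()
    if (s$corruption$mode == "near_td_tail") {
      k <- s$corruption$n_points
      idx <- (n - k + 1L):n
      # collapsing tail: the sample stops tracking the drive near Td
      # (softening / sliding off the plate) and the apparent moduli fall
      # away from the last valid level
      gp[idx] <- gp[n - k] * 0.25^seq_len(k)
      gpp[idx] <- gpp[n - k] * 0.25^seq_len(k)
    } else if (s$corruption$mode == "gel_like") {
      # frequency-independent elastic floor: G' parallel to and above G'',
      # so no crossover exists (indices stay empty; the pathology is global)
      gp <- gp + 2 * max(gpp)
    }
    corrupted[[i]] <- idx
    sweeps[[i]] <- frequency_sweep(omega, gp, gpp,
                                   temperature = s$temperatures[i],
                                   mode = "CS", amplitude = 300, gap = 0.5,
                                   sample_id = sprintf("synthetic_T%g", s$temperatures[i]))
  }
  names(corrupted) <- as.character(s$temperatures)
  manifest <- list(
    Mw = dist$Mw, Mn = dist$Mn, PDI = dist$PDI,
    components = s$truth_components,
    shift_factors = data.frame(temperature = s$temperatures,
                               log10_aT = s$true_log10_aT),
    reference_temperature = s$reference_temperature,
    corrupted_indices = corrupted, corruption_mode = s$corruption$mode,
    td_true = s$td_true, lve_upper_true = s$lve_upper_true,
    reptation = unclass(s$reptation), noise_sigma = s$noise_sigma,
    seed = s$seed)
  list(sweeps = sweeps, manifest = manifest)
}

#' Generate an amplitude sweep with a known LVE boundary
#'
#' `G'` holds a plateau up to `lve_upper_true` and decays as a power law
#' beyond it; `G''` is a fixed fraction of the plateau. Log-normal noise
#' keeps moduli positive.
#'
#' @param s a [synthetic_scenario()].
#' @param plateau_g_prime plateau level, Pa.
#' @param decay_exponent power-law decay beyond the boundary.
#' @param n_points sweep length.
#' @return List with `sweep` (an [amplitude_sweep()]) and `truth`
#'   (`lve_upper_true`, boundary index, plateau).
#' @export
generate_amplitude_sweep <- function(s, plateau_g_prime = 500,
                                     decay_exponent = 0.6, n_points = 25L) {
  stopifnot(inherits(s, "synthetic_scenario"))
  set.seed(s$seed + 1L)
  amp <- 10^seq(-3, 0.5, length.out = n_points)
  gp <- plateau_g_prime * pmin(1, (amp / s$lve_upper_true)^(-decay_exponent))
  gpp <- gp / 5
  if (s$noise_sigma > 0) {
    gp <- gp * exp(stats::rnorm(n_points, 0, s$noise_sigma))
    gpp <- gpp * exp(stats::rnorm(n_points, 0, s$noise_sigma))
  }
  sweep <- amplitude_sweep(amp, gp, gpp, temperature = s$temperatures[1L],
                           fixed_omega = 1, mode = "CD")
  list(sweep = sweep,
       truth = list(lve_upper_true = s$lve_upper_true,
                    boundary_index = max(which(amp <= s$lve_upper_true)),
                    plateau_g_prime = plateau_g_prime))
}

#' Generate a temperature sweep with both denaturation signatures
#'
#' The viscosity is a logistic sigmoid whose midpoint sits at `td_true`
#' (so the 50%-drop estimator is exact in the noiseless limit) and
#' tan(delta) is a Gaussian peak centered at the same temperature.
#'
#' @param s a [synthetic_scenario()].
#' @param t_range sweep range, degC.
#' @param step grid step, degC.
#' @param sigmoid_width logistic width of the viscosity transition, degC.
#' @param peak_width sd of the tan-delta peak, degC.
#' @param monotone_increasing if TRUE, generate a pathological sweep whose
#'   viscosity rises and whose tan-delta has no interior peak (both
#'   detectors must report absence).
#' @return List with `sweep` (a [temperature_sweep()]) and `truth`.
#' @export
generate_temperature_sweep <- function(s, t_range = c(23, 45), step = 0.25,
                                       sigmoid_width = 0.5, peak_width = 1.5,
                                       monotone_increasing = FALSE) {
  stopifnot(inherits(s, "synthetic_scenario"))
  set.seed(s$seed + 2L)
  temp <- seq(t_range[1L], t_range[2L], by = step)
  n <- length(temp)
  if (monotone_increasing) {
    eta <- 100 * exp(0.05 * (temp - temp[1L]))
    td <- 0.2 + 0.02 * (temp - temp[1L])
  } else {
    eta <- 1000 / (1 + exp((temp - s$td_true) / sigmoid_width))
    td <- 0.3 + 0.7 * exp(-(temp - s$td_true)^2 / (2 * peak_width^2))
  }
  if (s$noise_sigma > 0) {
    eta <- eta * exp(stats::rnorm(n, 0, s$noise_sigma))
    td <- td * exp(stats::rnorm(n, 0, s$noise_sigma))
  }
  list(sweep = temperature_sweep(temp, eta, td),
       truth = list(td_true = if (monotone_increasing) NA_real_ else s$td_true))
}

#' Write a generated scenario to disk
#'
#' Emits one frequency-sweep CSV (+ JSON sidecar) per temperature plus a
#' `truth.json` manifest; files are deterministic given the scenario seed.
#'
#' @param s a [synthetic_scenario()].
#' @param outdir output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
write_scenario <- function(s, outdir) {
  gen <- generate_frequency_sweeps(s)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (sw in gen$sweeps) {
    f <- file.path(outdir, sprintf("fsweep_T%g.csv", sw$temperature))
    write_result(sw, f)
    paths <- c(paths, f, sidecar_path(f))
  }
  tp <- file.path(outdir, "truth.json")
  man <- gen$manifest
  man$corrupted_indices <- lapply(man$corrupted_indices, as.integer)
  jsonlite::write_json(man, tp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(paths, tp))
}
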
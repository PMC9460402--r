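# Double-reptation mixing rule: forward prediction of the reptation modulus
# G_r(t) from a weight-based molecular-weight distribution w(M), parametric
# inversion back to w(M), and Mw/Mn/PDI moment reporting.

#' Reptation model parameters
#'
#' Parameters of the double-reptation transform
#' `G_r(t) = G_N (int_{Me}^inf F(M,t)^{1/beta} w(M) dM/M)^beta` with the
#' essentially exponential kernel `F(M,t) = exp(-t/lambda_d(M))`,
#' `lambda_d(M) = K M^alpha`.
#'
#' `K` fixes the absolute time scale and is degenerate with it: absolute Mw
#' accuracy depends entirely on this calibration. By default `K` is anchored
#' through a reference pair `(M_ref, lambda_ref)` via
#' `K = lambda_ref / M_ref^alpha`; supply `K` directly to override.
#'
#' @param G_N plateau modulus, Pa.
#' @param Me entanglement molecular weight, g/mol; the critical mass is
#'   `Mc = 2 Me`.
#' @param beta mixing exponent (2 = double reptation).
#' @param alpha reptation scaling exponent of the terminal time with mass.
#' @param K kernel prefactor, s (g/mol)^-alpha; computed from the anchor if
#'   `NULL`.
#' @param M_ref,lambda_ref calibration anchor: a chain of mass `M_ref` g/mol
#'   relaxes with terminal time `lambda_ref` s.
#' @return An object of class `reptation_params`.
#' @export
reptation_params <- function(G_N = 1000, Me = 5e4, beta = 2, alpha = 3.4,
                             K = NULL, M_ref = 6.8e5, lambda_ref = 1) {
  if (is.null(K)) K <- lambda_ref / M_ref^alpha
  vals <- c(G_N = G_N, Me = Me, beta = beta, alpha = alpha, K = K)
  if (any(vals <= 0)) stop_validation("all reptation parameters must be positive")
  structure(list(G_N = G_N, Me = Me, Mc = 2 * Me, beta = beta,
                 alpha = alpha, K = K), class = "reptation_params")
}

#' Reptation relaxation kernel of a monodisperse fraction
#'
#' `F(M, t) = exp(-t / lambda_d(M))` with `lambda_d(M) = K M^alpha`;
#' `F(M, 0) = 1` and `F` decays essentially exponentially.
#'
#' @param M molar mass, g/mol; must exceed the entanglement mass `Me`.
#' @param t time, s, nonnegative.
#' @param p a [reptation_params()].
#' @return Kernel values in `(0, 1]`, recycled over `M` and `t`.
#' @export
reptation_kernel <- function(M, t, p) {
  stopifnot(inherits(p, "reptation_params"))
  if (any(M <= p$Me))
    stop_validation("unentangled mass M <= Me outside the mixing-rule domain")
  if (any(t < 0)) stop_validation("t must be nonnegative")
  exp(-t / (p$K * M^p$alpha))
}

# ---- weight distribution container ------------------------------------

#' Weight-based molecular-weight distribution on a log-mass grid
#'
#' `w` is the weight-fraction density per `d ln M`, normalized so that
#' `int w d ln M = 1`. Moments: `Mw = int w M d ln M`,
#' `Mn = 1 / int (w/M) d ln M`, `PDI = Mw/Mn`.
#'
#' @param mass_grid molar masses, g/mol, log-spaced increasing.
#' @param w density values, nonnegative; renormalized with a warning if the
#'   integral deviates from 1 by more than 1e-6.
#' @param components optional data.frame `(weight, location, width)` of
#'   log-normal components (location = median mass g/mol, width = sd of
#'   ln M); when present, moments are computed analytically from them.
#' @return An object of class `mw_distribution` with fields `Mw`, `Mn`,
#'   `PDI`.
#' @export
mw_distribution <- function(mass_grid, w, components = NULL) {
  if (length(mass_grid) != length(w) || length(w) < 3L)
    stop_validation("mass_grid and w must be equal-length, >= 3 points")
  if (any(mass_grid <= 0)) stop_validation("mass grid must be positive")
  if (is.unsorted(mass_grid, strictly = TRUE))
    stop_validation("mass grid must be strictly increasing")
  if (any(w < 0)) stop_validation("w must be nonnegative")
  wq <- trapz_log_weights(mass_grid)
  Z <- sum(w * wq)
  if (Z <= 0) stop_validation("w integrates to zero")
  if (abs(Z - 1) > 1e-6) {
    warning(sprintf("w not normalized (integral %.6g); renormalizing", Z))
    w <- w / Z
  }
  if (!is.null(components)) {
    pi_i <- components$weight / sum(components$weight)
    mu <- log(components$location); s2 <- components$width^2
    Mw <- sum(pi_i * exp(mu + s2 / 2))
    Mn <- 1 / sum(pi_i * exp(-mu + s2 / 2))
  } else {
    Mw <- sum(w * wq * mass_grid)
    Mn <- 1 / sum(w * wq / mass_grid)
  }
  structure(list(mass_grid = as.numeric(mass_grid), w = as.numeric(w),
                 Mw = Mw, Mn = Mn, PDI = Mw / Mn, components = components),
            class = "mw_distribution")
}

#' Log-normal mixture distribution on a mass grid
#'
#' Builds a normalized [mw_distribution()] whose density in `ln M` is a
#' mixture of Gaussians (log-normals in `M`).
#'
#' @param components data.frame with columns `weight` (mixture proportions),
#'   `location` (median mass, g/mol), `width` (sd of `ln M`).
#' @param mass_grid evaluation grid, g/mol; default spans all components
#'   +/- 6 widths at 15 points/decade.
#' @return An [mw_distribution()].
#' @export
lognormal_mixture_distribution <- function(components, mass_grid = NULL) {
  stopifnot(all(c("weight", "location", "width") %in% names(components)))
  pi_i <- components$weight / sum(components$weight)
  mu <- log(components$location); sig <- pmax(components$width, 1e-6)
  if (is.null(mass_grid)) {
    lo <- exp(min(mu - 6 * sig)); hi <- exp(max(mu + 6 * sig))
    # guarantee a usable span and density even for near-monodisperse widths
    if (log10(hi / lo) < 0.2) { lo <- lo / 10^0.1; hi <- hi * 10^0.1 }
    n <- max(61L, ceiling(15 * log10(hi / lo)) + 1L)
    mass_grid <- 10^seq(log10(lo), log10(hi), length.out = n)
  }
  lM <- log(mass_grid)
  dens <- rowSums(vapply(seq_along(pi_i), function(i)
    pi_i[i] * stats::dnorm(lM, mu[i], sig[i]), numeric(length(lM))))
  wq <- trapz_log_weights(mass_grid)
  mw_distribution(mass_grid, dens / sum(dens * wq),
                  components = data.frame(weight = pi_i,
                                          location = exp(mu), width = sig))
}

# ---- forward transform -------------------------------------------------

#' Forward double-reptation prediction of the reptation modulus
#'
#' `G_r(t) = G_N (int F(M,t)^{1/beta} w(M) d ln M)^beta`, evaluated by
#' trapezoidal quadrature on the log-mass grid (the `dM/M` measure of the
#' mixing rule is `d ln M`). Only the entangled part of the grid
#' (`M > Me`) contributes; the grid must lie above `Me`.
#'
#' @param dist an [mw_distribution()].
#' @param time times, s.
#' @param p a [reptation_params()].
#' @return A [relaxation_curve()] of `G_r(t)`.
#' @export
forward_reptation <- function(dist, time, p) {
  stopifnot(inherits(dist, "mw_distribution"), inherits(p, "reptation_params"))
  if (any(dist$mass_grid <= p$Me))
    stop_validation("mass grid extends below Me; mixing rule undefined there")
  ppd <- (length(dist$mass_grid) - 1L) /
    log10(max(dist$mass_grid) / min(dist$mass_grid))
  if (ppd < 5) warning("mass grid coarser than 5 points/decade; quadrature may be inaccurate")
  wq <- trapz_log_weights(dist$mass_grid)
  lam_d <- p$K * dist$mass_grid^p$alpha
  # integrand rows: times, cols: masses
  Ikern <- exp(-outer(time, 1 / (p$beta * lam_d)))   # F^{1/beta}
  I <- as.numeric(Ikern %*% (dist$w * wq))
  relaxation_curve(time, p$G_N * pmax(I, .Machine$double.xmin)^p$beta)
}

# ---- spectrum -> relaxation target ------------------------------------

#' Convert a relaxation spectrum to a reptation-window relaxation target
#'
#' Evaluates `G(t)` from `H(lambda)` by log-time quadrature and restricts the
#' curve to `t > tau_e = K Me^alpha`, discarding sub-entanglement (Rouse-like)
#' times that the mixing rule does not model. Optionally rescales the
#' retained curve so its first value equals the plateau modulus.
#'
#' @param spec a [continuous_spectrum()].
#' @param p a [reptation_params()].
#' @param points_per_decade density of the output time grid.
#' @param rescale_to_plateau if TRUE, multiply the retained curve by
#'   `G_N / G(t_first)`; off by default (the unscaled curve is already
#'   `G_r` when the supplied `G_N` matches the data's plateau).
#' @return A [relaxation_curve()] restricted to the reptation window.
#' @export
spectrum_to_relaxation_target <- function(spec, p, points_per_decade = 10,
                                          rescale_to_plateau = FALSE) {
  stopifnot(inherits(spec, "continuous_spectrum"), inherits(p, "reptation_params"))
  tau_e <- p$K * p$Me^p$alpha
  t_hi <- max(spec$lambda_grid)
  t_lo <- max(min(spec$lambda_grid), tau_e)
  if (t_lo >= t_hi)
    stop_validation("data window entirely sub-entanglement (tau_e = %.3g s exceeds it)", tau_e)
  tgrid <- log_grid(t_lo, t_hi, points_per_decade)
  g <- relaxation_modulus(spec, tgrid)
  if (rescale_to_plateau) g$modulus <- g$modulus * p$G_N / g$modulus[1L]
  g
}

# ---- parametric inversion ---------------------------------------------

# map unconstrained theta -> component table for a k-component mixture
theta_to_components <- function(theta, k) {
  if (k == 1L) {
    data.frame(weight = 1, location = exp(theta[1L]), width = exp(theta[2L]))
  } else {
    a <- theta[seq_len(k - 1L)]                      # softmax logits vs last
    e <- exp(c(a, 0)); piv <- e / sum(e)
    mu <- theta[k:(2L * k - 1L)]
    sg <- exp(theta[(2L * k):(3L * k - 1L)])
    data.frame(weight = piv, location = exp(mu), width = sg)
  }
}

#' Invert a relaxation target to a molecular-weight distribution
#'
#' Fits a log-normal mixture `w(M)` (<= 3 components, Gaussians in `ln M`)
#' so that the forward double-reptation prediction matches the target
#' relaxation curve in least squares on `log G_r`. The fit is restricted to
#' the reptation window `G_r/G_N` in `[1e-4, 0.99]`; initial values come
#' from a deterministic multistart grid (no random numbers), so the
#' inversion is reproducible without seeds.
#'
#' @param target a [relaxation_curve()] (typically from
#'   [spectrum_to_relaxation_target()]).
#' @param p a [reptation_params()].
#' @param family `"lognormal_1"`, `"lognormal_mix_2"` or
#'   `"lognormal_mix_3"`.
#' @return An [mw_distribution()] with attributes `fit_rms` (rms residual in
#'   log10 `G_r`) and `params_used` (beta, alpha, K, G_N).
#' @export
invert_mwd <- function(target, p,
                       family = c("lognormal_1", "lognormal_mix_2", "lognormal_mix_3")) {
  stopifnot(inherits(target, "relaxation_curve"), inherits(p, "reptation_params"))
  family <- match.arg(family)
  k <- switch(family, lognormal_1 = 1L, lognormal_mix_2 = 2L, lognormal_mix_3 = 3L)
  npar <- if (k == 1L) 2L else 3L * k - 1L

  keep <- target$modulus / p$G_N >= 1e-4 & target$modulus / p$G_N <= 0.99
  t <- target$time[keep]; g <- target$modulus[keep]
  if (length(t) <= npar)
    stop_validation("target has %d usable points for %d parameters", length(t), npar)
  lg <- log10(g)

  # characteristic mass from the target's terminal time: G_r(t_char) ~ G_N/e
  i_char <- which.min(abs(g - p$G_N * exp(-1)))
  M_char <- max((t[i_char] / p$K)^(1 / p$alpha), 2 * p$Me)
  mu_c <- log(M_char)

  grid_lo <- max(p$Me * 1.05, exp(mu_c - 8))
  obj <- function(theta) {
    comp <- theta_to_components(theta, k)
    if (any(comp$location <= p$Me) || any(comp$width > 5) ||
        any(comp$location > 1e12)) return(1e6)
    hi <- exp(max(log(comp$location) + 6 * comp$width))
    mg <- log_grid(grid_lo, max(hi, grid_lo * 10), 12)
    dist <- suppressWarnings(lognormal_mixture_truncated(comp, mg))
    pred <- forward_reptation(dist, t, p)$modulus
    mean((log10(pred) - lg)^2)
  }

  # deterministic multistart
  mu_starts <- mu_c + c(-1, -0.35, 0, 0.35, 1)
  sg_starts <- c(0.3, 0.7, 1.1)
  starts <- list()
  if (k == 1L) {
    for (m in mu_starts) for (s in sg_starts) starts[[length(starts) + 1L]] <- c(m, log(s))
  } else if (k == 2L) {
    for (d in c(0.7, 1.5)) for (s in c(0.4, 0.8))
      starts[[length(starts) + 1L]] <- c(0, mu_c - d / 2, mu_c + d / 2, log(s), log(s))
  } else {
    for (d in c(0.8, 1.6))
      starts[[length(starts) + 1L]] <-
        c(0, 0, mu_c - d, mu_c, mu_c + d, log(0.4), log(0.4), log(0.4))
  }

  best <- NULL
  for (s0 in starts) {
    fit <- stats::optim(s0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish the winner
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 4000, reltol = 1e-13))
  rms <- sqrt(best$value)
  if (rms > 0.5)
    stop_validation("MWD inversion did not converge (rms %.3g in log10 units)", rms)

  comp <- theta_to_components(best$par, k)
  out <- lognormal_mixture_distribution(comp)
  attr(out, "fit_rms") <- rms
  attr(out, "params_used") <- list(G_N = p$G_N, Me = p$Me, beta = p$beta,
                                   alpha = p$alpha, K = p$K)
  out
}

# mixture density on a grid truncated at Me (renormalized); internal fast
# path for the inversion objective
lognormal_mixture_truncated <- function(components, mass_grid) {
  pi_i <- components$weight / sum(components$weight)
  mu <- log(components$location); sig <- pmax(components$width, 1e-6)
  lM <- log(mass_grid)
  dens <- 0
  for (i in seq_along(pi_i)) dens <- dens + pi_i[i] * stats::dnorm(lM, mu[i], sig[i])
  wq <- trapz_log_weights(mass_grid)
  Z <- sum(dens * wq)
  if (Z <= 0) stop_validation("mixture mass vanished on grid")
  suppressWarnings(mw_distribution(mass_grid, dens / Z))
}

# ---- reporting ---------------------------------------------------------

signif2 <- function(x) signif(x, 2L)

#' Summarize a molecular-weight distribution
#'
#' Reports `Mw`, `Mn` rounded to 2 significant figures and `PDI = Mw/Mn`
#' rounded to 1 decimal, the convention used for tabulated collagen results.
#' Accepts either an [mw_distribution()] or a list with `Mw` and `Mn`.
#'
#' @param x an [mw_distribution()] or `list(Mw =, Mn =)`.
#' @return A list `Mw`, `Mn` (rounded, g/mol), `PDI` (1 decimal), plus the
#'   unrounded values under `raw`.
#' @export
summarize_distribution <- function(x) {
  if (inherits(x, "mw_distribution")) {
    Mw <- x$Mw; Mn <- x$Mn
  } else {
    Mw <- x$Mw; Mn <- x$Mn
  }
  if (!(is.finite(Mw) && is.finite(Mn) && Mw > 0 && Mn > 0))
    stop_validation("Mw and Mn must be positive")
  pdi <- Mw / Mn
  list(Mw = signif2(Mw), Mn = signif2(Mn), PDI = round(pdi, 1L),
       raw = list(Mw = Mw, Mn = Mn, PDI = pdi))
}

#' @export
print.mw_distribution <- function(x, ...) {
  cat(sprintf("<mw_distribution> Mw = %.3g g/mol, Mn = %.3g g/mol, PDI = %.2f (%d grid points)\n",
              x$Mw, x$Mn, x$PDI, length(x$mass_grid)))
  invisible(x)
}
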
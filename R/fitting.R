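# Model-based smoothing, anomaly flagging and crossover extrapolation for
# inhomogeneous G'/G'' frequency sweeps: fit both curves simultaneously in
# log-log space, grow a trusted prefix from the low-frequency end, flag
# points that break from the model, and extrapolate the G' = G'' crossover.

# ---- model backends ----------------------------------------------------

# initialize an n-mode Maxwell fit: log-spaced relaxation times over the
# reciprocal data window, moduli by nonnegative least squares on relative
# residuals
maxwell_init <- function(omega, gp, gpp, n_modes) {
  lam <- if (n_modes == 1L) 1 / sqrt(max(omega) * min(omega))
         else 10^seq(log10(0.5 / max(omega)), log10(2 / min(omega)),
                     length.out = n_modes)
  wl <- outer(omega, lam); denom <- 1 + wl^2
  A <- rbind((wl^2 / denom) / gp, (wl / denom) / gpp)
  b <- rep(1, 2L * length(omega))
  G <- pracma::lsqnonneg(A, b)$x
  G[G <= 0] <- max(G, 1e-6) * 1e-4
  list(G = G, lambda = lam)
}

maxwell_resid <- function(theta, omega, gp, gpp) {
  n <- length(theta) / 2L
  theta <- pmin(pmax(theta, -200), 200)     # keep exp() finite
  G <- exp(theta[seq_len(n)]); lam <- exp(theta[n + seq_len(n)])
  wl <- outer(omega, lam); denom <- 1 + wl^2
  fp <- as.numeric((wl^2 / denom) %*% G)
  fpp <- as.numeric((wl / denom) %*% G)
  c(log10(fp) - log10(gp), log10(fpp) - log10(gpp))
}

fit_maxwell_n <- function(omega, gp, gpp, n_modes) {
  init <- maxwell_init(omega, gp, gpp, n_modes)
  theta0 <- c(log(init$G), log(init$lambda))
  # relaxation times confined to (just beyond) the reciprocal data window:
  # modes outside it are unidentifiable and would extrapolate erratically
  g_scale <- log(max(gp, gpp))
  lower <- c(rep(g_scale - 30, n_modes), rep(log(0.1 / max(omega)), n_modes))
  upper <- c(rep(g_scale + 10, n_modes), rep(log(10 / min(omega)), n_modes))
  theta0 <- pmin(pmax(theta0, lower), upper)
  fit <- minpack.lm::nls.lm(theta0, fn = maxwell_resid,
                            lower = lower, upper = upper,
                            omega = omega, gp = gp, gpp = gpp,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  par <- fit$par
  if (any(!is.finite(par))) par <- theta0      # LM diverged: keep the init
  par <- pmin(pmax(par, -200), 200)
  n <- n_modes
  list(G = exp(par[seq_len(n)]), lambda = exp(par[n + seq_len(n)]),
       rss = sum(maxwell_resid(par, omega, gp, gpp)^2),
       nres = 2L * length(omega), npar = 2L * n_modes)
}

vandermonde_log <- function(omega, degree) {
  lw <- log10(omega)
  outer(lw, 0:degree, `^`)
}

fit_poly_d <- function(omega, gp, gpp, degree) {
  V <- vandermonde_log(omega, degree)
  cp <- stats::lm.fit(V, log10(gp))
  cpp <- stats::lm.fit(V, log10(gpp))
  rss <- sum(cp$residuals^2) + sum(cpp$residuals^2)
  list(coef_p = unname(cp$coefficients), coef_pp = unname(cpp$coefficients),
       rss = rss, nres = 2L * length(omega), npar = 2L * (degree + 1L))
}

predict_backend <- function(model, params, omega) {
  if (model == "maxwell_modes") {
    spec <- maxwell_spectrum(params$G, params$lambda)
    m <- forward_moduli_discrete(spec, omega)
    list(g_prime = m$g_prime, g_double_prime = m$g_double_prime)
  } else {
    V <- vandermonde_log(omega, length(params$coef_p) - 1L)
    list(g_prime = 10^as.numeric(V %*% params$coef_p),
         g_double_prime = 10^as.numeric(V %*% params$coef_pp))
  }
}

aicc <- function(rss, nres, npar) {
  if (nres - npar - 1L <= 0L) return(Inf)
  nres * log(max(rss, 1e-300) / nres) + 2 * npar +
    2 * npar * (npar + 1) / (nres - npar - 1)
}

npar_of <- function(model, cx) if (model == "maxwell_modes") 2L * cx else 2L * (cx + 1L)

# fit one backend at the complexity minimizing AICc (up to max_complexity);
# complexities whose parameter count exceeds the number of sweep points are
# infeasible for the subset at hand
fit_best_complexity <- function(omega, gp, gpp, model, max_complexity) {
  best <- NULL
  for (cx in seq_len(max_complexity)) {
    npar <- npar_of(model, cx)
    if (npar > length(omega)) next
    f <- if (model == "maxwell_modes") fit_maxwell_n(omega, gp, gpp, cx)
         else fit_poly_d(omega, gp, gpp, cx)
    ic <- aicc(f$rss, f$nres, f$npar)
    if (is.null(best) || ic < best$ic) best <- list(fit = f, ic = ic, complexity = cx)
  }
  if (is.null(best))
    stop_validation("fewer points (%d) than parameters of the smallest model", length(omega))
  best
}

# ---- public fit --------------------------------------------------------

#' Fit, smooth and repair a frequency sweep
#'
#' Fits `log G'` and `log G''` simultaneously against `log omega` with either
#' a shared-mode generalized Maxwell model (physically constrained: `G'' >
#' G'` at low frequency, single terminal crossover) or an unconstrained
#' polynomial in log-log space. Model complexity (number of modes / degree)
#' is selected by the small-sample-corrected Akaike criterion.
#'
#' Anomalous points (e.g. corrupted near-denaturation tails) are detected by
#' growing a trusted prefix from the low-frequency end: each subsequent
#' point is flagged when its worst log10 residual against the model refit on
#' the trusted points exceeds `anomaly_k` times the robust (MAD-based)
#' residual scale of the trusted points. Flagged points are excluded and the
#' model extrapolates over them.
#'
#' @param sweep a [frequency_sweep()].
#' @param model `"maxwell_modes"` (default) or `"loglog_poly"`.
#' @param max_complexity maximum number of Maxwell modes / polynomial degree.
#' @param anomaly_k flagging threshold in robust residual-scale units.
#' @return An object of class `fit_result`: `model`, `params`,
#'   `n_modes_or_degree`, `flagged_indices`, `rms_log_residual` (log10,
#'   over retained points, both curves), `fitted_curves` (dense table),
#'   `sweep_ref`, and the data window `omega_range`.
#' @export
fit_modulus_curves <- function(sweep, model = c("maxwell_modes", "loglog_poly"),
                               max_complexity = 6L, anomaly_k = 4) {
  stopifnot(inherits(sweep, "frequency_sweep"))
  model <- match.arg(model)
  if (max_complexity < 1L) stop_validation("max_complexity must be >= 1")
  omega <- sweep$omega; gp <- sweep$g_prime; gpp <- sweep$g_double_prime
  if (any(gp <= 0) || any(gpp <= 0))
    stop_validation("log-space fitting requires strictly positive moduli")
  n <- length(omega)
  min_par <- if (model == "maxwell_modes") 2L else 4L
  if (npar_of(model, max_complexity) > n)
    stop_validation("fewer points (%d) than parameters (%d) of the requested model",
                    n, npar_of(model, max_complexity))

  # trusted prefix: at least half the sweep, and enough residuals for the
  # smallest model
  m0 <- max(4L, ceiling(n / 2))
  m0 <- min(m0, n)
  trusted <- seq_len(m0)
  sel <- fit_best_complexity(omega[trusted], gp[trusted], gpp[trusted],
                             model, max_complexity)
  flagged <- integer()
  refit <- function(idx) {
    if (model == "maxwell_modes") fit_maxwell_n(omega[idx], gp[idx], gpp[idx],
                                                sel$complexity)
    else fit_poly_d(omega[idx], gp[idx], gpp[idx], sel$complexity)
  }
  cur <- sel$fit
  point_resid <- function(fit_obj, idx) {
    pr <- predict_backend(model, fit_obj, omega[idx])
    pmax(abs(log10(pr$g_prime) - log10(gp[idx])),
         abs(log10(pr$g_double_prime) - log10(gpp[idx])))
  }
  if (m0 < n) {
    # one-step-ahead residuals of the last prefix points seed the robust
    # scale, so it reflects extrapolation/model error, not just noise
    ext_hist <- numeric()
    for (m in max(min_par + 2L, m0 - 2L):m0) {
      f_m <- refit(seq_len(m - 1L))
      ext_hist <- c(ext_hist, point_resid(f_m, m))
    }
    for (j in (m0 + 1L):n) {
      rj <- point_resid(cur, j)    # extrapolation residual: fit excludes j
      # scale tracks the recent extrapolation error (which grows smoothly
      # with model inadequacy), so only abrupt departures are flagged
      scale <- max(1.4826 * stats::median(abs(ext_hist - stats::median(ext_hist))),
                   stats::median(ext_hist),
                   utils::tail(ext_hist, 3L), 5e-3)
      if (rj > anomaly_k * scale) {
        flagged <- c(flagged, j)
      } else {
        trusted <- c(trusted, j)
        ext_hist <- c(ext_hist, rj)
        cur <- refit(trusted)
      }
    }
  }
  if (length(trusted) == 0L || length(flagged) == n)
    stop_validation("curve unusable: all points flagged")

  # final complexity re-selection on the full trusted set
  sel <- fit_best_complexity(omega[trusted], gp[trusted], gpp[trusted],
                             model, max_complexity)
  cur <- sel$fit
  pred <- predict_backend(model, cur, omega[trusted])
  rms <- sqrt(mean(c(log10(pred$g_prime) - log10(gp[trusted]),
                     log10(pred$g_double_prime) - log10(gpp[trusted]))^2))
  dense_omega <- log_grid(min(omega), max(omega), 25)
  dense <- predict_backend(model, cur, dense_omega)
  params <- if (model == "maxwell_modes") list(G = cur$G, lambda = cur$lambda)
            else list(coef_p = cur$coef_p, coef_pp = cur$coef_pp)
  structure(list(
    sweep_ref = list(sample_id = sweep$sample_id, temperature = sweep$temperature),
    model = model, params = params, n_modes_or_degree = sel$complexity,
    flagged_indices = flagged, rms_log_residual = rms,
    fitted_curves = data.frame(omega = dense_omega, g_prime = dense$g_prime,
                               g_double_prime = dense$g_double_prime),
    omega_range = range(omega), retained_indices = trusted,
    data = list(omega = omega, g_prime = gp, g_double_prime = gpp)
  ), class = "fit_result")
}

#' Evaluate a fitted model at arbitrary frequencies
#'
#' @param fit a `fit_result` from [fit_modulus_curves()].
#' @param omega angular frequencies, rad/s.
#' @return List with `g_prime`, `g_double_prime`.
#' @export
predict_fit <- function(fit, omega) {
  stopifnot(inherits(fit, "fit_result"))
  predict_backend(fit$model, fit$params, omega)
}

# ---- crossover ---------------------------------------------------------

#' Locate the G' = G'' crossover of a fitted sweep
#'
#' Scans the fitted curves for roots of `log G' - log G''` on a dense log
#' grid, searching the data window first and then up to
#' `search_decades_beyond_data` above it (the direction in which missing
#' cut-off points are expected when sweeps are truncated near
#' denaturation); bracketed roots are refined by bisection. Extrapolating
#' below the window is deliberately not attempted: data with `G' > G''`
#' throughout are gel-like and a model-implied crossover beneath the
#' measured range would be an artifact. When multiple roots exist the
#' lowest-frequency root at which `G' - G''` crosses from negative to
#' positive (end of flow behavior) is returned together with the root
#' count.
#'
#' @param fit a `fit_result`.
#' @param search_decades_beyond_data extrapolation cap in decades (default
#'   1; extrapolated crossovers are always flagged).
#' @return A list of class `crossover_point` (`omega_c`, `g_c`,
#'   `extrapolated`, `temperature`, `n_roots`), or `NULL` with a
#'   `"gel-like, no crossover"` diagnostic message when no root exists in
#'   the extended window.
#' @export
find_crossover <- function(fit, search_decades_beyond_data = 1) {
  stopifnot(inherits(fit, "fit_result"))
  lo <- fit$omega_range[1L]
  hi <- fit$omega_range[2L] * 10^(search_decades_beyond_data)
  grid <- 10^seq(log10(lo), log10(hi), length.out = 4000L)
  m <- predict_backend(fit$model, fit$params, grid)
  f <- log10(m$g_prime) - log10(m$g_double_prime)
  sgn <- sign(f)
  idx <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  roots <- numeric(); rising <- logical()
  for (i in idx) {
    r <- stats::uniroot(function(w) {
      p <- predict_backend(fit$model, fit$params, w)
      log10(p$g_prime) - log10(p$g_double_prime)
    }, lower = grid[i], upper = grid[i + 1L], tol = 1e-12)$root
    roots <- c(roots, r)
    rising <- c(rising, f[i + 1L] > f[i])
  }
  # exact tangency on a grid point
  exact <- which(f == 0)
  if (length(exact)) {
    roots <- c(roots, grid[exact])
    rising <- c(rising, rep(TRUE, length(exact)))
    ord <- order(roots); roots <- roots[ord]; rising <- rising[ord]
  }
  cand <- roots[rising]
  if (!length(cand)) {
    message("gel-like, no crossover: G' and G'' do not intersect within the search window")
    return(NULL)
  }
  wc <- min(cand)
  gc_ <- predict_backend(fit$model, fit$params, wc)$g_prime
  structure(list(omega_c = wc, g_c = gc_,
                 extrapolated = wc < fit$omega_range[1L] || wc > fit$omega_range[2L],
                 temperature = fit$sweep_ref$temperature,
                 n_roots = length(roots)),
            class = "crossover_point")
}

#' Check that crossover frequency increases with temperature
#'
#' With increasing temperature (below denaturation) molecules relax faster,
#' so the `G' = G''` crossover must move to higher frequency. Violations
#' mark the sweep set as suspect for time-temperature superposition.
#'
#' @param points list of `crossover_point` objects at distinct temperatures.
#' @return A list of class `monotonicity_report`: per-adjacent-pair table
#'   (`t_lower`, `t_upper`, `omega_lower`, `omega_upper`, `pass`) and an
#'   overall `pass` flag.
#' @export
check_crossover_monotonicity <- function(points) {
  points <- Filter(Negate(is.null), points)
  if (length(points) < 2L) stop_validation("need >= 2 crossover points at distinct temperatures")
  temp <- vapply(points, `[[`, numeric(1L), "temperature")
  wc <- vapply(points, `[[`, numeric(1L), "omega_c")
  if (anyDuplicated(temp)) stop_validation("temperatures must be distinct")
  ord <- order(temp); temp <- temp[ord]; wc <- wc[ord]
  n <- length(temp)
  tab <- data.frame(t_lower = temp[-n], t_upper = temp[-1L],
                    omega_lower = wc[-n], omega_upper = wc[-1L],
                    pass = wc[-1L] > wc[-n])
  structure(list(pairs = tab, pass = all(tab$pass)),
            class = "monotonicity_report")
}
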
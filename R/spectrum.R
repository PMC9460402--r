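# Generalized Maxwell framework: discrete and continuous relaxation spectra,
# forward models for G(t), G'(omega), G''(omega), and the regularized inverse
# from master-curve moduli to H(lambda).

#' Discrete (generalized Maxwell) relaxation spectrum
#'
#' A set of Maxwell elements `(G_i, lambda_i)`: spring moduli in Pa and
#' relaxation times in s. The relaxation modulus is
#' `G(t) = sum_i G_i exp(-t/lambda_i)` and the dynamic moduli follow the
#' standard single-mode Lorentzian kernels summed over modes.
#'
#' @param G mode moduli, Pa, nonnegative.
#' @param lambda mode relaxation times, s, positive; stored in increasing
#'   order.
#' @return An object of class `maxwell_spectrum`.
#' @export
maxwell_spectrum <- function(G, lambda) {
  if (length(G) != length(lambda) || length(G) < 1L)
    stop_validation("need >= 1 mode with equal-length G and lambda")
  if (any(G < 0)) stop_validation("mode moduli must be nonnegative")
  if (any(lambda <= 0)) stop_validation("relaxation times must be positive")
  ord <- order(lambda)
  structure(list(G = as.numeric(G[ord]), lambda = as.numeric(lambda[ord]),
                 N = length(G)), class = "maxwell_spectrum")
}

#' Continuous relaxation spectrum H(lambda) on a log-spaced grid
#'
#' `H(lambda) d ln(lambda)` is the contribution to the modulus from
#' relaxation times in `[lambda, lambda e^{d ln lambda}]`; the linear-measure
#' density is `F = H / lambda`.
#'
#' @param lambda_grid relaxation times, s, log-spaced increasing.
#' @param H spectrum values, Pa, nonnegative.
#' @return An object of class `continuous_spectrum` with the derived
#'   `F_density = H / lambda`.
#' @export
continuous_spectrum <- function(lambda_grid, H) {
  if (length(lambda_grid) != length(H) || length(H) < 2L)
    stop_validation("lambda_grid and H must be equal-length, >= 2 points")
  if (any(lambda_grid <= 0)) stop_validation("lambda grid must be positive")
  if (is.unsorted(lambda_grid, strictly = TRUE))
    stop_validation("lambda grid must be strictly increasing")
  if (any(H < -1e-12 * max(abs(H), 1))) stop_validation("H must be nonnegative")
  H <- pmax(H, 0)
  structure(list(lambda_grid = as.numeric(lambda_grid), H = as.numeric(H),
                 F_density = as.numeric(H / lambda_grid)),
            class = "continuous_spectrum")
}

#' Log-spaced grid constructor
#'
#' @param min,max grid bounds (positive, `min < max`).
#' @param points_per_decade grid density.
#' @return Numeric vector of log-spaced values including both bounds' decades.
#' @export
log_grid <- function(min, max, points_per_decade = 10) {
  if (!(min > 0 && max > min)) stop_validation("need 0 < min < max")
  n <- max(2L, ceiling(log10(max / min) * points_per_decade) + 1L)
  10^seq(log10(min), log10(max), length.out = n)
}

# trapezoid weights on a log grid: integrates f(lambda) d ln(lambda)
trapz_log_weights <- function(x) {
  lx <- log(x)
  n <- length(lx)
  w <- numeric(n)
  w[1L] <- (lx[2L] - lx[1L]) / 2
  w[n] <- (lx[n] - lx[n - 1L]) / 2
  if (n > 2L) w[2:(n - 1L)] <- (lx[3:n] - lx[1:(n - 2L)]) / 2
  w
}

#' Dynamic moduli of a discrete Maxwell spectrum
#'
#' `G'(omega) = sum_i G_i (omega lambda_i)^2 / (1 + (omega lambda_i)^2)`,
#' `G''(omega) = sum_i G_i (omega lambda_i) / (1 + (omega lambda_i)^2)`.
#'
#' @param spec a [maxwell_spectrum()].
#' @param omega angular frequencies, rad/s, positive.
#' @return A list with numeric vectors `g_prime` and `g_double_prime`.
#' @export
forward_moduli_discrete <- function(spec, omega) {
  stopifnot(inherits(spec, "maxwell_spectrum"))
  if (any(omega <= 0)) stop_validation("omega must be positive")
  wl <- outer(omega, spec$lambda)             # n_omega x n_modes
  denom <- 1 + wl^2
  list(g_prime = as.numeric((wl^2 / denom) %*% spec$G),
       g_double_prime = as.numeric((wl / denom) %*% spec$G))
}

#' Dynamic moduli of a continuous spectrum
#'
#' Trapezoidal quadrature on the log-lambda grid of
#' `G'(omega) = int H(lambda) (omega lambda)^2/(1+(omega lambda)^2) d ln lambda`
#' and the corresponding loss kernel.
#'
#' @param spec a [continuous_spectrum()].
#' @param omega angular frequencies, rad/s, positive.
#' @return A list with `g_prime`, `g_double_prime`, and a `warnings`
#'   character vector (non-empty when the grid is coarser than 5
#'   points/decade).
#' @export
forward_moduli_continuous <- function(spec, omega) {
  stopifnot(inherits(spec, "continuous_spectrum"))
  if (any(omega <= 0)) stop_validation("omega must be positive")
  warn <- character()
  ppd <- (length(spec$lambda_grid) - 1L) /
    log10(max(spec$lambda_grid) / min(spec$lambda_grid))
  if (ppd < 5) warn <- "lambda grid coarser than 5 points/decade; quadrature may be inaccurate"
  wq <- trapz_log_weights(spec$lambda_grid)
  wl <- outer(omega, spec$lambda_grid)
  denom <- 1 + wl^2
  hw <- spec$H * wq
  list(g_prime = as.numeric((wl^2 / denom) %*% hw),
       g_double_prime = as.numeric((wl / denom) %*% hw),
       warnings = warn)
}

#' Relaxation modulus G(t) of a discrete or continuous spectrum
#'
#' Discrete: `G(t) = sum_i G_i exp(-t/lambda_i)`. Continuous: log-lambda
#' trapezoidal quadrature of `H(lambda) exp(-t/lambda)`.
#'
#' @param spec a [maxwell_spectrum()] or [continuous_spectrum()].
#' @param time times, s, positive.
#' @return A [relaxation_curve()].
#' @export
relaxation_modulus <- function(spec, time) {
  if (any(time <= 0)) stop_validation("time must be positive")
  g <- if (inherits(spec, "maxwell_spectrum")) {
    as.numeric(exp(-outer(time, 1 / spec$lambda)) %*% spec$G)
  } else if (inherits(spec, "continuous_spectrum")) {
    wq <- trapz_log_weights(spec$lambda_grid)
    as.numeric(exp(-outer(time, 1 / spec$lambda_grid)) %*% (spec$H * wq))
  } else stop_validation("spec must be a maxwell_spectrum or continuous_spectrum")
  relaxation_curve(time, pmax(g, .Machine$double.xmin))
}

#' Loss tangent from forward moduli
#'
#' @param spec a spectrum object.
#' @param omega angular frequencies, rad/s.
#' @return `G''/G'` at each frequency.
#' @export
tan_delta_of <- function(spec, omega) {
  m <- if (inherits(spec, "maxwell_spectrum")) forward_moduli_discrete(spec, omega)
       else forward_moduli_continuous(spec, omega)
  m$g_double_prime / m$g_prime
}

# ---- inversion ---------------------------------------------------------

# second-difference operator on n points (n-2 rows)
second_diff_matrix <- function(n) {
  if (n < 3L) return(matrix(0, 0L, n))
  D <- matrix(0, n - 2L, n)
  for (i in seq_len(n - 2L)) D[i, i:(i + 2L)] <- c(1, -2, 1)
  D
}

# L-curve corner by maximum Menger curvature on (log rho, log eta),
# falling back to the point farthest from the endpoint chord.
lcurve_corner <- function(rho, eta) {
  keep <- which(rho > 0 & eta > 0)
  if (length(keep) < 3L) return(if (length(keep)) keep[which.min(rho[keep])] else 1L)
  x <- log10(rho[keep]); y <- log10(eta[keep])
  n <- length(x)
  curv <- rep(-Inf, n)
  for (i in 2:(n - 1L)) {
    a <- c(x[i - 1L], y[i - 1L]); b <- c(x[i], y[i]); cc <- c(x[i + 1L], y[i + 1L])
    ab <- sqrt(sum((b - a)^2)); bc <- sqrt(sum((cc - b)^2)); ca <- sqrt(sum((cc - a)^2))
    area2 <- abs((b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2]))
    if (ab * bc * ca > 0) curv[i] <- 2 * area2 / (ab * bc * ca)
  }
  i <- which.max(curv)
  if (!is.finite(curv[i]) || curv[i] <= 0) {
    # fallback: farthest point from the chord joining the endpoints
    v <- c(x[n] - x[1], y[n] - y[1]); v <- v / sqrt(sum(v^2))
    d <- abs((x - x[1]) * v[2] - (y - y[1]) * v[1])
    i <- which.max(d)
  }
  keep[i]
}

#' Invert master-curve moduli to a continuous relaxation spectrum
#'
#' Solves the ill-posed problem of recovering `H(lambda)` from `G'(omega)`,
#' `G''(omega)` by nonnegative least squares on relative (approximately
#' log-scale) modulus residuals with a second-difference curvature penalty on
#' `H` along the log-lambda grid. The penalty strength is selected by the
#' L-curve corner over the candidate `reg_strengths`.
#'
#' @param mc a `master_curve` (or [frequency_sweep()]) providing `omega`,
#'   `g_prime`, `g_double_prime`.
#' @param lambda_grid relaxation-time grid, s; default spans the reciprocal
#'   frequency window of the data extended one decade each side at
#'   `points_per_decade` points.
#' @param reg_strengths candidate curvature penalty strengths.
#' @param points_per_decade grid density used when `lambda_grid` is NULL.
#' @return A [continuous_spectrum()] with a `diagnostics` attribute: chosen
#'   strength, refit rms in log10 moduli, L-curve table, fraction of spectrum
#'   mass outside the data window, and warnings.
#' @export
invert_relaxation_spectrum <- function(mc, lambda_grid = NULL,
                                       reg_strengths = 10^seq(-6, 2, by = 0.5),
                                       points_per_decade = 10) {
  omega <- mc$omega; gp <- mc$g_prime; gpp <- mc$g_double_prime
  if (log10(max(omega) / min(omega)) < 2)
    stop_validation("master curve must span >= 2 decades of omega")
  if (is.null(lambda_grid))
    lambda_grid <- log_grid(0.1 / max(omega), 10 / min(omega), points_per_decade)
  n <- length(lambda_grid)
  warn <- character()

  if (all(gp == 0) && all(gpp == 0)) {
    out <- continuous_spectrum(lambda_grid, rep(0, n))
    attr(out, "diagnostics") <- list(strength = NA_real_, refit_rms_log10 = 0,
                                     warnings = "zero moduli; H = 0")
    return(out)
  }

  wq <- trapz_log_weights(lambda_grid)
  wl <- outer(omega, lambda_grid)
  denom <- 1 + wl^2
  Kp <- sweep(wl^2 / denom, 2L, wq, `*`)   # G' kernel  (storage)
  Kpp <- sweep(wl / denom, 2L, wq, `*`)    # G'' kernel (loss)

  ok_p <- gp > 0; ok_pp <- gpp > 0
  # relative residuals: rows scaled by 1/G approximate log residuals
  A0 <- rbind(Kp[ok_p, , drop = FALSE] / gp[ok_p],
              Kpp[ok_pp, , drop = FALSE] / gpp[ok_pp])
  b0 <- c(rep(1, sum(ok_p)), rep(1, sum(ok_pp)))
  D <- second_diff_matrix(n)

  sols <- vector("list", length(reg_strengths))
  rho <- eta <- rep(NA_real_, length(reg_strengths))
  for (k in seq_along(reg_strengths)) {
    a <- reg_strengths[k]
    A <- rbind(A0, sqrt(a) * D)
    b <- c(b0, rep(0, nrow(D)))
    h <- pracma::lsqnonneg(A, b)$x
    sols[[k]] <- h
    rho[k] <- sqrt(mean((A0 %*% h - b0)^2))
    eta[k] <- sqrt(sum((D %*% h)^2))
  }
  if (all(!is.finite(rho))) stop_validation("spectrum inversion failed for all strengths")
  if (max(eta, na.rm = TRUE) <= 1e-14 || diff(range(log10(pmax(rho, 1e-300)))) < 1e-8) {
    k_best <- which.min(rho)
    warn <- c(warn, "flat L-curve: returning smallest-residual solution")
  } else {
    k_best <- lcurve_corner(rho, eta)
    # guard against over-smoothing (the corner is ill-defined as noise -> 0):
    # never accept a fit measurably worse than the best achievable; take the
    # smoothest solution within a factor 1.5 of the minimum residual instead
    rho_min <- min(rho, na.rm = TRUE)
    if (!is.finite(rho[k_best]) || rho[k_best] > 1.5 * rho_min) {
      ok <- which(rho <= 1.5 * rho_min)
      k_best <- ok[which.max(reg_strengths[ok])]
    }
  }
  H <- sols[[k_best]]
  out <- continuous_spectrum(lambda_grid, H)

  fwd <- forward_moduli_continuous(out, omega)
  sel_p <- ok_p & fwd$g_prime > 0; sel_pp <- ok_pp & fwd$g_double_prime > 0
  refit <- sqrt(mean(c(log10(fwd$g_prime[sel_p] / gp[sel_p]),
                       log10(fwd$g_double_prime[sel_pp] / gpp[sel_pp]))^2))
  inside <- lambda_grid >= 1 / max(omega) & lambda_grid <= 1 / min(omega)
  mass <- sum(H * wq)
  mass_out <- if (mass > 0) sum((H * wq)[!inside]) / mass else 0
  if (mass_out > 0.2)
    warn <- c(warn, sprintf("%.0f%% of spectrum mass lies outside the data window (unreliable)",
                            100 * mass_out))
  attr(out, "diagnostics") <- list(
    strength = reg_strengths[k_best], refit_rms_log10 = refit,
    lcurve = data.frame(strength = reg_strengths, residual = rho, seminorm = eta),
    mass_outside_window = mass_out, warnings = warn)
  out
}

#' Fit a dense discrete Maxwell spectrum to a relaxation curve
#'
#' Nonnegative least squares of `G(t) = sum_i G_i exp(-t/lambda_i)` on a
#' fixed log-spaced relaxation-time grid, with rows scaled by `1/G(t)` so
#' decades contribute equally. Used to re-express a computed `G(t)` as
#' dynamic moduli through the Maxwell kernels.
#'
#' @param curve a [relaxation_curve()].
#' @param lambda_grid relaxation-time grid; default spans the time window
#'   extended half a decade each side, 8 points/decade.
#' @param ridge small ridge stabilizer on the mode weights.
#' @return A [maxwell_spectrum()] (zero-weight modes dropped).
#' @export
fit_maxwell_to_relaxation <- function(curve, lambda_grid = NULL, ridge = 1e-8) {
  stopifnot(inherits(curve, "relaxation_curve"))
  t <- curve$time; g <- curve$modulus
  keep <- g > max(g) * 1e-8        # fully relaxed tail carries no information
  t <- t[keep]; g <- g[keep]
  if (length(t) < 3L) stop_validation("need >= 3 positive modulus values")
  if (is.null(lambda_grid))
    lambda_grid <- log_grid(min(t) / sqrt(10), max(t) * sqrt(10), 8)
  E <- exp(-outer(t, 1 / lambda_grid))
  A <- rbind(E / g, sqrt(ridge) * diag(length(lambda_grid)))
  b <- c(rep(1, length(t)), rep(0, length(lambda_grid)))
  Gm <- pracma::lsqnonneg(A, b)$x
  nz <- Gm > max(Gm) * 1e-10
  if (!any(nz)) stop_validation("degenerate relaxation curve: no positive modes")
  maxwell_spectrum(Gm[nz], lambda_grid[nz])
}
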
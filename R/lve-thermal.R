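# QC stage: linear viscoelastic region from amplitude sweeps, denaturation
# temperature from temperature sweeps (50% viscosity drop; tan-delta peak).

#' Detect the linear viscoelastic region of an amplitude sweep
#'
#' The LVE region is the amplitude range over which the moduli are
#' independent of the applied stress or strain. Operationally: the longest
#' contiguous low-amplitude run of points in which every `G'` lies within
#' `+/- rel_tol` of the run's median; ties between equally long runs go to
#' the one starting at lower amplitude.
#'
#' @param sweep an [amplitude_sweep()].
#' @param rel_tol relative plateau tolerance (default 0.05, the conventional
#'   5% criterion).
#' @return A list of class `lve_region`: `temperature`, `amplitude_lower`,
#'   `amplitude_upper`, `plateau_g_prime` (the run median, Pa),
#'   `n_points_in_region`, `indices`.
#' @export
detect_lve_region <- function(sweep, rel_tol = 0.05) {
  stopifnot(inherits(sweep, "amplitude_sweep"))
  if (!(rel_tol > 0 && rel_tol < 1)) stop_validation("rel_tol must lie in (0,1)")
  gp <- sweep$g_prime
  n <- length(gp)
  run_ok <- function(i, j) {
    med <- stats::median(gp[i:j])
    all(abs(gp[i:j] - med) <= rel_tol * med)
  }
  best <- NULL
  for (i in seq_len(n - 2L)) {
    # largest j for this i (runs are nested: if [i,j] fails adding j+1 may
    # still fail/succeed with a different median, so scan exhaustively)
    for (j in seq(i + 2L, n)) {
      if (run_ok(i, j)) {
        if (is.null(best) || (j - i) > (best[2L] - best[1L])) best <- c(i, j)
      }
    }
  }
  if (is.null(best))
    stop_validation("no LVE region: no contiguous run of >= 3 points within %.0f%% of its median",
                    100 * rel_tol)
  i <- best[1L]; j <- best[2L]
  structure(list(temperature = sweep$temperature,
                 amplitude_lower = sweep$amplitude[i],
                 amplitude_upper = sweep$amplitude[j],
                 plateau_g_prime = stats::median(gp[i:j]),
                 n_points_in_region = j - i + 1L,
                 indices = i:j),
            class = "lve_region")
}

#' Denaturation temperature from the viscosity drop
#'
#' `Td` is the lowest temperature at which the complex viscosity has fallen
#' to `drop_fraction` of its initial value (mean of the first 3 points),
#' located by linear interpolation between the bracketing samples.
#'
#' @param sweep a [temperature_sweep()].
#' @param drop_fraction fraction of the initial viscosity defining the
#'   threshold (default 0.5: the 50% drop criterion).
#' @return Temperature in degrees C, or `NA` with a `diagnostic` attribute
#'   when the threshold is never crossed.
#' @export
detect_td_viscosity <- function(sweep, drop_fraction = 0.5) {
  stopifnot(inherits(sweep, "temperature_sweep"))
  if (!(drop_fraction > 0 && drop_fraction < 1))
    stop_validation("drop_fraction must lie in (0,1)")
  eta <- sweep$viscosity; temp <- sweep$temperature
  eta0 <- mean(eta[seq_len(min(3L, length(eta)))])
  thr <- drop_fraction * eta0
  below <- which(eta <= thr)
  if (!length(below)) {
    out <- NA_real_
    attr(out, "diagnostic") <- sprintf(
      "viscosity never fell to %.0f%% of its initial value (min %.3g vs threshold %.3g Pa s)",
      100 * drop_fraction, min(eta), thr)
    return(out)
  }
  i <- below[1L]
  if (i == 1L) return(temp[1L])
  # linear interpolation between the bracketing samples
  temp[i - 1L] + (thr - eta[i - 1L]) * (temp[i] - temp[i - 1L]) / (eta[i] - eta[i - 1L])
}

#' Denaturation temperature from the tan-delta maximum
#'
#' `Td` is the temperature of the maximum of `tan(delta) = G''/G'` after
#' 3-point moving-average smoothing; an interior maximum is refined by
#' parabolic interpolation over the three points around the discrete argmax.
#' A maximum at either boundary cannot distinguish denaturation from drift
#' and is rejected.
#'
#' @param sweep a [temperature_sweep()] with at least 5 points.
#' @return Temperature in degrees C, or `NA` with a `diagnostic` attribute
#'   `"peak not bracketed"` when the smoothed maximum sits at a boundary.
#' @export
detect_td_tandelta <- function(sweep) {
  stopifnot(inherits(sweep, "temperature_sweep"))
  td <- sweep$tan_delta; temp <- sweep$temperature
  n <- length(td)
  if (n < 5L) stop_validation("need >= 5 points for the tan-delta peak")
  sm <- td
  sm[2:(n - 1L)] <- (td[1:(n - 2L)] + td[2:(n - 1L)] + td[3:n]) / 3
  i <- which.max(sm)
  if (i == 1L || i == n) {
    out <- NA_real_
    attr(out, "diagnostic") <- "peak not bracketed: smoothed tan-delta maximum at sweep boundary"
    return(out)
  }
  # parabolic refinement over the three points around the argmax
  y <- sm[(i - 1L):(i + 1L)]; x <- temp[(i - 1L):(i + 1L)]
  d <- (y[1L] - y[3L]) / (2 * (y[1L] - 2 * y[2L] + y[3L]))
  if (!is.finite(d) || abs(d) > 1) return(temp[i])
  # assume (locally) uniform spacing for the vertex offset
  temp[i] + d * (x[3L] - x[1L]) / 2
}

#' Joint denaturation-temperature report
#'
#' Runs both Td estimators and reports their agreement. Neither estimator is
#' privileged; collagen Td tables typically carry a +/- 1.5 degC
#' uncertainty, which is the natural scale for judging the difference.
#'
#' @param sweep a [temperature_sweep()].
#' @param drop_fraction passed to [detect_td_viscosity()].
#' @return A list of class `denaturation_result`: `td_viscosity`,
#'   `td_tandelta` (degC or NA), `method_agreement` (absolute difference,
#'   degC, or NA), `diagnostics`.
#' @export
detect_denaturation <- function(sweep, drop_fraction = 0.5) {
  tv <- detect_td_viscosity(sweep, drop_fraction)
  tt <- detect_td_tandelta(sweep)
  diag <- c(attr(tv, "diagnostic"), attr(tt, "diagnostic"))
  structure(list(td_viscosity = as.numeric(tv),
                 td_tandelta = as.numeric(tt),
                 method_agreement = if (is.na(tv) || is.na(tt)) NA_real_
                                    else abs(tv - tt),
                 diagnostics = if (length(diag)) diag else character()),
            class = "denaturation_result")
}
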
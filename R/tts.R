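# Time-temperature superposition: estimate horizontal (and optionally
# vertical) shift factors by pairwise registration of fitted curves, and
# assemble the master curve at a reference temperature.

fit_temperature <- function(fit) fit$sweep_ref$temperature

# registration objective: rms^2 log10 distance between the already-shifted
# reference curve (cumulative shift s_ref) and candidate curve at shift s,
# over the overlap of their shifted fitted windows. Returns Inf if no overlap.
register_pair_objective <- function(fit_ref, s_ref, b_ref, fit_new, s, vertical) {
  win_ref <- log10(fit_ref$omega_range) + s_ref
  win_new <- log10(fit_new$omega_range) + s
  lo <- max(win_ref[1L], win_new[1L]); hi <- min(win_ref[2L], win_new[2L])
  if (hi - lo < 0.05) return(list(value = Inf, b = 0))
  x <- 10^seq(lo, hi, length.out = 60L)
  mr <- predict_backend(fit_ref$model, fit_ref$params, x / 10^s_ref)
  mn <- predict_backend(fit_new$model, fit_new$params, x / 10^s)
  dp <- log10(mr$g_prime) + b_ref - log10(mn$g_prime)
  dpp <- log10(mr$g_double_prime) + b_ref - log10(mn$g_double_prime)
  b <- if (vertical) mean(c(dp, dpp)) else 0
  list(value = mean(c(dp - b, dpp - b)^2), b = b)
}

#' Estimate time-temperature-superposition shift factors
#'
#' Shift factors are found by sequential pairwise registration outward from
#' the reference temperature: each sweep's fitted curve is registered
#' against its already-shifted neighbor by minimizing the summed squared
#' difference of `log G'` and `log G''` over the overlap window as a
#' function of `log10 aT` (plus an analytically optimal `log10 bT` when
#' `vertical = TRUE`). Registration operates on fitted curves, not raw
#' points, so overlap windows need not share abscissae.
#'
#' @param fits list of `fit_result` objects at distinct temperatures.
#' @param t_ref reference temperature, degrees C; default is the temperature
#'   whose sweep retained the most points.
#' @param vertical also estimate vertical shifts `log10 bT` (off by
#'   default: horizontal-only TTS).
#' @param max_shift_decades search bound for each pairwise `log10 aT` step.
#' @return A list of class `shift_factor_set`: `reference_temperature` and a
#'   data.frame `entries` with `temperature`, `log10_aT`, `log10_bT` (the
#'   reference row has both shifts 0).
#' @export
estimate_shift_factors <- function(fits, t_ref = NULL, vertical = FALSE,
                                   max_shift_decades = 4) {
  temps <- vapply(fits, fit_temperature, numeric(1L))
  if (anyDuplicated(temps)) stop_validation("temperatures must be unique")
  if (is.null(t_ref)) {
    npts <- vapply(fits, function(f) length(f$retained_indices), integer(1L))
    t_ref <- temps[which.max(npts)]
  }
  if (!any(abs(temps - t_ref) < 1e-9))
    stop_validation("no sweep at the reference temperature %.2f C", t_ref)
  ord <- order(temps)
  fits <- fits[ord]; temps <- temps[ord]
  i_ref <- which(abs(temps - t_ref) < 1e-9)
  s <- rep(NA_real_, length(temps)); b <- rep(NA_real_, length(temps))
  s[i_ref] <- 0; b[i_ref] <- 0

  register_one <- function(i_known, i_new) {
    coarse <- seq(s[i_known] - max_shift_decades, s[i_known] + max_shift_decades,
                  by = 0.05)
    vals <- vapply(coarse, function(sc)
      register_pair_objective(fits[[i_known]], s[i_known], b[i_known],
                              fits[[i_new]], sc, vertical)$value, numeric(1L))
    if (all(!is.finite(vals)))
      stop_validation("no overlap achievable within +/-%g decades between %.1f C and %.1f C",
                      max_shift_decades, temps[i_known], temps[i_new])
    k <- which.min(vals)
    lo <- coarse[max(1L, k - 2L)]; hi <- coarse[min(length(coarse), k + 2L)]
    opt <- stats::optimize(function(sc)
      register_pair_objective(fits[[i_known]], s[i_known], b[i_known],
                              fits[[i_new]], sc, vertical)$value,
      interval = c(lo, hi), tol = 1e-8)
    s[i_new] <<- opt$minimum
    b[i_new] <<- register_pair_objective(fits[[i_known]], s[i_known], b[i_known],
                                         fits[[i_new]], opt$minimum, vertical)$b +
                 b[i_known]
  }
  if (i_ref < length(temps))
    for (i in (i_ref + 1L):length(temps)) register_one(i - 1L, i)
  if (i_ref > 1L)
    for (i in (i_ref - 1L):1L) register_one(i + 1L, i)

  structure(list(reference_temperature = t_ref,
                 entries = data.frame(temperature = temps, log10_aT = s,
                                      log10_bT = b)),
            class = "shift_factor_set")
}

#' Assemble the master curve from fitted sweeps and shift factors
#'
#' Applies `omega -> aT * omega` (and `G -> bT * G` when vertical shifts are
#' present) to the retained (unflagged) data points of every sweep, merges
#' and sorts them, and reports the rms log10 discrepancy over overlapping
#' regions (each point compared against the log-log linear interpolant of
#' every other temperature's shifted points covering it).
#'
#' @param fits list of `fit_result` objects.
#' @param shifts a `shift_factor_set` covering every sweep temperature.
#' @return A list of class `master_curve`: `reference_temperature`, `omega`
#'   (shifted, increasing), `g_prime`, `g_double_prime`,
#'   `source_temperature_per_point`, `overlap_rms_log10`.
#' @export
build_master_curve <- function(fits, shifts) {
  stopifnot(inherits(shifts, "shift_factor_set"))
  temps <- vapply(fits, fit_temperature, numeric(1L))
  ord <- order(temps)               # deterministic under input permutation
  fits <- fits[ord]; temps <- temps[ord]
  ent <- shifts$entries
  pieces <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    row <- which(abs(ent$temperature - temps[i]) < 1e-9)
    if (!length(row))
      stop_validation("no shift factor for temperature %.2f C", temps[i])
    aT <- 10^ent$log10_aT[row]; bT <- 10^ent$log10_bT[row]
    keep <- fits[[i]]$retained_indices
    d <- fits[[i]]$data
    pieces[[i]] <- data.frame(omega = d$omega[keep] * aT,
                              g_prime = d$g_prime[keep] * bT,
                              g_double_prime = d$g_double_prime[keep] * bT,
                              source = temps[i])
  }
  all_pts <- do.call(rbind, pieces)
  all_pts <- all_pts[order(all_pts$omega, all_pts$source), ]

  # overlap discrepancy: each point vs the interpolant of other temperatures
  diffs <- numeric()
  for (i in seq_along(pieces)) for (j in seq_along(pieces)) {
    if (i == j) next
    pi_ <- pieces[[i]]; pj <- pieces[[j]]
    inside <- pj$omega >= min(pi_$omega) & pj$omega <= max(pi_$omega)
    if (sum(inside) == 0L || nrow(pi_) < 2L) next
    ip <- stats::approx(log10(pi_$omega), log10(pi_$g_prime),
                        xout = log10(pj$omega[inside]))$y
    ipp <- stats::approx(log10(pi_$omega), log10(pi_$g_double_prime),
                         xout = log10(pj$omega[inside]))$y
    diffs <- c(diffs, ip - log10(pj$g_prime[inside]),
               ipp - log10(pj$g_double_prime[inside]))
  }
  structure(list(reference_temperature = shifts$reference_temperature,
                 omega = all_pts$omega, g_prime = all_pts$g_prime,
                 g_double_prime = all_pts$g_double_prime,
                 source_temperature_per_point = all_pts$source,
                 overlap_rms_log10 = if (length(diffs)) sqrt(mean(diffs^2)) else NA_real_),
            class = "master_curve")
}

#' @export
print.master_curve <- function(x, ...) {
  cat(sprintf("<master_curve> %d points, %.3g-%.3g rad/s at Tref = %.1f C (overlap rms %.2g)\n",
              length(x$omega), min(x$omega), max(x$omega),
              x$reference_temperature, x$overlap_rms_log10))
  invisible(x)
}
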
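# One-way fixed-effects ANOVA over Mw populations: raw-data and
# summary-statistics variants, with the alpha = 0.05 decision convention
# used for reproducibility assessment.

anova_from_ss <- function(labels, ns, means, sds) {
  N <- sum(ns); g <- length(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df_b <- g - 1L; df_w <- N - g
  flagged <- FALSE
  if (ssw <= 0 && ssb <= 0) {
    f <- 0; p <- 1; flagged <- TRUE      # no variance anywhere: p = 1 convention
  } else if (ssw <= 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ssb / df_b) / (ssw / df_w)
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  structure(list(
    f_statistic = f, p_value = p,
    df_between = as.integer(df_b), df_within = as.integer(df_w),
    group_summaries = data.frame(label = labels, n = as.integer(ns),
                                 mean = means, sd = sds),
    decision = if (p > 0.05) "fail to reject equal means (p > 0.05)"
               else "reject equal means (p < 0.05)",
    degenerate = flagged), class = "anova_result")
}

#' One-way ANOVA over labeled groups
#'
#' Classical fixed-effects one-way analysis of variance: the F statistic is
#' the ratio of between-group to pooled within-group mean squares, with the
#' upper-tail p-value from the F distribution and a decision string at the
#' 95% confidence level. Degenerate input (all groups constant and equal)
#' returns `p = 1` with a `degenerate` flag.
#'
#' @param groups named list of numeric vectors, each of length >= 2; at
#'   least 2 groups.
#' @return An object of class `anova_result`: `f_statistic`, `p_value`,
#'   `df_between`, `df_within`, `group_summaries` (label, n, mean, sd),
#'   `decision`, `degenerate`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_validation("need >= 2 groups")
  ns <- lengths(groups)
  if (any(ns < 2L))
    stop_validation("every group needs n >= 2 (group %d has %d)",
                    which(ns < 2L)[1L], min(ns))
  labels <- if (is.null(names(groups))) as.character(seq_along(groups))
            else names(groups)
  anova_from_ss(labels, ns,
                vapply(groups, mean, numeric(1L)),
                vapply(groups, stats::sd, numeric(1L)))
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the between-group and pooled within-group sums of squares
#' from `(n, mean, sd)` triples; identical to [one_way_anova()] whenever the
#' summaries were computed from the raw groups. Enables ANOVA on tabulated
#' results whose raw replicates are unavailable.
#'
#' @param summaries data.frame with columns `n`, `mean`, `sd` (optionally
#'   `label`).
#' @return An `anova_result`, as for [one_way_anova()].
#' @export
anova_from_summaries <- function(summaries) {
  stopifnot(all(c("n", "mean", "sd") %in% names(summaries)))
  if (nrow(summaries) < 2L) stop_validation("need >= 2 groups")
  if (any(summaries$n < 2L)) stop_validation("every group needs n >= 2")
  if (any(summaries$sd < 0)) stop_validation("sd must be nonnegative")
  labels <- if ("label" %in% names(summaries)) as.character(summaries$label)
            else as.character(seq_len(nrow(summaries)))
  anova_from_ss(labels, summaries$n, summaries$mean, summaries$sd)
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.3g; %s\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value, x$decision))
  invisible(x)
}
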
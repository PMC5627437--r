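#' Optimal survival cutpoint for a single gene
#'
#' Scans every distinct observed expression value as a candidate threshold
#' dividing the cohort into "low" (at or below the cut) and "high" (above)
#' groups, keeps candidates leaving at least `min_group_frac` of the samples
#' on each side, computes the two-sample log-rank chi-square statistic at
#' each, and returns the cut maximizing it (first maximum on ties, scanning
#' candidates in increasing order). The resulting high-vs-low comparison is
#' reported as a proportional-hazards fit.
#'
#' The maximally selected statistic is anti-conservative relative to a
#' prespecified cut — the returned p-value is not adjusted for the search;
#' this mirrors the common single-gene baseline and is documented rather
#' than corrected.
#'
#' @param expr Numeric expression vector in the row order of `surv` (>= 10
#'   samples).
#' @param surv Survival table with >= 2 events.
#' @param min_group_frac Minimum fraction of samples on each side of an
#'   admissible cut (default 0.1).
#' @return A list of class `"optimal_cutpoint"`: `cut`, `statistic`
#'   (log-rank chi-square at the cut), `comparison` (a
#'   `"subgroup_comparison"`, high vs. low treated as unfavorable vs.
#'   favorable orientation), and `scan` (tibble of candidate cuts and
#'   statistics).
#' @export
optimal_cutpoint <- function(expr, surv, min_group_frac = 0.1) {
  surv <- validate_survival(surv)
  if (length(expr) != nrow(surv)) abort("`expr` length must match `surv` rows")
  if (length(expr) < 10) abort("need at least 10 samples")
  if (sum(surv$event) < 2) abort("need at least 2 events")
  n <- length(expr)
  min_n <- max(1L, ceiling(min_group_frac * n))
  candidates <- sort(unique(expr))
  # cutting at value c: low = expr <= c; last candidate leaves high empty
  ok <- vapply(candidates, function(cc) {
    n_low <- sum(expr <= cc)
    n_low >= min_n && (n - n_low) >= min_n
  }, logical(1))
  candidates <- candidates[ok]
  if (length(candidates) == 0) abort("no admissible cut under min_group_frac")

  stat <- vapply(candidates, function(cc) {
    grp <- factor(expr > cc, levels = c(FALSE, TRUE))
    sd_ <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ grp)
    unname(sd_$chisq)
  }, numeric(1))
  best <- which.max(stat) # first maximum
  cut <- candidates[best]

  groups <- structure(
    tibble(
      sample_id = surv$sample_id,
      group = ifelse(expr > cut, "unfavorable_group", "favorable_group")
    ),
    degenerate = FALSE,
    class = c("subgroup_assignment", "tbl_df", "tbl", "data.frame")
  )
  comparison <- suppressWarnings(compare_subgroup_survival(groups, surv))
  structure(
    list(
      cut = cut,
      statistic = stat[best],
      comparison = comparison,
      scan = tibble(cut = candidates, statistic = stat)
    ),
    class = "optimal_cutpoint"
  )
}

#' @export
print.optimal_cutpoint <- function(x, ...) {
  cat(sprintf(
    "<optimal_cutpoint> cut = %.4g (log-rank chi-square %.3g); high vs low HR = %.3g, Cox p = %.3g\n",
    x$cut, x$statistic, x$comparison$hazard_ratio, x$comparison$p_value
  ))
  invisible(x)
}
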
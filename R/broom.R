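#' Tidy a subgroup comparison
#'
#' @param x A `"subgroup_comparison"`.
#' @param ... Unused.
#' @return One-row tibble with the test statistic, p-value and group sizes.
#' @export
tidy.subgroup_comparison <- function(x, ...) {
  tibble(
    statistic_kind = x$statistic_kind,
    p_value = x$p_value,
    hazard_ratio = x$hazard_ratio,
    n_favorable = unname(x$n_per_group[["favorable_group"]]),
    n_unfavorable = unname(x$n_per_group[["unfavorable_group"]]),
    flag = x$flag
  )
}

#' @rdname tidy.subgroup_comparison
#' @export
glance.subgroup_comparison <- function(x, ...) tidy.subgroup_comparison(x, ...)

#' Tidy cross-validation results
#'
#' `tidy()` returns the per-fold table; `glance()` the one-row summary
#' (median and SD of train- and test-fold p-values).
#'
#' @param x A `"cv_result"`.
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) as_tibble(x)

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) attr(x, "summary")

#' Tidy a drug-similarity object into pairwise correlations
#'
#' @param x A `"drug_similarity"`.
#' @param ... Unused.
#' @return Tibble with one row per unordered drug pair: `drug_a`, `drug_b`,
#'   `similarity`, `n_pairs`.
#' @export
tidy.drug_similarity <- function(x, ...) {
  r <- x$similarity
  idx <- which(upper.tri(r), arr.ind = TRUE)
  tibble(
    drug_a = rownames(r)[idx[, 1]],
    drug_b = colnames(r)[idx[, 2]],
    similarity = r[idx],
    n_pairs = x$n_pairs[idx]
  )
}

#' Tidy an optimal-cutpoint result
#'
#' @param x An `"optimal_cutpoint"`.
#' @param ... Unused.
#' @return One-row tibble with the cut, its log-rank statistic, and the
#'   resulting high-vs-low comparison.
#' @export
tidy.optimal_cutpoint <- function(x, ...) {
  tibble(
    cut = x$cut,
    statistic = x$statistic,
    p_value = x$comparison$p_value,
    hazard_ratio = x$comparison$hazard_ratio
  )
}

#' Glance at a tumor workflow
#'
#' @param x A `"tumor_workflow"`.
#' @param ... Unused.
#' @return One-row tibble: per-stage gene counts, subgroup p and HR, CV
#'   medians when available.
#' @export
glance.tumor_workflow <- function(x, ...) {
  cv <- if (!is.null(x$cv)) attr(x$cv, "summary") else
    tibble(median_train_p = NA_real_, median_test_p = NA_real_)
  tibble(
    n_screen_hits = nrow(x$hits),
    n_signature = nrow(x$signature),
    subgroup_p = if (!is.null(x$comparison)) x$comparison$p_value else NA_real_,
    hazard_ratio = if (!is.null(x$comparison)) x$comparison$hazard_ratio else NA_real_,
    median_train_p = cv$median_train_p[1],
    median_test_p = cv$median_test_p[1]
  )
}
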
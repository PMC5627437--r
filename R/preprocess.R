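#' Log2-normalize a raw-count expression matrix
#'
#' Replaces each count x by log2(x + 1). The pseudocount of 1 keeps zeros at
#' zero and makes the transform monotone, so within-gene sample ranks are
#' preserved.
#'
#' @param m An [expression_matrix()] on the `"raw_count"` scale with
#'   non-negative values.
#' @return The matrix on the `"log2"` scale.
#' @export
log2_normalize <- function(m) {
  if (expr_scale(m) != "raw_count") abort("`m` must be on the raw_count scale")
  if (any(m < 0, na.rm = TRUE)) abort("raw counts must be non-negative")
  expression_matrix(log2(unclass(m) + 1), scale = "log2")
}

#' Remove low-count genes
#'
#' A gene is removed when its count is `max_count` or smaller in strictly
#' more than `frac` of the samples (defaults: count <= 2 in over 80% of
#' samples). Applied to raw counts, before log transformation. Surviving
#' genes keep their original order; samples are untouched.
#'
#' @param m An [expression_matrix()] on the `"raw_count"` scale.
#' @param max_count Count threshold defining "low" (default 2).
#' @param frac Removal triggers when the low-count fraction of samples is
#'   strictly greater than this (default 0.8).
#' @return The filtered matrix.
#' @export
filter_low_count <- function(m, max_count = 2, frac = 0.8) {
  if (expr_scale(m) != "raw_count") abort("low-count filter applies to raw counts")
  low_frac <- rowMeans(unclass(m) <= max_count, na.rm = TRUE)
  keep <- low_frac <= frac
  if (!any(keep)) warn("all genes removed by the low-count filter")
  keep_genes(m, keep)
}

#' Remove low-variability genes by coefficient of variation
#'
#' A gene is removed when its coefficient of variation (sample SD with the
#' n-1 denominator, divided by the absolute mean) is `min_cv` or smaller.
#' Genes with zero mean (CV undefined) are removed with a warning, as are
#' genes missing in more than 20% of samples.
#'
#' @param m An [expression_matrix()].
#' @param min_cv CV at or below which a gene is dropped (default 0.05).
#' @return The filtered matrix.
#' @export
filter_low_cv <- function(m, min_cv = 0.05) {
  vals <- unclass(m)
  na_frac <- rowMeans(is.na(vals))
  if (any(na_frac > 0.2)) {
    warn(sprintf("%d gene(s) with > 20%% missing values dropped", sum(na_frac > 0.2)))
  }
  mu <- rowMeans(vals, na.rm = TRUE)
  s <- apply(vals, 1L, sd, na.rm = TRUE)
  zero_mean <- !is.na(mu) & mu == 0
  if (any(zero_mean)) {
    warn(sprintf("%d zero-mean gene(s) removed (CV undefined)", sum(zero_mean)))
  }
  cv <- s / abs(mu)
  keep <- na_frac <= 0.2 & !zero_mean & !is.na(cv) & cv > min_cv
  if (!any(keep)) warn("all genes removed by the CV filter")
  keep_genes(m, keep)
}
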
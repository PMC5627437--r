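#' High-expression threshold for one gene
#'
#' The discretization cutoff is the gene's median plus half of its sample
#' standard deviation (n-1 denominator); a sample counts as "high" for that
#' gene when its expression is at or above the threshold.
#'
#' @param expr Numeric vector with at least 2 finite values.
#' @return A single numeric threshold.
#' @export
#' @examples
#' expression_threshold(c(0, 2)) # 1 + sqrt(2)/2
expression_threshold <- function(expr) {
  expr <- expr[is.finite(expr)]
  if (length(expr) < 2) abort("need at least 2 finite values")
  median(expr) + sd(expr) / 2
}

#' Class samples by survival outcome
#'
#' In `patient_class` mode each sample is classed against the cohort's
#' median event time: "poor" if it had an event at or before that time,
#' "good" if it remained event-free at least that long (whether censored
#' later or having a later event), and "neutral" when censored earlier
#' (insufficient follow-up). In `gene_direction` mode classing is deferred
#' to the per-gene Cox direction and this function only records the mode.
#'
#' @param surv Survival table with >= 2 events.
#' @param mode `"patient_class"` or `"gene_direction"`.
#' @return Tibble of class `"sample_classing"`: `sample_id`, `class`
#'   (`"good"`, `"poor"`, `"neutral"`, or NA in gene_direction mode), with
#'   a `mode` attribute.
#' @export
class_samples_survival <- function(surv, mode = c("gene_direction",
                                                  "patient_class")) {
  mode <- match.arg(mode)
  surv <- validate_survival(surv)
  if (sum(surv$event) == 0) abort("no events in survival table")
  if (mode == "gene_direction") {
    out <- tibble(sample_id = surv$sample_id, class = NA_character_)
  } else {
    med <- median(surv$time[surv$event == 1])
    cls <- ifelse(surv$event == 1 & surv$time <= med, "poor",
                  ifelse(surv$time >= med, "good", "neutral"))
    if (!any(cls == "good") || !any(cls == "poor")) {
      warn("degenerate survival classing: a class is empty")
    }
    out <- tibble(sample_id = surv$sample_id, class = cls)
  }
  structure(out, mode = mode, anchor = "survival",
            class = c("sample_classing", class(out)))
}

#' Class cell lines by IC-50 extremes
#'
#' A line is "sensitive" when its IC-50 for the drug lies at or below the
#' `lower_q` quantile of the IC-50 distribution across lines, "resistant" at
#' or above the `upper_q` quantile, "neutral" otherwise (quartiles by
#' default; type-7 quantile interpolation). Classing is rank-based, so any
#' monotone transform of IC-50 (e.g. log) gives the same classes.
#'
#' @param ic50 Named numeric vector of IC-50 values (names = line ids) or a
#'   tibble with `line_id` and `ic50`.
#' @param lower_q,upper_q Quantile cutoffs (defaults 0.25 / 0.75).
#' @return Tibble of class `"sample_classing"`: `sample_id`, `class`
#'   (`"sensitive"`/`"resistant"`/`"neutral"`).
#' @export
class_lines_sensitivity <- function(ic50, lower_q = 0.25, upper_q = 0.75) {
  if (is.data.frame(ic50)) ic50 <- setNames(ic50$ic50, ic50$line_id)
  if (length(ic50) < 5) abort("need at least 5 lines")
  if (is.null(names(ic50))) abort("`ic50` must be named by line id")
  if (max(ic50, na.rm = TRUE) == min(ic50, na.rm = TRUE)) {
    warn("constant IC-50: all lines neutral")
    cls <- rep("neutral", length(ic50))
  } else {
    q <- quantile(ic50, c(lower_q, upper_q), na.rm = TRUE, type = 7)
    cls <- ifelse(ic50 <= q[1], "sensitive",
                  ifelse(ic50 >= q[2], "resistant", "neutral"))
  }
  out <- tibble(sample_id = names(ic50), class = cls)
  structure(out, mode = "sample_class", anchor = "sensitivity",
            class = c("sample_classing", class(out)))
}

#' Discretize expression into favorability scores
#'
#' Builds the samples x genes matrix of favorability scores F in
#' \{-1, 0, +1\}. A score is nonzero only when the sample's expression of
#' the gene is at or above the gene's threshold (median + SD/2, computed on
#' this matrix unless frozen thresholds are supplied). The sign comes from
#' the anchor condition:
#'
#' * `mode = "gene_direction"`: +1 for genes the screen calls favorable
#'   (negative Cox coefficient / negative Kendall tau with IC-50), -1 for
#'   unfavorable genes — all nonzero scores in a gene column share one sign;
#' * `mode = "sample_class"`: +1 when the sample is in the good-survival
#'   (or drug-sensitive) class, -1 in the poor (resistant) class, 0 for
#'   neutral samples.
#'
#' @param m An [expression_matrix()] (log scale).
#' @param screen Screen results restricting and orienting the genes
#'   (required in gene_direction mode; rows with NA direction are dropped).
#' @param classing A `"sample_classing"` (required in sample_class mode).
#' @param mode `"gene_direction"` or `"sample_class"`.
#' @param anchor `"survival"` or `"sensitivity"` (recorded in the result).
#' @param thresholds Optional named per-gene thresholds to apply frozen
#'   (e.g. from training folds); computed from `m` when NULL.
#' @return Integer samples x genes matrix of class `"favorability_matrix"`
#'   with attributes `thresholds`, `anchor`, `mode`, `classing`.
#' @export
score_matrix <- function(m, screen = NULL, classing = NULL,
                         mode = c("gene_direction", "sample_class"),
                         anchor = c("survival", "sensitivity"),
                         thresholds = NULL) {
  mode <- match.arg(mode)
  anchor <- match.arg(anchor)
  vals <- unclass(m)

  if (!is.null(screen)) {
    screen <- as_tibble(screen)
    genes <- intersect(screen$gene_id[!is.na(screen$direction)], rownames(vals))
    vals <- vals[genes, , drop = FALSE]
  }
  if (nrow(vals) == 0) abort("no genes left to score")

  if (is.null(thresholds)) {
    thresholds <- apply(vals, 1L, expression_threshold)
  } else {
    if (is.null(names(thresholds))) abort("`thresholds` must be named by gene")
    missing_thr <- setdiff(rownames(vals), names(thresholds))
    if (length(missing_thr)) abort("missing thresholds for some genes")
    thresholds <- thresholds[rownames(vals)]
  }
  high <- vals >= thresholds # thresholds recycled down rows (genes)

  if (mode == "gene_direction") {
    if (is.null(screen)) abort("gene_direction mode requires `screen`")
    dirs <- setNames(screen$direction, screen$gene_id)[rownames(vals)]
    sign_g <- ifelse(dirs == "favorable", 1L, -1L)
    scores <- t(high * sign_g) # samples x genes
  } else {
    if (is.null(classing)) abort("sample_class mode requires `classing`")
    cls <- setNames(classing$class, classing$sample_id)[colnames(vals)]
    if (anyNA(cls)) abort("classing must cover every sample")
    sign_s <- ifelse(cls %in% c("good", "sensitive"), 1L,
                     ifelse(cls %in% c("poor", "resistant"), -1L, 0L))
    scores <- t(high) * sign_s
  }
  storage.mode(scores) <- "integer"
  dimnames(scores) <- list(colnames(vals), rownames(vals))
  structure(scores, thresholds = thresholds, anchor = anchor, mode = mode,
            classing = classing, class = c("favorability_matrix", "matrix",
                                           "array"))
}

#' @export
print.favorability_matrix <- function(x, ...) {
  cat(sprintf(
    "<favorability_matrix> %d samples x %d genes (anchor %s, mode %s); +1: %d, -1: %d, 0: %d\n",
    nrow(x), ncol(x), attr(x, "anchor"), attr(x, "mode"),
    sum(x == 1L), sum(x == -1L), sum(x == 0L)
  ))
  invisible(x)
}

#' Write a favorability matrix with its JSON sidecar
#'
#' The scores go to `<stem>.tsv` (first column `sample_id`); thresholds,
#' anchor, mode and any sample classing go to `<stem>.json`.
#'
#' @param F A `"favorability_matrix"`.
#' @param stem Output path stem.
#' @return The paths written, invisibly.
#' @export
write_favorability_tsv <- function(F, stem) {
  tsv <- paste0(stem, ".tsv")
  df <- tibble::as_tibble(unclass(F), rownames = "sample_id")
  readr::write_tsv(df, tsv)
  side <- paste0(stem, ".json")
  classing <- attr(F, "classing")
  jsonlite::write_json(
    list(
      anchor = attr(F, "anchor"),
      mode = attr(F, "mode"),
      thresholds = as.list(attr(F, "thresholds")),
      classing = if (is.null(classing)) NULL else as.list(
        setNames(classing$class, classing$sample_id)
      )
    ),
    side, auto_unbox = TRUE, digits = NA
  )
  invisible(c(tsv, side))
}
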
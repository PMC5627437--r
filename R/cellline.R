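#' Kendall rank correlation with p-value
#'
#' Tie-corrected Kendall tau-b between two paired vectors, with an exact
#' two-sided p-value (full permutation distribution of the concordance
#' statistic) for n <= 8 without ties and the normal approximation
#' otherwise.
#'
#' @param x,y Paired numeric vectors with at least 5 complete pairs.
#' @return Tibble with `tau`, `p_value`, `n`.
#' @export
kendall_tau <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) abort("need at least 5 paired finite values")
  if (max(x) == min(x) || max(y) == min(y)) {
    abort("tau undefined for a constant vector")
  }
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    cor.test(x, y, method = "kendall", exact = !has_ties && n <= 8)
  )
  tibble(tau = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Screen genes against drug IC-50 by Kendall correlation
#'
#' The cell-line analogue of the survival screen: per gene, the Kendall tau
#' between expression across lines and the drug's IC-50. A gene is a hit
#' when |tau| > `min_tau` and p <= `max_p` (defaults: 0.2 and 0.01). A
#' negative tau with IC-50 means high expression tracks lower IC-50, i.e.
#' sensitivity, so such genes are labeled favorable; positive tau is
#' unfavorable (resistance). Constant genes are skipped with a warning.
#'
#' @param m Log-scale [expression_matrix()], ideally CV-filtered
#'   ([filter_low_cv()]).
#' @param ic50 Named IC-50 vector (names = line ids) or tibble with
#'   `line_id`, `ic50`; at least 5 lines.
#' @param min_tau Absolute tau that must be exceeded (default 0.2).
#' @param max_p Largest admissible p (default 0.01).
#' @return Tibble of class `"screen_result"`: `gene_id`, `tau`, `p_value`,
#'   `direction`, `hit`.
#' @export
screen_genes_ic50 <- function(m, ic50, min_tau = 0.2, max_p = 0.01) {
  if (is.data.frame(ic50)) ic50 <- setNames(ic50$ic50, ic50$line_id)
  if (length(ic50) < 5) abort("need at least 5 lines")
  common <- intersect(colnames(m), names(ic50))
  if (length(common) < 5) abort("fewer than 5 lines shared between matrix and IC-50")
  vals <- unclass(m)[, common, drop = FALSE]
  y <- ic50[common]
  rows <- purrr::map(seq_len(nrow(vals)), function(i) {
    x <- vals[i, ]
    res <- tryCatch(kendall_tau(x, y), error = function(e) NULL)
    if (is.null(res)) {
      return(tibble(gene_id = rownames(vals)[i], tau = NA_real_,
                    p_value = NA_real_, direction = NA_character_))
    }
    dplyr::mutate(res[, c("tau", "p_value")],
                  gene_id = rownames(vals)[i],
                  direction = ifelse(.data$tau < 0, "favorable", "unfavorable"),
                  .before = 1)
  })
  out <- dplyr::bind_rows(rows)[, c("gene_id", "tau", "p_value", "direction")]
  n_skip <- sum(is.na(out$tau))
  if (n_skip > 0) warn(sprintf("%d constant gene(s) skipped", n_skip))
  out$hit <- !is.na(out$tau) & abs(out$tau) > min_tau & out$p_value <= max_p
  structure(out, min_tau = min_tau, max_p = max_p,
            class = c("screen_result", class(out)))
}

#' End-to-end cell-line sensitivity pipeline for one drug
#'
#' Composes the cell-line branch: low-CV gene filter, Kendall-tau screen
#' against the drug's IC-50, sensitive/resistant classing of lines at the
#' IC-50 extremes, favorability scoring, k-means subgrouping, and a Wilcoxon
#' comparison of IC-50 between the subgroups.
#'
#' @param m Log-scale [expression_matrix()] (genes x lines).
#' @param panel A [dose_response_panel()].
#' @param drug Drug identifier present in the panel.
#' @param min_cv CV filter threshold (default 0.05).
#' @param min_tau,max_p Screen thresholds (defaults 0.2 and 0.01).
#' @param mode Favorability mode, `"gene_direction"` (default) or
#'   `"sample_class"` (uses the sensitive/resistant line classes).
#' @param lower_q,upper_q IC-50 quantiles for line classing.
#' @param k,n_restarts,seed Clustering parameters.
#' @return List of class `"cellline_pipeline"`: `screen`, `hits`,
#'   `classing`, `favorability`, `groups`, `comparison`, `manifest` (tibble
#'   of per-stage gene/line counts).
#' @export
run_cellline_pipeline <- function(m, panel, drug,
                                  min_cv = 0.05, min_tau = 0.2, max_p = 0.01,
                                  mode = c("gene_direction", "sample_class"),
                                  lower_q = 0.25, upper_q = 0.75,
                                  k = 2, n_restarts = 50, seed = 1L) {
  mode <- match.arg(mode)
  ic50 <- panel_ic50(panel, drug)
  m2 <- suppressWarnings(filter_low_cv(m, min_cv = min_cv))
  screen <- suppressWarnings(screen_genes_ic50(m2, ic50, min_tau = min_tau,
                                               max_p = max_p))
  hits <- screen_hits(screen)
  classing <- suppressWarnings(
    class_lines_sensitivity(ic50[intersect(names(ic50), colnames(m2))],
                            lower_q = lower_q, upper_q = upper_q)
  )
  if (nrow(hits) == 0) {
    warn("zero-gene signature: no genes passed the IC-50 screen")
    return(structure(
      list(screen = screen, hits = hits, classing = classing,
           favorability = NULL, groups = NULL, comparison = NULL,
           manifest = cellline_manifest(m, m2, hits)),
      class = "cellline_pipeline"
    ))
  }
  Fm <- score_matrix(m2, screen = hits, classing = classing, mode = mode,
                     anchor = "sensitivity")
  groups <- cluster_subgroups(Fm, k = k, n_restarts = n_restarts, seed = seed)
  comparison <- if (!isTRUE(attr(groups, "degenerate")) &&
                    dplyr::n_distinct(groups$group) == 2) {
    compare_subgroup_ic50(groups, ic50)
  } else NULL
  structure(
    list(screen = screen, hits = hits, classing = classing,
         favorability = Fm, groups = groups, comparison = comparison,
         manifest = cellline_manifest(m, m2, hits)),
    class = "cellline_pipeline"
  )
}

cellline_manifest <- function(m, m_cv, hits) {
  tibble(
    stage = c("input", "cv_filter", "ic50_screen"),
    n_genes = c(nrow(m), nrow(m_cv), nrow(hits))
  )
}
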
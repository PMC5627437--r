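#' Kaplan-Meier plot of a subgroup comparison
#'
#' @param object A `"subgroup_comparison"` produced by
#'   [compare_subgroup_survival()].
#' @param ... Unused.
#' @return A ggplot: step survival curves per subgroup, annotated with the
#'   Cox p-value and hazard ratio.
#' @export
autoplot.subgroup_comparison <- function(object, ...) {
  if (is.null(object$km)) {
    abort("no Kaplan-Meier coordinates (Wilcoxon comparison?)")
  }
  km <- dplyr::bind_rows(
    tibble(time = 0, survival = 1, group = unique(object$km$group)),
    object$km
  )
  ggplot2::ggplot(km, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Time (days)", y = "Progression-free survival",
      colour = NULL,
      subtitle = sprintf("Cox p = %.3g, HR (unfavorable vs favorable) = %.3g",
                         object$p_value, object$hazard_ratio)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a favorability matrix
#'
#' @param object A `"favorability_matrix"`.
#' @param ... Unused.
#' @return A ggplot tile map, samples in rows and genes in columns,
#'   favorable (+1) red, unfavorable (-1) blue, neutral (0) pale yellow.
#' @export
autoplot.favorability_matrix <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object), rownames = "sample_id")
  long <- tidyr::pivot_longer(df, -"sample_id", names_to = "gene_id",
                              values_to = "score")
  long$sample_id <- factor(long$sample_id, levels = rev(rownames(object)))
  long$gene_id <- factor(long$gene_id, levels = colnames(object))
  ggplot2::ggplot(long, ggplot2::aes(.data$gene_id, .data$sample_id,
                                     fill = factor(.data$score))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(`-1` = "#2166AC", `0` = "#FFFFBF", `1` = "#B2182B"),
      name = "F"
    ) +
    ggplot2::labs(x = "Gene", y = "Sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Volcano-style view of a survival or IC-50 screen
#'
#' @param object A `"screen_result"` tibble.
#' @param ... Unused.
#' @return A ggplot of effect size (per-SD log-hazard, or Kendall tau)
#'   against -log10 p, hits highlighted.
#' @export
autoplot.screen_result <- function(object, ...) {
  df <- as_tibble(object)
  effect <- if ("coefficient" %in% names(df)) "coefficient" else "tau"
  ggplot2::ggplot(df, ggplot2::aes(.data[[effect]], -log10(.data$p_value),
                                   colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#B2182B"),
                                 name = "hit") +
    ggplot2::labs(
      x = if (effect == "coefficient") "log-hazard per SD" else "Kendall tau",
      y = expression(-log[10] ~ p)
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of phenotype-sensitivity correlations
#'
#' One bar per drug, Spearman rho of the trait against -log10(IC-50);
#' solid fill marks FDR-significant correlations (q < 0.05).
#'
#' @param records A `"correlation_records"` tibble from
#'   [correlate_sensitivity()] or [core_vs_sensitivity()].
#' @return A ggplot, faceted by trait when several are present.
#' @export
plot_correlations <- function(records) {
  df <- as_tibble(records)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$drug, .data$rho,
                                        alpha = .data$significant)) +
    ggplot2::geom_col(fill = "#2166AC") +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 1),
                                name = "q < 0.05") +
    ggplot2::labs(x = NULL, y = "Spearman rho vs -log10(IC-50)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if (dplyr::n_distinct(df$trait) > 1) {
    p <- p + ggplot2::facet_wrap(~trait)
  }
  p
}
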
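#' Cluster samples into response subgroups
#'
#' k-means on the rows (samples) of the favorability matrix, integer scores
#' treated as reals, Euclidean distance, best of `n_restarts` random starts
#' by within-cluster sum of squares, deterministic given `seed`. With k = 2
#' the cluster with the higher mean favorability score is labeled
#' `favorable_group` and the other `unfavorable_group`; for k > 2 groups are
#' labeled `group_1`, `group_2`, ... in decreasing mean favorability.
#'
#' @param F A `"favorability_matrix"` (samples x genes).
#' @param k Number of subgroups (default 2).
#' @param n_restarts Random restarts (default 50).
#' @param seed Integer seed.
#' @return Tibble of class `"subgroup_assignment"`: `sample_id`, `group`.
#'   Attributes: `centers` (group x gene centroid matrix),
#'   `mean_favorability` (named per group), `degenerate` (TRUE when the
#'   matrix had fewer than k distinct rows and no split was possible).
#' @export
cluster_subgroups <- function(F, k = 2, n_restarts = 50, seed = 1L) {
  k <- check_count(k, "k", min = 1L)
  X <- unclass(F)
  storage.mode(X) <- "double"
  if (nrow(X) < 2 * k) abort("need at least 2k samples")
  n_distinct_rows <- nrow(unique(X))
  if (n_distinct_rows < k) {
    warn("favorability matrix is not separable (fewer distinct rows than k)")
    out <- tibble(sample_id = rownames(X),
                  group = rep("favorable_group", nrow(X)))
    return(structure(out,
                     centers = matrix(colMeans(X), 1,
                                      dimnames = list("favorable_group",
                                                      colnames(X))),
                     mean_favorability = c(favorable_group = mean(X)),
                     degenerate = TRUE,
                     class = c("subgroup_assignment", class(out))))
  }
  set.seed(as.integer(seed))
  km <- kmeans(X, centers = k, nstart = n_restarts, iter.max = 50)
  mean_fav <- vapply(seq_len(k), function(i) mean(X[km$cluster == i, ]),
                     numeric(1))
  ord <- order(mean_fav, decreasing = TRUE)
  labels <- if (k == 2) c("favorable_group", "unfavorable_group") else
    paste0("group_", seq_len(k))
  relabel <- setNames(labels, ord) # cluster index -> label
  group <- unname(relabel[as.character(km$cluster)])
  centers <- km$centers[ord, , drop = FALSE]
  rownames(centers) <- labels
  out <- tibble(sample_id = rownames(X), group = group)
  structure(out,
            centers = centers,
            mean_favorability = setNames(mean_fav[ord], labels),
            degenerate = FALSE,
            class = c("subgroup_assignment", class(out)))
}

# assign new samples to the nearest stored centroid (Euclidean)
assign_to_centroids <- function(F, centers) {
  X <- unclass(F)
  storage.mode(X) <- "double"
  X <- X[, colnames(centers), drop = FALSE]
  d2 <- vapply(seq_len(nrow(centers)), function(i) {
    rowSums(sweep(X, 2, centers[i, ])^2)
  }, numeric(nrow(X)))
  nearest <- max.col(-d2, ties.method = "first")
  out <- tibble(sample_id = rownames(X), group = rownames(centers)[nearest])
  structure(out, centers = centers, degenerate = FALSE,
            class = c("subgroup_assignment", class(out)))
}

#' Compare progression-free survival between subgroups
#'
#' Fits a proportional-hazards model with the subgroup as the only
#' covariate and reports the likelihood-ratio p-value and the hazard ratio
#' oriented as unfavorable vs. favorable (HR > 1 means the unfavorable-
#' signature group progresses faster), regardless of group label order.
#' Kaplan-Meier coordinates per group are attached for plotting.
#'
#' @param groups A `"subgroup_assignment"` with exactly 2 groups.
#' @param surv Survival table covering the assigned samples.
#' @return A list of class `"subgroup_comparison"`: `p_value`,
#'   `hazard_ratio`, `n_per_group`, `events_per_group`, `statistic_kind`
#'   (`"cox_lr"`), `flag` (`"ok"` or `"zero_events_group"`), `km` (tibble
#'   `time`, `survival`, `group`).
#' @export
compare_subgroup_survival <- function(groups, surv) {
  surv <- validate_survival(surv)
  df <- dplyr::inner_join(as_tibble(groups), surv, by = "sample_id")
  glev <- c("favorable_group", "unfavorable_group")
  if (!all(glev %in% df$group)) abort("need both favorable and unfavorable groups")
  df$group <- factor(df$group, levels = glev)
  ev <- tapply(df$event, df$group, sum)
  if (sum(ev) < 1) abort("no events in either group")
  flag <- "ok"
  if (any(ev == 0)) {
    warn("a group has zero events; comparison flagged unstable")
    flag <- "zero_events_group"
  }
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ group, data = df,
                    ties = "efron")
  )
  p <- stats::pchisq(2 * diff(fit$loglik), df = 1, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  km <- tibble(
    time = sf$time,
    survival = sf$surv,
    group = rep(sub("^group=", "", names(sf$strata)), sf$strata)
  )
  structure(
    list(
      p_value = unname(p),
      hazard_ratio = unname(exp(stats::coef(fit))),
      n_per_group = table(df$group),
      events_per_group = ev,
      statistic_kind = "cox_lr",
      flag = flag,
      km = km
    ),
    class = "subgroup_comparison"
  )
}

#' Compare IC-50 between cell-line subgroups
#'
#' Two-sided Wilcoxon rank-sum test of log IC-50 between the favorable- and
#' unfavorable-signature groups. The reported direction is the sign of the
#' unfavorable-minus-favorable median log IC-50 difference (positive =
#' unfavorable group more resistant).
#'
#' @param groups A `"subgroup_assignment"`.
#' @param ic50 Named IC-50 vector (names = line ids) or tibble with
#'   `line_id`, `ic50`.
#' @return A `"subgroup_comparison"` with `statistic_kind = "wilcoxon"` and
#'   `median_log_ic50_diff`.
#' @export
compare_subgroup_ic50 <- function(groups, ic50) {
  if (is.data.frame(ic50)) ic50 <- setNames(ic50$ic50, ic50$line_id)
  df <- as_tibble(groups)
  df$log_ic50 <- log(ic50[df$sample_id])
  glev <- c("favorable_group", "unfavorable_group")
  if (!all(glev %in% df$group)) abort("need both favorable and unfavorable groups")
  df <- df[!is.na(df$log_ic50), ]
  if (any(table(df$group)[glev] < 2)) abort("both groups need >= 2 lines")
  x_unf <- df$log_ic50[df$group == "unfavorable_group"]
  x_fav <- df$log_ic50[df$group == "favorable_group"]
  if (max(df$log_ic50) == min(df$log_ic50)) {
    warn("all IC-50 values tied; p = 1")
    p <- 1
  } else {
    p <- suppressWarnings(wilcox.test(x_unf, x_fav)$p.value)
  }
  structure(
    list(
      p_value = unname(p),
      hazard_ratio = NA_real_,
      median_log_ic50_diff = median(x_unf) - median(x_fav),
      n_per_group = table(factor(df$group, levels = glev)),
      statistic_kind = "wilcoxon",
      flag = "ok",
      km = NULL
    ),
    class = "subgroup_comparison"
  )
}

#' @export
print.subgroup_comparison <- function(x, ...) {
  cat(sprintf(
    "<subgroup_comparison> %s p = %.3g%s; n = %s\n",
    x$statistic_kind, x$p_value,
    if (!is.na(x$hazard_ratio)) sprintf(", HR (unfavorable vs favorable) = %.3g",
                                        x$hazard_ratio) else "",
    paste(x$n_per_group, collapse = "/")
  ))
  invisible(x)
}

#' Cross-validated subgroup stratification
#'
#' Splits the cohort into `n_folds` test subsets. For each fold the whole
#' pipeline — proportional-hazards screen, optional confounder filter,
#' per-gene high-expression thresholds (median + SD/2) and gene directions —
#' is estimated on the training samples only, then applied frozen to the
#' held-out fold: test samples receive favorability scores under the
#' training thresholds/directions and are assigned to the nearest training
#' k-means centroid. Train- and test-fold subgroup survival p-values are
#' recorded per fold.
#'
#' @param m Log-scale [expression_matrix()].
#' @param surv Survival table.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment and clustering.
#' @param alpha Screen p threshold.
#' @param binary_covariates,ordinal_covariates Confounder columns; `NULL`
#'   skips the confounder filter.
#' @param k,n_restarts Clustering parameters.
#' @return Tibble of class `"cv_result"`, one row per completed fold:
#'   `fold`, `n_train`, `n_test`, `n_genes`, `train_p`, `train_hr`,
#'   `test_p`, `test_hr`. Attribute `summary` holds median and SD of train
#'   and test p-values.
#' @export
cross_validate <- function(m, surv, n_folds = 5, seed = 1L, alpha = 0.05,
                           binary_covariates = NULL, ordinal_covariates = NULL,
                           k = 2, n_restarts = 20) {
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  surv <- validate_survival(surv)
  m <- align_samples(m, surv)
  n <- nrow(surv)
  if (n < n_folds) abort("fewer samples than folds")
  set.seed(as.integer(seed))
  fold_id <- sample(rep(seq_len(n_folds), length.out = n))

  rows <- purrr::map(seq_len(n_folds), function(f) {
    test_idx <- which(fold_id == f)
    train_idx <- which(fold_id != f)
    surv_tr <- surv[train_idx, ]
    surv_te <- surv[test_idx, ]
    if (sum(surv_tr$event) < 2 || sum(surv_te$event) < 1) {
      warn(sprintf("fold %d skipped: too few events", f))
      return(NULL)
    }
    m_tr <- align_samples(m, surv_tr)
    m_te <- align_samples(m, surv_te)

    scr <- suppressWarnings(screen_genes(m_tr, surv_tr, alpha = alpha))
    hits <- screen_hits(scr)
    if (!is.null(binary_covariates) || !is.null(ordinal_covariates)) {
      hits <- suppressWarnings(filter_confounders(
        hits, m_tr, surv_tr,
        binary_covariates = binary_covariates %||% character(0),
        ordinal_covariates = ordinal_covariates %||% character(0),
        alpha = alpha
      ))
    }
    if (nrow(hits) < 2) {
      warn(sprintf("fold %d skipped: fewer than 2 screened genes", f))
      return(NULL)
    }
    thr <- apply(unclass(m_tr)[hits$gene_id, , drop = FALSE], 1L,
                 expression_threshold)
    F_tr <- score_matrix(m_tr, screen = hits, mode = "gene_direction",
                         anchor = "survival", thresholds = thr)
    grp_tr <- cluster_subgroups(F_tr, k = k, n_restarts = n_restarts,
                                seed = derive_seed(seed, f))
    if (isTRUE(attr(grp_tr, "degenerate")) ||
        dplyr::n_distinct(grp_tr$group) < 2) {
      warn(sprintf("fold %d skipped: degenerate training clustering", f))
      return(NULL)
    }
    F_te <- score_matrix(m_te, screen = hits, mode = "gene_direction",
                         anchor = "survival", thresholds = thr)
    grp_te <- assign_to_centroids(F_te, attr(grp_tr, "centers"))

    cmp_tr <- tryCatch(suppressWarnings(compare_subgroup_survival(grp_tr, surv_tr)),
                       error = function(e) NULL)
    cmp_te <- tryCatch(suppressWarnings(compare_subgroup_survival(grp_te, surv_te)),
                       error = function(e) NULL)
    if (is.null(cmp_tr) || is.null(cmp_te)) {
      warn(sprintf("fold %d skipped: a group had no events", f))
      return(NULL)
    }
    tibble(
      fold = f, n_train = length(train_idx), n_test = length(test_idx),
      n_genes = nrow(hits),
      train_p = cmp_tr$p_value, train_hr = cmp_tr$hazard_ratio,
      test_p = cmp_te$p_value, test_hr = cmp_te$hazard_ratio
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("all folds were skipped")
  summary <- tibble(
    median_train_p = median(out$train_p), sd_train_p = sd(out$train_p),
    median_test_p = median(out$test_p), sd_test_p = sd(out$test_p),
    n_folds_completed = nrow(out)
  )
  structure(out, summary = summary, class = c("cv_result", class(out)))
}
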
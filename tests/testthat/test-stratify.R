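block_favorability <- function() {
  vals <- rbind(
    matrix(1L, 10, 8), # 10 samples scoring +1 everywhere
    matrix(-1L, 10, 8) # 10 samples scoring -1 everywhere
  )
  dimnames(vals) <- list(sprintf("s%02d", 1:20), paste0("g", 1:8))
  structure(vals, anchor = "survival", mode = "gene_direction",
            thresholds = setNames(rep(0, 8), paste0("g", 1:8)),
            class = c("favorability_matrix", "matrix", "array"))
}

test_that("separable blocks split perfectly with correct group labels", {
  Fm <- block_favorability()
  grp <- cluster_subgroups(Fm, seed = 1)
  expect_false(attr(grp, "degenerate"))
  expect_identical(grp$group[1:10], rep("favorable_group", 10))
  expect_identical(grp$group[11:20], rep("unfavorable_group", 10))
  mf <- attr(grp, "mean_favorability")
  expect_gt(mf[["favorable_group"]], mf[["unfavorable_group"]])
})

test_that("an all-zero favorability matrix is flagged non-separable", {
  Fm <- block_favorability()
  Fm[] <- 0L
  expect_warning(grp <- cluster_subgroups(Fm, seed = 1), "not separable")
  expect_true(attr(grp, "degenerate"))
})

test_that("clustering is invariant to sample order and deterministic under seed", {
  set.seed(20)
  vals <- rbind(matrix(rbinom(80, 1, 0.8), 10, 8),
                -matrix(rbinom(80, 1, 0.8), 10, 8))
  dimnames(vals) <- list(sprintf("s%02d", 1:20), paste0("g", 1:8))
  Fm <- structure(vals, class = c("favorability_matrix", "matrix", "array"))
  g1 <- cluster_subgroups(Fm, seed = 5)
  g2 <- cluster_subgroups(Fm, seed = 5)
  expect_identical(g1, g2)
  perm <- sample(1:20)
  Fp <- structure(vals[perm, ], class = c("favorability_matrix", "matrix", "array"))
  gp <- cluster_subgroups(Fp, seed = 5)
  joined <- dplyr::inner_join(tibble::as_tibble(g1), tibble::as_tibble(gp),
                              by = "sample_id")
  expect_equal(adjusted_rand_index(joined$group.x, joined$group.y), 1)
})

test_that("relabeling subgroups inverts the hazard ratio", {
  set.seed(21)
  n <- 60
  grp_lab <- rep(c("favorable_group", "unfavorable_group"), each = n / 2)
  surv <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:n),
    time = rexp(n, 0.02 * ifelse(grp_lab == "unfavorable_group", 3, 1)),
    event = rbinom(n, 1, 0.8)
  )
  mk <- function(lab) structure(
    tibble::tibble(sample_id = surv$sample_id, group = lab),
    degenerate = FALSE,
    class = c("subgroup_assignment", "tbl_df", "tbl", "data.frame")
  )
  c1 <- compare_subgroup_survival(mk(grp_lab), surv)
  flipped <- ifelse(grp_lab == "favorable_group", "unfavorable_group",
                    "favorable_group")
  c2 <- compare_subgroup_survival(mk(flipped), surv)
  expect_equal(c1$hazard_ratio, 1 / c2$hazard_ratio, tolerance = 1e-8)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-8)
  expect_gt(c1$hazard_ratio, 1)
  expect_s3_class(autoplot(c1), "ggplot")
  td <- tidy(c1)
  expect_equal(td$p_value, c1$p_value)
})

test_that("Wilcoxon IC-50 comparison matches the exact tail for disjoint groups", {
  groups <- structure(
    tibble::tibble(
      sample_id = paste0("L", 1:10),
      group = rep(c("favorable_group", "unfavorable_group"), each = 5)
    ),
    degenerate = FALSE,
    class = c("subgroup_assignment", "tbl_df", "tbl", "data.frame")
  )
  ic <- setNames(c(1:5, 101:105), paste0("L", 1:10)) # disjoint ranges
  cmp <- compare_subgroup_ic50(groups, ic)
  expect_equal(cmp$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_gt(cmp$median_log_ic50_diff, 0)

  tied <- setNames(rep(2, 10), paste0("L", 1:10))
  expect_warning(cmp2 <- compare_subgroup_ic50(groups, tied), "tied")
  expect_equal(cmp2$p_value, 1)
})

test_that("cross-validation is reproducible and test folds are honest", {
  cfg <- tumor_sim_config(n_samples = 150, n_genes = 150, seed = 31)
  sim <- simulate_tumor_cohort(cfg)
  cv1 <- suppressWarnings(cross_validate(sim$expression, sim$survival, seed = 8))
  cv2 <- suppressWarnings(cross_validate(sim$expression, sim$survival, seed = 8))
  expect_identical(tibble::as_tibble(cv1), tibble::as_tibble(cv2))
  g <- glance(cv1)
  # no-leakage direction: test p should not beat train p
  expect_gte(g$median_test_p, g$median_train_p)
  expect_equal(nrow(tidy(cv1)), g$n_folds_completed)
})
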
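sim_small_null <- function(seed, n = 60, g = 40) {
  cfg <- tumor_sim_config(n_samples = n, n_genes = g, n_favorable = 0,
                          n_unfavorable = 0, n_confounded = 0, seed = seed)
  simulate_tumor_cohort(cfg)
}

test_that("constant expression is flagged with p = 1", {
  surv <- make_surv_fixture()
  res <- cox_univariate(rep(3, nrow(surv)), surv)
  expect_identical(res$flag, "constant")
  expect_equal(res$p_value, 1)
  expect_equal(res$hazard_ratio, 1)
})

test_that("a strongly planted unfavorable gene gets a positive coefficient", {
  hits_pos <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 120
    x <- rnorm(n)
    time <- rexp(n, rate = 0.05 * exp(0.5 * x))
    cens <- rexp(n, rate = 0.03)
    surv <- tibble::tibble(
      sample_id = sprintf("S%03d", 1:n),
      time = pmin(time, cens), event = as.integer(time <= cens)
    )
    cox_univariate(x, surv)$coefficient > 0
  }, logical(1))
  expect_gte(mean(hits_pos), 0.95)
})

test_that("screen enforces the sign convention on every gene", {
  sim <- sim_small_null(11)
  scr <- screen_genes(sim$expression, sim$survival, alpha = 1)
  ok <- scr$flag == "ok"
  expect_true(all(scr$hit[ok])) # alpha = 1 retains all convergent genes
  expect_true(all((scr$direction[ok] == "favorable") ==
                    (scr$coefficient[ok] < 0)))
  expect_true(all((scr$hazard_ratio[ok] < 1) == (scr$coefficient[ok] < 0)))
  expect_equal(scr$hazard_ratio[ok], exp(scr$coefficient[ok]))
})

test_that("screen rejects a sample mismatch and names the offender", {
  sim <- sim_small_null(12)
  surv_bad <- sim$survival
  surv_bad$sample_id[1] <- "NOT_A_SAMPLE"
  expect_error(screen_genes(sim$expression, surv_bad), "NOT_A_SAMPLE")
})

test_that("confounder filter removes covariate-associated genes and is order-independent", {
  cfg <- tumor_sim_config(n_samples = 100, n_genes = 80, n_favorable = 10,
                          n_unfavorable = 10, n_confounded = 20, seed = 21)
  sim <- simulate_tumor_cohort(cfg)
  scr <- suppressWarnings(screen_genes(sim$expression, sim$survival, alpha = 1))
  sub <- dplyr::filter(
    tibble::as_tibble(scr),
    gene_id %in% c(sim$truth$confounded_genes, sim$truth$favorable_genes)
  )
  f_ab <- filter_confounders(sub, sim$expression, sim$survival,
                             binary_covariates = "tp53_mutant",
                             ordinal_covariates = "age")
  f_ba <- filter_confounders(sub, sim$expression, sim$survival,
                             binary_covariates = "tp53_mutant",
                             ordinal_covariates = "age")
  # removing by (tp53, age) and (age, tp53) keeps the same survivors
  f_swapped <- filter_confounders(
    filter_confounders(sub, sim$expression, sim$survival,
                       binary_covariates = character(0),
                       ordinal_covariates = "age"),
    sim$expression, sim$survival,
    binary_covariates = "tp53_mutant", ordinal_covariates = character(0)
  )
  expect_setequal(f_ab$gene_id, f_ba$gene_id)
  expect_setequal(f_ab$gene_id, f_swapped$gene_id)
  removed <- attr(f_ab, "removed")$gene_id
  expect_gte(mean(sim$truth$confounded_genes %in% removed), 0.9)
})

test_that("confounder filter handles empty hit lists and single-level covariates", {
  sim <- sim_small_null(13)
  scr <- screen_genes(sim$expression, sim$survival)
  empty <- dplyr::filter(tibble::as_tibble(scr), FALSE)
  out <- filter_confounders(empty, sim$expression, sim$survival)
  expect_equal(nrow(out), 0)

  surv1 <- sim$survival
  surv1$tp53_mutant <- 0
  hits <- head(tibble::as_tibble(scr), 5)
  expect_warning(
    filter_confounders(hits, sim$expression, surv1,
                       binary_covariates = "tp53_mutant",
                       ordinal_covariates = "age"),
    "single level"
  )
})

test_that("null-covariate removal fraction matches the per-test alpha", {
  # covariates independent of expression: expected removal ~ 1 - 0.95^k
  removed_frac <- vapply(1:6, function(s) {
    sim <- sim_small_null(400 + s, n = 80, g = 100)
    scr <- suppressWarnings(screen_genes(sim$expression, sim$survival, alpha = 1))
    filt <- filter_confounders(tibble::as_tibble(scr), sim$expression,
                               sim$survival,
                               binary_covariates = "tp53_mutant",
                               ordinal_covariates = c("stage", "age"))
    nrow(attr(filt, "removed")) / nrow(scr)
  }, numeric(1))
  expect_lt(abs(mean(removed_frac) - (1 - 0.95^3)), 0.06)
})
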
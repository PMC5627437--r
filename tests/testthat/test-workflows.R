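small_planted_cohort <- function(seed = 51) {
  cfg <- tumor_sim_config(n_samples = 120, n_genes = 200, n_favorable = 15,
                          n_unfavorable = 15, n_confounded = 10, seed = seed)
  simulate_tumor_cohort(cfg)
}

test_that("tumor workflow reports a monotone gene funnel and is reproducible", {
  sim <- small_planted_cohort()
  wf1 <- suppressWarnings(run_tumor_workflow(sim$expression, sim$survival,
                                             n_folds = 0, seed = 4))
  wf2 <- suppressWarnings(run_tumor_workflow(sim$expression, sim$survival,
                                             n_folds = 0, seed = 4))
  expect_true(all(diff(wf1$manifest$n_genes) <= 0))
  expect_identical(wf1$manifest, wf2$manifest)
  expect_identical(wf1$config_hash, wf2$config_hash)
  expect_identical(tibble::as_tibble(wf1$groups), tibble::as_tibble(wf2$groups))
  g <- glance(wf1)
  expect_equal(g$n_signature, nrow(wf1$signature))
})

test_that("restricting the signature to a gene subset re-stratifies", {
  sim <- small_planted_cohort(52)
  wf <- suppressWarnings(run_tumor_workflow(sim$expression, sim$survival,
                                            n_folds = 0, seed = 4))
  subset_genes <- wf$signature$gene_id[1:10]
  wf_sub <- suppressWarnings(run_tumor_workflow(
    sim$expression, sim$survival, restrict_genes = subset_genes,
    n_folds = 0, seed = 4
  ))
  expect_lte(nrow(wf_sub$signature), 10)
  expect_true(!is.null(wf_sub$comparison))
  expect_true(all(wf_sub$signature$gene_id %in% subset_genes))
})

test_that("tumor workflow writes the artifact set with a manifest", {
  sim <- small_planted_cohort(53)
  gmt <- gene_set_collection(
    list(planted_fav = sim$truth$favorable_genes,
         planted_unf = sim$truth$unfavorable_genes),
    universe = rownames(sim$expression)
  )
  out_dir <- withr::local_tempdir()
  wf <- suppressWarnings(run_tumor_workflow(sim$expression, sim$survival,
                                            gene_sets = gmt, n_folds = 3,
                                            seed = 4, out_dir = out_dir))
  expect_true(all(file.exists(file.path(out_dir, c(
    "screen.tsv", "signature.tsv", "favorability.tsv", "favorability.json",
    "subgroups.tsv", "km_coordinates.tsv", "cv_folds.tsv", "manifest.json"
  )))))
  man <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  expect_identical(man$config_hash, wf$config_hash)
})

test_that("raw-count input exercises the low-count filter in the funnel", {
  cfg <- tumor_sim_config(n_samples = 60, n_genes = 120, n_favorable = 10,
                          n_unfavorable = 10, n_confounded = 0,
                          scale = "raw_count", n_low_count = 20, seed = 54)
  sim <- simulate_tumor_cohort(cfg)
  wf <- suppressWarnings(run_tumor_workflow(sim$expression, sim$survival,
                                            n_folds = 0, seed = 1))
  funnel <- setNames(wf$manifest$n_genes, wf$manifest$stage)
  expect_lte(funnel[["low_count_filter"]], funnel[["input"]] - 20)
})

test_that("cell-line workflow terminates gracefully on a zero-gene signature", {
  sim <- simulate_cellline_panel(n_lines = 20, n_genes = 50, n_signal = 0,
                                 seed = 55)
  wf <- suppressWarnings(run_cellline_workflow(sim$expression, sim$panel,
                                               "5-FU", min_tau = 1.05))
  expect_equal(nrow(wf$hits), 0)
  expect_null(wf$comparison)
  expect_equal(wf$manifest$n_genes[3], 0)
})

test_that("phenotype workflow emits one correlation table per trait", {
  panel <- simulate_phenotype_panel(n_lines = 30, seed = 56)
  out_dir <- withr::local_tempdir()
  wf1 <- run_phenotype_workflow(panel, out_dir = out_dir)
  expect_named(wf1$correlations, c("kp", "volume", "kg"))
  for (tr in names(wf1$correlations)) {
    expect_s3_class(wf1$correlations[[tr]], "correlation_records")
    expect_true(file.exists(file.path(out_dir,
                                      sprintf("correlations_%s.tsv", tr))))
  }
  expect_true(file.exists(file.path(out_dir, "drug_tree.nwk")))
  wf2 <- run_phenotype_workflow(panel)
  expect_identical(tibble::as_tibble(wf1$core), tibble::as_tibble(wf2$core))
})
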
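test_that("growth rate satisfies the doubling-time identity", {
  expect_equal(growth_rate(2, log(2)), 2)
  expect_equal(growth_rate(1, 0.6931), 1, tolerance = 1e-4)
  # homogeneity in volume
  expect_equal(growth_rate(3 * 1.7, 0.4), 3 * growth_rate(1.7, 0.4))
  expect_error(growth_rate(-1, 1), "positive")
  expect_error(growth_rate(1, 0), "positive")
})

test_that("growth rate agrees with a forward simulation of linear growth", {
  # grow volume linearly at kg from V0; division at 2 V0; the inter-division
  # time must equal ln 2 / kp
  for (case in list(c(V0 = 2000, kp = 0.5), c(V0 = 1500, kp = 1.2))) {
    V0 <- case[["V0"]]; kp <- case[["kp"]]
    kg <- growth_rate(V0, kp)
    dt <- 1e-6
    v <- V0
    t <- 0
    while (v < 2 * V0) {
      v <- v + kg * dt
      t <- t + dt
    }
    expect_equal(t, log(2) / kp, tolerance = 1e-4)
    # closed form: time to double is exactly V0 / kg
    expect_equal(V0 / kg, log(2) / kp, tolerance = 1e-9)
  }
})

test_that("a trait that is a monotone transform of sensitivity has rho 1", {
  panel <- simulate_phenotype_panel(n_lines = 20, n_drugs = 3, seed = 5)
  ic <- panel_ic50(panel, panel$ic50$drug_id[1])
  ph <- panel$phenotypes
  ph$oracle_trait <- exp(-log10(ic[ph$line_id])) # monotone in -log10(IC-50)
  panel2 <- dose_response_panel(panel$ic50, ph)
  rec <- correlate_sensitivity(panel2, "oracle_trait", min_pairs = 10)
  expect_equal(rec$rho[rec$drug == panel$ic50$drug_id[1]], 1)
})

test_that("BH q-values match the step-up definition", {
  set.seed(17)
  panel <- simulate_phenotype_panel(n_lines = 30, seed = 17)
  rec <- correlate_sensitivity(panel, "kp")
  expect_equal(rec$q_value, brute_bh(rec$p_value), tolerance = 1e-12)
  core <- core_vs_sensitivity(panel)
  expect_equal(core$q_value, brute_bh(core$p_value), tolerance = 1e-12)
})

test_that("CORE analysis skips constant metabolites and finds the planted sign", {
  panel <- simulate_phenotype_panel(n_lines = 60, seed = 21)
  tr <- attr(panel, "truth")
  ph <- panel$phenotypes
  ph$core_flat <- 1
  panel2 <- dose_response_panel(panel$ic50, ph)
  expect_warning(core <- core_vs_sensitivity(panel2), "constant")
  expect_false("core_flat" %in% core$trait)
  tgt <- core[core$trait == tr$core_target_metabolite &
                core$drug %in% tr$core_target_drugs, ]
  # planted release-associated resistance: negative rho vs sensitivity
  expect_true(all(tgt$rho < 0))
  expect_gte(mean(tgt$significant), 0.8)
})

test_that("drug similarity is symmetric with unit diagonal and order-invariant", {
  panel <- simulate_phenotype_panel(n_lines = 40, seed = 23)
  ds <- drug_similarity(panel)
  r <- ds$similarity
  expect_equal(unname(diag(r)), rep(1, ncol(r)))
  expect_equal(r, t(r), tolerance = 1e-12)

  shuffled <- dose_response_panel(
    dplyr::arrange(panel$ic50, dplyr::desc(drug_id), line_id),
    panel$phenotypes
  )
  ds2 <- drug_similarity(shuffled)
  fam1 <- cut_drug_families(ds, 3)
  fam2 <- cut_drug_families(ds2, 3)
  expect_equal(adjusted_rand_index(fam1[names(fam2)], fam2), 1)
})

test_that("identical drugs correlate perfectly and merge first", {
  set.seed(25)
  lines <- sprintf("L%02d", 1:12)
  base <- 10^rnorm(12)
  ic50 <- dplyr::bind_rows(
    tibble::tibble(line_id = lines, drug_id = "twin_a", ic50 = base),
    tibble::tibble(line_id = lines, drug_id = "twin_b", ic50 = base),
    tibble::tibble(line_id = lines, drug_id = "other", ic50 = 10^rnorm(12))
  )
  ds <- drug_similarity(dose_response_panel(ic50))
  expect_equal(ds$similarity["twin_a", "twin_b"], 1)
  first_merge <- ds$tree$labels[-ds$tree$merge[1, ]]
  expect_setequal(first_merge, c("twin_a", "twin_b"))

  flat <- dplyr::bind_rows(
    ic50, tibble::tibble(line_id = lines, drug_id = "flat", ic50 = 2)
  )
  expect_warning(drug_similarity(dose_response_panel(flat)), "zero-variance")
})

test_that("the dendrogram exports as Newick readable by ape", {
  panel <- simulate_phenotype_panel(n_lines = 30, n_drugs = 6, seed = 27)
  ds <- drug_similarity(panel)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_drug_tree_newick(ds, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, colnames(ds$similarity))
})
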
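#' Configuration for a synthetic tumor cohort
#'
#' Defines a cohort with known planted structure: two coherent expression
#' "programs" (one favorable, one unfavorable for progression-free survival),
#' a block of confounder-associated genes with no direct hazard effect, and
#' exponential event/censoring times under a proportional-hazards model.
#'
#' Planted genes load on a shared latent program factor per direction
#' (`program_cor` is the fraction of each planted gene's variance explained
#' by its program), which reproduces the coherent favorable/unfavorable gene
#' blocks seen in real favorability heatmaps and gives each planted gene a
#' detectable marginal association with survival.
#'
#' @param n_samples,n_genes Cohort and transcriptome size.
#' @param n_favorable,n_unfavorable Planted genes whose program lowers /
#'   raises the hazard.
#' @param n_confounded Genes with a mean shift of `confound_shift` SD between
#'   levels of the binary `tp53_mutant` covariate and no hazard effect.
#' @param effect_log_hazard Per-sample log-hazard contributed per unit of the
#'   normalized planted-program contrast (see details in the vignette).
#' @param baseline_hazard Exponential event rate (events per day) at zero
#'   planted risk. Must be > 0.
#' @param censoring_rate Independent exponential censoring rate (> 0); the
#'   expected censoring fraction under the null is
#'   `censoring_rate / (censoring_rate + baseline_hazard)`.
#' @param program_cor Variance fraction each planted gene shares with its
#'   program factor, in \[0, 1).
#' @param program_anticor Anti-correlation between the favorable and
#'   unfavorable programs within a sample, in \[0, 1): the two program
#'   factors share a common response axis with opposite signs and
#'   correlation `-program_anticor`. This mirrors the observed structure in
#'   which samples enriched for favorable scores are depleted for
#'   unfavorable ones.
#' @param confound_shift Mean shift (in gene SD units) between covariate
#'   levels for confounded genes; at least 1 by default.
#' @param covariates Named character vector of clinical covariate types
#'   (`"binary"`, `"ordinal"`, `"continuous"`); the first binary covariate is
#'   the designated confounder.
#' @param scale Output scale; `"raw_count"` additionally plants
#'   `n_low_count` near-zero-count genes to exercise the low-count filter.
#' @param n_low_count Number of low-count genes in raw-count mode.
#' @param seed Integer seed; generation is a pure function of config + seed.
#' @return A list of class `"tumor_sim_config"`.
#' @export
tumor_sim_config <- function(n_samples = 200, n_genes = 1000,
                             n_favorable = 25, n_unfavorable = 25,
                             n_confounded = 25,
                             effect_log_hazard = 0.5,
                             baseline_hazard = 0.05,
                             censoring_rate = 0.03,
                             program_cor = 0.6,
                             program_anticor = 0.5,
                             confound_shift = 1,
                             covariates = c(tp53_mutant = "binary",
                                            stage = "ordinal",
                                            age = "continuous",
                                            grade = "ordinal",
                                            nodal_status = "ordinal"),
                             scale = c("log2", "raw_count"),
                             n_low_count = 0,
                             seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_favorable <- check_count(n_favorable, "n_favorable")
  n_unfavorable <- check_count(n_unfavorable, "n_unfavorable")
  n_confounded <- check_count(n_confounded, "n_confounded")
  n_low_count <- check_count(n_low_count, "n_low_count")
  if (n_favorable + n_unfavorable + n_confounded + n_low_count > n_genes) {
    abort("planted gene counts exceed n_genes")
  }
  if (!is.finite(effect_log_hazard)) abort("effect_log_hazard must be finite")
  if (baseline_hazard <= 0 || censoring_rate <= 0) {
    abort("baseline_hazard and censoring_rate must be > 0")
  }
  if (program_cor < 0 || program_cor >= 1) abort("program_cor must be in [0, 1)")
  if (program_anticor < 0 || program_anticor >= 1) {
    abort("program_anticor must be in [0, 1)")
  }
  scale <- match.arg(scale)
  if (!any(covariates == "binary")) abort("at least one binary covariate required")
  structure(
    list(
      n_samples = n_samples, n_genes = n_genes,
      n_favorable = n_favorable, n_unfavorable = n_unfavorable,
      n_confounded = n_confounded, effect_log_hazard = effect_log_hazard,
      baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
      program_cor = program_cor, program_anticor = program_anticor,
      confound_shift = confound_shift,
      covariates = covariates, scale = scale, n_low_count = n_low_count,
      seed = as.integer(seed)
    ),
    class = "tumor_sim_config"
  )
}

#' Simulate a tumor cohort with planted survival signal
#'
#' Expression is Gaussian on the log2 scale; planted favorable/unfavorable
#' genes load on a shared program factor per direction. The per-sample
#' log-hazard is
#' `effect_log_hazard * (sum z_unfavorable - sum z_favorable) / sqrt(n_planted)`
#' over standardized planted-gene expression, event times are exponential
#' under proportional hazards, and censoring is independent exponential.
#' Confounded genes get a mean shift between levels of the designated binary
#' covariate and no hazard effect.
#'
#' @param config A [tumor_sim_config()].
#' @return A list with `expression` ([expression_matrix()]), `survival`
#'   (tibble: `sample_id`, `time`, `event`, covariates), and `truth` (list:
#'   `favorable_genes`, `unfavorable_genes`, `confounded_genes`,
#'   `low_count_genes`, `per_sample_risk`, `planted_subgroup`).
#' @export
simulate_tumor_cohort <- function(config) {
  stopifnot(inherits(config, "tumor_sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  g <- config$n_genes
  sample_ids <- sprintf("S%03d", seq_len(n))
  gene_ids <- sprintf("G%05d", seq_len(g))

  # covariates
  cov_df <- purrr::imap(config$covariates, function(type, nm) {
    switch(type,
      binary = rbinom(n, 1, 0.4),
      ordinal = sample(1:4, n, replace = TRUE),
      continuous = rnorm(n, 65, 10),
      abort(sprintf("unknown covariate type '%s'", type))
    )
  })
  cov_df <- tibble::as_tibble(cov_df)
  confounder <- cov_df[[names(config$covariates)[config$covariates == "binary"][1]]]

  # gene role assignment: leading blocks, then null genes
  idx <- seq_len(g)
  fav_idx <- idx[seq_len(config$n_favorable)]
  unf_idx <- idx[config$n_favorable + seq_len(config$n_unfavorable)]
  conf_idx <- idx[config$n_favorable + config$n_unfavorable + seq_len(config$n_confounded)]
  low_idx <- idx[config$n_favorable + config$n_unfavorable + config$n_confounded +
                   seq_len(config$n_low_count)]

  # standardized expression: planted genes share a program factor
  z <- matrix(rnorm(g * n), nrow = g, dimnames = list(gene_ids, sample_ids))
  a <- sqrt(config$program_cor)
  q <- config$program_anticor
  v <- rnorm(n) # shared response axis
  u_fav <- -sqrt(q) * v + sqrt(1 - q) * rnorm(n)
  u_unf <- sqrt(q) * v + sqrt(1 - q) * rnorm(n)
  if (length(fav_idx)) {
    z[fav_idx, ] <- a * matrix(u_fav, length(fav_idx), n, byrow = TRUE) +
      sqrt(1 - a^2) * z[fav_idx, , drop = FALSE]
  }
  if (length(unf_idx)) {
    z[unf_idx, ] <- a * matrix(u_unf, length(unf_idx), n, byrow = TRUE) +
      sqrt(1 - a^2) * z[unf_idx, , drop = FALSE]
  }
  if (length(conf_idx)) {
    shift <- config$confound_shift * matrix(confounder, length(conf_idx), n, byrow = TRUE)
    z[conf_idx, ] <- z[conf_idx, , drop = FALSE] + shift
  }

  # planted per-sample risk
  n_planted <- length(fav_idx) + length(unf_idx)
  if (n_planted > 0) {
    risk <- config$effect_log_hazard *
      (colSums(z[unf_idx, , drop = FALSE]) - colSums(z[fav_idx, , drop = FALSE])) /
      sqrt(n_planted)
  } else {
    risk <- rep(0, n)
  }

  event_time <- rexp(n, rate = config$baseline_hazard * exp(risk))
  cens_time <- rexp(n, rate = config$censoring_rate)
  time <- pmin(event_time, cens_time)
  event <- as.integer(event_time <= cens_time)

  # dress standardized values up as log2 expression
  mu <- runif(g, 2, 10)
  sigma <- runif(g, 0.5, 2)
  vals <- mu + sigma * z
  if (config$scale == "raw_count") {
    vals <- matrix(
      rpois(g * n, lambda = pmax(2^vals - 1, 0)),
      nrow = g, dimnames = dimnames(z)
    )
    if (length(low_idx)) {
      vals[low_idx, ] <- rpois(length(low_idx) * n, 0.3)
    }
    vals <- vals * 1.0 # numeric storage
  }

  surv <- dplyr::bind_cols(
    tibble(sample_id = sample_ids, time = time, event = event),
    cov_df
  )
  truth <- list(
    favorable_genes = gene_ids[fav_idx],
    unfavorable_genes = gene_ids[unf_idx],
    confounded_genes = gene_ids[conf_idx],
    low_count_genes = gene_ids[low_idx],
    per_sample_risk = setNames(risk, sample_ids),
    planted_subgroup = setNames(
      ifelse(risk > median(risk), "high_risk", "low_risk"), sample_ids
    )
  )
  list(
    expression = expression_matrix(vals, scale = config$scale),
    survival = surv,
    truth = truth
  )
}

#' Simulate a cell-line panel with expression-IC-50 signal
#'
#' Log IC-50 for one drug is standard Gaussian across lines; each signal
#' gene's standardized expression is correlated with log IC-50 through a
#' Gaussian copula calibrated so the population Kendall tau equals
#' `target_tau` (correlation `sin(pi * tau / 2)`), with the sign split evenly
#' between resistance-associated (positive tau) and sensitivity-associated
#' (negative tau) genes. Null genes are independent of IC-50.
#'
#' @param n_lines Number of cell lines (>= 5).
#' @param n_genes Number of genes.
#' @param n_signal Number of signal genes (<= n_genes).
#' @param target_tau Target absolute Kendall tau, |tau| < 1.
#' @param drug Drug name used in the returned panel.
#' @param seed Integer seed.
#' @return A list with `expression` ([expression_matrix()]), `panel`
#'   (a [dose_response_panel()] with one drug), and `truth` (signal gene ids
#'   and signs, +1 = resistance-associated).
#' @export
simulate_cellline_panel <- function(n_lines = 44, n_genes = 1000, n_signal = 50,
                                    target_tau = 0.4, drug = "5-FU", seed = 1L) {
  n_lines <- check_count(n_lines, "n_lines", min = 5L)
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_signal <- check_count(n_signal, "n_signal")
  if (n_signal > n_genes) abort("n_signal must be <= n_genes")
  if (abs(target_tau) >= 1) abort("|target_tau| must be < 1")
  set.seed(as.integer(seed))

  line_ids <- sprintf("CL%03d", seq_len(n_lines))
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  z_ic <- rnorm(n_lines)
  r <- sin(pi * target_tau / 2)

  z <- matrix(rnorm(n_genes * n_lines), nrow = n_genes,
              dimnames = list(gene_ids, line_ids))
  signs <- integer(0)
  if (n_signal > 0) {
    signs <- rep(c(1L, -1L), length.out = n_signal)
    sig_idx <- seq_len(n_signal)
    z[sig_idx, ] <- signs * r * matrix(z_ic, n_signal, n_lines, byrow = TRUE) +
      sqrt(1 - r^2) * z[sig_idx, , drop = FALSE]
  }
  mu <- runif(n_genes, 4, 10)
  sigma <- runif(n_genes, 0.5, 1.5)
  vals <- mu + sigma * z

  ic50 <- tibble(
    line_id = line_ids,
    drug_id = drug,
    ic50 = 10^(z_ic) # micromolar, log10-normal
  )
  truth <- list(
    signal_genes = gene_ids[seq_len(n_signal)],
    signs = setNames(signs, gene_ids[seq_len(n_signal)]),
    target_tau = target_tau
  )
  list(
    expression = expression_matrix(vals, scale = "log2"),
    panel = dose_response_panel(ic50),
    truth = truth
  )
}

#' Simulate an NCI-60-like phenotype panel
#'
#' Generates per-line cell volume (fL) and proliferation rate (1/day) with a
#' planted negative rank correlation between them, and per-(line, drug)
#' IC-50 values whose sensitivity `-log10(IC-50)` is positively rank-
#' correlated with proliferation rate, negatively with volume, and
#' uncorrelated with the volume-corrected growth rate
#' `kg = V0 * kp / ln 2` (the sensitivity latent is proportional to the
#' difference of the volume and proliferation latents, which is orthogonal
#' to their sum). Drugs belong to three planted mechanism families sharing a
#' family factor, so pairwise IC-50 correlations are higher within families.
#' Two metabolite consumption/release (CORE) columns are included:
#' phosphocholine release negatively correlated with sensitivity to the
#' drugs of one designated family, and a null 2-deoxycytidine column.
#'
#' @param n_lines Number of cell lines (>= 10).
#' @param n_drugs Number of drugs (default 17, named after antimetabolite
#'   agents; generic names beyond 17).
#' @param vol_kp_cor Latent correlation between log volume and log
#'   proliferation rate (negative).
#' @param seed Integer seed.
#' @return A [dose_response_panel()] with an attached `"truth"` attribute
#'   (drug families, CORE target drugs).
#' @export
simulate_phenotype_panel <- function(n_lines = 60, n_drugs = 17,
                                     vol_kp_cor = -0.6, seed = 1L) {
  n_lines <- check_count(n_lines, "n_lines", min = 10L)
  n_drugs <- check_count(n_drugs, "n_drugs", min = 3L)
  if (vol_kp_cor <= -1 || vol_kp_cor >= 1) abort("vol_kp_cor must be in (-1, 1)")
  set.seed(as.integer(seed))

  line_ids <- sprintf("CL%03d", seq_len(n_lines))
  drug_names <- c(
    "Gemcitabine", "Methotrexate", "Pemetrexed", "Thioguanine", "Thiopurine",
    "Fluorouracil", "5-FUDR", "Hydroxyurea", "Ara-C", "Azacytidine",
    "Cladribine", "Decitabine", "Pentostatin", "Cytarabine",
    "Fludarabine phosphate", "Clofarabine", "Capecitabine"
  )
  drug_ids <- if (n_drugs <= length(drug_names)) drug_names[seq_len(n_drugs)] else
    c(drug_names, sprintf("Drug%02d", seq_len(n_drugs - length(drug_names))))

  # latent volume (a) and proliferation (b) with negative correlation
  a <- rnorm(n_lines)
  b <- vol_kp_cor * a + sqrt(1 - vol_kp_cor^2) * rnorm(n_lines)
  volume <- exp(log(2000) + 0.35 * a)      # fL
  kp <- exp(log(0.5) + 0.35 * b)           # 1/day

  # sensitivity latent orthogonal to a + b (hence to log growth rate)
  s_perp <- (b - a) / sqrt(2 - 2 * vol_kp_cor)
  families <- sort(rep(1:3, length.out = n_drugs))
  fam_factor <- matrix(rnorm(n_lines * 3), n_lines, 3)
  sens <- vapply(seq_len(n_drugs), function(d) {
    0.55 * s_perp + 0.65 * fam_factor[, families[d]] + 0.35 * rnorm(n_lines)
  }, numeric(n_lines))
  colnames(sens) <- drug_ids

  ic50 <- tidyr::pivot_longer(
    tibble::as_tibble(10^(-sens)) |> dplyr::mutate(line_id = line_ids),
    -"line_id", names_to = "drug_id", values_to = "ic50"
  )

  # CORE: phosphocholine release anti-correlated with family-2 sensitivity
  core_target <- drug_ids[families == 2]
  lambda <- 0.7
  core_pc <- -(lambda * fam_factor[, 2] + sqrt(1 - lambda^2) * rnorm(n_lines))
  core_dc <- rnorm(n_lines)

  phenotypes <- tibble(
    line_id = line_ids,
    volume = volume,
    kp = kp,
    core_phosphocholine = core_pc,
    core_2_deoxycytidine = core_dc
  )
  panel <- dose_response_panel(ic50, phenotypes)
  attr(panel, "truth") <- list(
    drug_families = setNames(families, drug_ids),
    core_target_drugs = core_target,
    core_target_metabolite = "core_phosphocholine"
  )
  panel
}
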
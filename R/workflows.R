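#' Tumor-survival signature workflow
#'
#' Runs the full tumor branch on one cohort: low-count filter and log2
#' normalization (raw-count input only), genome-wide proportional-hazards
#' screen, clinical-confounder filter, favorability scoring, k-means
#' stratification, subgroup survival comparison, optional cross-validation,
#' and optional Fisher enrichment of the favorable and unfavorable
#' signatures run separately. A manifest records the gene count surviving
#' each stage (a monotone non-increasing funnel) and a hash of the
#' configuration; with `out_dir` set, every artifact is written as TSV plus
#' a JSON manifest.
#'
#' @param m An [expression_matrix()] (raw counts or log2).
#' @param surv Survival table.
#' @param gene_sets Optional `"gene_set_collection"` for enrichment.
#' @param restrict_genes Optional gene identifiers (e.g. a metabolic gene
#'   list); the signature is intersected with it before scoring and
#'   stratification is re-run on the restricted signature.
#' @param alpha_screen,alpha_confounder Raw p thresholds (defaults 0.05).
#' @param binary_covariates,ordinal_covariates Confounder columns; `NULL`
#'   disables that part of the filter.
#' @param mode Favorability mode (default `"gene_direction"`).
#' @param k,n_restarts Clustering parameters.
#' @param n_folds Cross-validation folds; `0` skips CV.
#' @param seed Integer seed for clustering and fold assignment.
#' @param out_dir Optional output directory for artifacts.
#' @return List of class `"tumor_workflow"`: `screen`, `hits`, `filtered`,
#'   `favorability`, `groups`, `comparison`, `cv`, `enrichment` (list with
#'   `favorable`/`unfavorable` or NULL), `manifest`, `config`,
#'   `config_hash`.
#' @export
run_tumor_workflow <- function(m, surv, gene_sets = NULL,
                               restrict_genes = NULL,
                               alpha_screen = 0.05, alpha_confounder = 0.05,
                               binary_covariates = "tp53_mutant",
                               ordinal_covariates = c("stage", "age", "grade",
                                                      "nodal_status"),
                               mode = c("gene_direction", "sample_class"),
                               k = 2, n_restarts = 50, n_folds = 5,
                               seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  config <- list(
    workflow = "tumor", alpha_screen = alpha_screen,
    alpha_confounder = alpha_confounder,
    binary_covariates = binary_covariates,
    ordinal_covariates = ordinal_covariates, mode = mode, k = k,
    n_restarts = n_restarts, n_folds = n_folds, seed = as.integer(seed),
    restrict_genes = restrict_genes
  )
  config_hash <- rlang::hash(config)
  surv <- validate_survival(surv)

  n_input <- nrow(m)
  if (expr_scale(m) == "raw_count") {
    m <- suppressWarnings(filter_low_count(m))
    m <- log2_normalize(m)
  }
  n_after_low <- nrow(m)

  screen <- suppressWarnings(screen_genes(m, surv, alpha = alpha_screen))
  hits <- screen_hits(screen)
  filtered <- if (!is.null(binary_covariates) || !is.null(ordinal_covariates)) {
    suppressWarnings(filter_confounders(
      hits, m, surv,
      binary_covariates = binary_covariates %||% character(0),
      ordinal_covariates = ordinal_covariates %||% character(0),
      alpha = alpha_confounder
    ))
  } else hits
  signature <- filtered
  if (!is.null(restrict_genes)) {
    signature <- dplyr::filter(as_tibble(signature),
                               .data$gene_id %in% restrict_genes)
  }
  if (nrow(signature) < 2) {
    abort(sprintf(
      "stage 'signature': only %d gene(s) survive; cannot stratify",
      nrow(signature)
    ))
  }

  classing <- class_samples_survival(surv, mode = if (mode == "sample_class")
    "patient_class" else "gene_direction")
  Fm <- score_matrix(m, screen = signature,
                     classing = if (mode == "sample_class") classing else NULL,
                     mode = mode, anchor = "survival")
  groups <- cluster_subgroups(Fm, k = k, n_restarts = n_restarts, seed = seed)
  comparison <- if (!isTRUE(attr(groups, "degenerate")) &&
                    dplyr::n_distinct(groups$group) == 2) {
    suppressWarnings(compare_subgroup_survival(groups, surv))
  } else NULL

  cv <- if (n_folds >= 2) {
    tryCatch(
      suppressWarnings(cross_validate(
        m, surv, n_folds = n_folds, seed = seed, alpha = alpha_screen,
        binary_covariates = binary_covariates,
        ordinal_covariates = ordinal_covariates, k = k,
        n_restarts = max(10, n_restarts %/% 2)
      )),
      error = function(e) {
        warn(paste0("cross-validation failed: ", conditionMessage(e)))
        NULL
      }
    )
  } else NULL

  enrichment <- NULL
  if (!is.null(gene_sets)) {
    sig <- as_tibble(signature)
    enrichment <- list(
      favorable = tryCatch(
        fisher_enrichment(sig$gene_id[sig$direction == "favorable"], gene_sets),
        error = function(e) NULL),
      unfavorable = tryCatch(
        fisher_enrichment(sig$gene_id[sig$direction == "unfavorable"], gene_sets),
        error = function(e) NULL)
    )
  }

  manifest <- tibble(
    stage = c("input", "low_count_filter", "survival_screen",
              "confounder_filter", "signature"),
    n_genes = c(n_input, n_after_low, nrow(hits), nrow(filtered),
                nrow(signature))
  )
  out <- structure(
    list(screen = screen, hits = hits, filtered = filtered,
         signature = signature, favorability = Fm, groups = groups,
         comparison = comparison, cv = cv, enrichment = enrichment,
         manifest = manifest, config = config, config_hash = config_hash),
    class = "tumor_workflow"
  )
  if (!is.null(out_dir)) write_tumor_artifacts(out, out_dir)
  out
}

write_tumor_artifacts <- function(wf, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(as_tibble(wf$screen), file.path(out_dir, "screen.tsv"))
  readr::write_tsv(as_tibble(wf$signature), file.path(out_dir, "signature.tsv"))
  write_favorability_tsv(wf$favorability, file.path(out_dir, "favorability"))
  readr::write_tsv(as_tibble(wf$groups), file.path(out_dir, "subgroups.tsv"))
  if (!is.null(wf$comparison) && !is.null(wf$comparison$km)) {
    readr::write_tsv(wf$comparison$km, file.path(out_dir, "km_coordinates.tsv"))
  }
  if (!is.null(wf$cv)) {
    readr::write_tsv(as_tibble(wf$cv), file.path(out_dir, "cv_folds.tsv"))
  }
  if (!is.null(wf$enrichment)) {
    for (side in names(wf$enrichment)) {
      er <- wf$enrichment[[side]]
      if (!is.null(er)) {
        er2 <- dplyr::mutate(
          as_tibble(er),
          overlapping_genes = purrr::map_chr(.data$overlapping_genes,
                                             paste, collapse = ";")
        )
        readr::write_tsv(er2, file.path(out_dir,
                                        sprintf("enrichment_%s.tsv", side)))
      }
    }
  }
  jsonlite::write_json(
    list(config = wf$config, config_hash = wf$config_hash,
         manifest = wf$manifest,
         comparison = if (is.null(wf$comparison)) NULL else
           list(p_value = wf$comparison$p_value,
                hazard_ratio = wf$comparison$hazard_ratio)),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(out_dir)
}

#' Cell-line sensitivity workflow
#'
#' Wraps [run_cellline_pipeline()] and adds optional enrichment of the
#' favorable/unfavorable signatures and artifact writing.
#'
#' @inheritParams run_cellline_pipeline
#' @param gene_sets Optional `"gene_set_collection"`.
#' @param out_dir Optional output directory.
#' @return List of class `"cellline_workflow"`: the pipeline fields plus
#'   `enrichment`, `config`, `config_hash`.
#' @export
run_cellline_workflow <- function(m, panel, drug, gene_sets = NULL,
                                  min_cv = 0.05, min_tau = 0.2, max_p = 0.01,
                                  mode = c("gene_direction", "sample_class"),
                                  k = 2, n_restarts = 50, seed = 1L,
                                  out_dir = NULL) {
  mode <- match.arg(mode)
  config <- list(workflow = "cellline", drug = drug, min_cv = min_cv,
                 min_tau = min_tau, max_p = max_p, mode = mode, k = k,
                 n_restarts = n_restarts, seed = as.integer(seed))
  pipe <- run_cellline_pipeline(m, panel, drug, min_cv = min_cv,
                                min_tau = min_tau, max_p = max_p, mode = mode,
                                k = k, n_restarts = n_restarts, seed = seed)
  enrichment <- NULL
  if (!is.null(gene_sets) && nrow(pipe$hits) > 0) {
    enrichment <- list(
      favorable = tryCatch(
        fisher_enrichment(pipe$hits$gene_id[pipe$hits$direction == "favorable"],
                          gene_sets), error = function(e) NULL),
      unfavorable = tryCatch(
        fisher_enrichment(pipe$hits$gene_id[pipe$hits$direction == "unfavorable"],
                          gene_sets), error = function(e) NULL)
    )
  }
  out <- structure(
    c(pipe, list(enrichment = enrichment, config = config,
                 config_hash = rlang::hash(config))),
    class = "cellline_workflow"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(as_tibble(pipe$screen), file.path(out_dir, "screen.tsv"))
    if (!is.null(pipe$favorability)) {
      write_favorability_tsv(pipe$favorability,
                             file.path(out_dir, "favorability"))
      readr::write_tsv(as_tibble(pipe$groups),
                       file.path(out_dir, "subgroups.tsv"))
    }
    jsonlite::write_json(
      list(config = config, config_hash = out$config_hash,
           manifest = pipe$manifest,
           comparison = if (is.null(pipe$comparison)) NULL else
             list(p_value = pipe$comparison$p_value,
                  median_log_ic50_diff = pipe$comparison$median_log_ic50_diff)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      null = "null"
    )
  }
  out
}

#' Phenotype-correlates workflow
#'
#' Computes per-line growth rates, correlates proliferation rate, cell
#' volume and growth rate with drug sensitivity, correlates CORE metabolite
#' profiles with sensitivity, and builds the drug-similarity matrix with
#' hierarchical clustering.
#'
#' @param panel A [dose_response_panel()] with `volume`, `kp`, and `core_*`
#'   phenotype columns.
#' @param out_dir Optional output directory (one correlation table per
#'   trait, CORE table, similarity TSV, Newick dendrogram).
#' @return List of class `"phenotype_workflow"`: `correlations` (named list
#'   of `"correlation_records"` for kp, volume, kg), `core`,
#'   `similarity` (a `"drug_similarity"`), `config_hash`.
#' @export
run_phenotype_workflow <- function(panel, out_dir = NULL) {
  stopifnot(inherits(panel, "dose_response_panel"))
  config <- list(workflow = "phenotype")
  correlations <- list(
    kp = correlate_sensitivity(panel, "kp"),
    volume = correlate_sensitivity(panel, "volume"),
    kg = correlate_sensitivity(panel, "kg")
  )
  core <- core_vs_sensitivity(panel)
  similarity <- drug_similarity(panel)
  out <- structure(
    list(correlations = correlations, core = core, similarity = similarity,
         config = config, config_hash = rlang::hash(config)),
    class = "phenotype_workflow"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tr in names(correlations)) {
      readr::write_tsv(as_tibble(correlations[[tr]]),
                       file.path(out_dir, sprintf("correlations_%s.tsv", tr)))
    }
    readr::write_tsv(as_tibble(core), file.path(out_dir, "core_correlations.tsv"))
    sim_df <- tibble::as_tibble(similarity$similarity, rownames = "drug_id")
    readr::write_tsv(sim_df, file.path(out_dir, "drug_similarity.tsv"))
    write_drug_tree_newick(similarity, file.path(out_dir, "drug_tree.nwk"))
  }
  out
}
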
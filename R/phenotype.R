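#' Volume-corrected growth rate
#'
#' Converts a proliferation rate constant into an overall growth rate (rate
#' of volume synthesis): assuming linear volume growth from the post-
#' division volume V0 to 2 V0 over one doubling time Td = ln 2 / kp, the
#' growth rate is kg = V0 * kp / ln 2 (units volume per time). The
#' correction removes the coupling between small cell size and fast
#' division when correlating proliferation with drug sensitivity.
#'
#' @param V0 Post-division cell volume (> 0), e.g. fL.
#' @param kp Proliferation rate constant (> 0), e.g. 1/day.
#' @return Growth rate, volume per time. Vectorized over lines.
#' @export
#' @examples
#' growth_rate(2, log(2)) # doubles V0 = 2 in unit time: kg = 2
growth_rate <- function(V0, kp) {
  if (any(!is.finite(V0)) || any(!is.finite(kp)) ||
      any(V0 <= 0) || any(kp <= 0)) {
    abort("V0 and kp must be positive and finite")
  }
  V0 * kp / log(2)
}

#' Correlate a cell phenotype with drug sensitivity
#'
#' Per drug, the Spearman correlation between a per-line trait (`"kp"`,
#' `"volume"`, the derived `"kg"` = [growth_rate()], or any phenotype
#' column) and sensitivity defined as -log10(IC-50). q-values are
#' Benjamini-Hochberg adjusted across the family of drugs for that trait;
#' the significance flag is q < 0.05. Drugs with fewer than `min_pairs`
#' complete pairs are skipped with a warning. Since Spearman correlation is
#' rank-based, the log base of the sensitivity transform is immaterial.
#'
#' @param panel A [dose_response_panel()] with phenotypes.
#' @param trait Phenotype column name, or `"kg"` to use the growth rate
#'   derived from `volume` and `kp`.
#' @param min_pairs Minimum complete pairs per drug (default 10).
#' @return Tibble of class `"correlation_records"`: `trait`, `drug`, `rho`,
#'   `p_value`, `q_value`, `n`, `significant`.
#' @export
correlate_sensitivity <- function(panel, trait, min_pairs = 10) {
  stopifnot(inherits(panel, "dose_response_panel"))
  ph <- panel$phenotypes
  if (is.null(ph)) abort("panel has no phenotypes")
  tv <- if (trait == "kg" && !"kg" %in% names(ph)) {
    growth_rate(ph$volume, ph$kp)
  } else {
    if (!trait %in% names(ph)) abort(sprintf("trait '%s' not in phenotypes", trait))
    ph[[trait]]
  }
  names(tv) <- ph$line_id
  drugs <- unique(panel$ic50$drug_id)
  rows <- purrr::map(drugs, function(d) {
    ic <- panel_ic50(panel, d)
    lines <- intersect(names(ic), names(tv))
    x <- tv[lines]
    y <- -log10(ic[lines])
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_pairs) {
      warn(sprintf("drug '%s' skipped: fewer than %d complete pairs", d, min_pairs))
      return(NULL)
    }
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
    tibble(trait = trait, drug = d, rho = unname(ct$estimate),
           p_value = ct$p.value, n = sum(ok))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("no drug had enough complete pairs")
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < 0.05
  structure(out[, c("trait", "drug", "rho", "p_value", "q_value", "n",
                    "significant")],
            class = c("correlation_records", class(out)))
}

#' Correlate metabolite consumption/release with drug sensitivity
#'
#' Spearman correlation between each CORE column (`core_*`, positive =
#' metabolite released, negative = consumed) and -log10(IC-50) for each
#' drug, with a single Benjamini-Hochberg adjustment across all
#' (metabolite, drug) pairs (switch to `within_metabolite` to adjust per
#' metabolite). Constant metabolites are skipped.
#'
#' @param panel A [dose_response_panel()] with `core_*` phenotype columns.
#' @param fdr_scope `"global"` (default) or `"within_metabolite"`.
#' @param min_pairs Minimum complete pairs (default 10).
#' @return A `"correlation_records"` tibble (trait = metabolite column).
#' @export
core_vs_sensitivity <- function(panel, fdr_scope = c("global",
                                                     "within_metabolite"),
                                min_pairs = 10) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(inherits(panel, "dose_response_panel"))
  ph <- panel$phenotypes
  mets <- grep("^core_", names(ph), value = TRUE)
  if (length(mets) == 0) abort("panel has no core_* metabolite columns")
  keep <- vapply(mets, function(mt) {
    v <- ph[[mt]]
    length(unique(v[is.finite(v)])) > 1
  }, logical(1))
  if (any(!keep)) {
    warn(sprintf("constant metabolite(s) skipped: %s",
                 paste(mets[!keep], collapse = ", ")))
  }
  mets <- mets[keep]
  out <- purrr::map_dfr(mets, function(mt) {
    res <- correlate_sensitivity(panel, trait = mt, min_pairs = min_pairs)
    res$q_value <- NULL
    res$significant <- NULL
    res
  })
  out$q_value <- if (fdr_scope == "global") {
    p.adjust(out$p_value, method = "BH")
  } else {
    stats::ave(out$p_value, out$trait,
               FUN = function(p) p.adjust(p, method = "BH"))
  }
  out$significant <- out$q_value < 0.05
  structure(out[, c("trait", "drug", "rho", "p_value", "q_value", "n",
                    "significant")],
            class = c("correlation_records", class(out)))
}

#' Pairwise drug-sensitivity similarity and clustering
#'
#' Symmetric matrix of pairwise Pearson correlations between drugs' IC-50
#' profiles across cell lines (pairwise-complete observations), followed by
#' hierarchical clustering on the distance 1 - r (average linkage by
#' default). Drugs with zero variance are excluded with a warning.
#'
#' @param panel A [dose_response_panel()] with >= 3 drugs.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param min_pairs Minimum pairwise-complete observations (default 10).
#' @return List of class `"drug_similarity"`: `similarity` (correlation
#'   matrix, unit diagonal), `tree` (hclust), `n_pairs` (matrix of pair
#'   counts), `leaf_order`.
#' @export
drug_similarity <- function(panel, linkage = "average", min_pairs = 10) {
  stopifnot(inherits(panel, "dose_response_panel"))
  m <- panel_ic50_matrix(panel)
  if (ncol(m) < 3) abort("need at least 3 drugs")
  vars <- apply(m, 2L, function(v) stats::var(v, na.rm = TRUE))
  if (any(is.na(vars) | vars == 0)) {
    warn(sprintf("zero-variance drug(s) excluded: %s",
                 paste(colnames(m)[is.na(vars) | vars == 0], collapse = ", ")))
    m <- m[, !(is.na(vars) | vars == 0), drop = FALSE]
  }
  npairs <- crossprod(!is.na(m))
  if (any(npairs < min_pairs)) {
    abort(sprintf("some drug pairs have fewer than %d complete observations",
                  min_pairs))
  }
  r <- cor(m, use = "pairwise.complete.obs", method = "pearson")
  tree <- hclust(as.dist(1 - r), method = linkage)
  structure(
    list(similarity = r, tree = tree, n_pairs = npairs,
         leaf_order = colnames(r)[tree$order]),
    class = "drug_similarity"
  )
}

#' Cut the drug dendrogram into families
#'
#' @param ds A `"drug_similarity"`.
#' @param k Number of families.
#' @return Named integer vector of family memberships.
#' @export
cut_drug_families <- function(ds, k = 3) {
  stopifnot(inherits(ds, "drug_similarity"))
  stats::cutree(ds$tree, k = k)
}

#' Write a drug dendrogram as Newick
#'
#' @param ds A `"drug_similarity"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_drug_tree_newick <- function(ds, path) {
  stopifnot(inherits(ds, "drug_similarity"))
  phy <- ape::as.phylo(ds$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
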
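#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene identifiers;
#'   duplicates within a set are removed.
#' @param universe Background gene universe; defaults to the union of all
#'   set members. Set members outside the universe are intersected away at
#'   test time.
#' @return List of class `"gene_set_collection"` with `sets` and `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("all gene sets must be named")
  }
  if (anyDuplicated(names(sets))) abort("duplicate gene-set names")
  sets <- purrr::map(sets, unique)
  if (any(lengths(sets) == 0)) abort("empty gene set")
  universe <- unique(universe %||% unlist(sets, use.names = FALSE))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT dialect: one set per line — name, description,
#' then member genes. Duplicate set names are rejected; duplicate members
#' within a set are deduplicated; malformed lines (fewer than 3 fields)
#' raise an error naming the line.
#'
#' @param path GMT file path.
#' @param universe Optional background universe (see
#'   [gene_set_collection()]).
#' @return A `"gene_set_collection"`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn("empty GMT file: empty collection")
    return(structure(list(sets = list(), universe = universe %||% character(0)),
                     class = "gene_set_collection"))
  }
  parsed <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parsed) < 3)
  if (length(bad)) {
    abort(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
                  bad[1]))
  }
  names(parsed) <- vapply(parsed, `[[`, character(1), 1L)
  if (anyDuplicated(names(parsed))) abort("duplicate gene-set names in GMT")
  sets <- purrr::map(parsed, function(f) unique(f[-(1:2)]))
  gene_set_collection(sets, universe = universe)
}

#' Fisher's-exact gene-set over-representation test
#'
#' One-sided (enrichment direction) Fisher's exact test per gene set, from
#' the 2x2 table of in-query / in-set membership over the universe. The
#' query and every set are intersected with the universe first. No
#' multiple-testing correction is applied: the significant view is raw
#' p < `alpha`. The p-value is the hypergeometric upper tail
#' P(overlap >= observed).
#'
#' @param query Character vector of gene identifiers (e.g. the favorable or
#'   unfavorable signature).
#' @param collection A `"gene_set_collection"`.
#' @param alpha Significance threshold for the `significant` flag (default
#'   0.05).
#' @return Tibble of class `"enrichment_result"`, sorted by p: `set_name`,
#'   `overlap`, `set_size`, `query_size`, `universe_size`, `p_value`,
#'   `significant`, `overlapping_genes` (list column).
#' @export
fisher_enrichment <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- collection$universe
  query <- intersect(unique(query), universe)
  if (length(query) == 0) abort("query empty after intersection with universe")
  rows <- purrr::imap(collection$sets, function(members, nm) {
    members <- intersect(members, universe)
    ov <- intersect(query, members)
    tab <- matrix(c(
      length(ov),
      length(members) - length(ov),
      length(query) - length(ov),
      length(universe) - length(members) - length(query) + length(ov)
    ), nrow = 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    tibble(
      set_name = nm, overlap = length(ov), set_size = length(members),
      query_size = length(query), universe_size = length(universe),
      p_value = p, overlapping_genes = list(sort(ov))
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$p_value)
  out$significant <- out$p_value < alpha
  structure(out, alpha = alpha,
            class = c("enrichment_result", class(out)))
}
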
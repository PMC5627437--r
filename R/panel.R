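#' Construct a dose-response panel
#'
#' Couples per-(line, drug) IC-50 measurements with optional per-line
#' phenotypes. IC-50 is stored long (one row per line x drug, original
#' concentration units, strictly positive where present). Phenotype columns
#' may include `volume` (fL), `kp` (proliferation rate, 1/day) and any number
#' of `core_*` metabolite consumption/release columns (fmol/cell/h; positive
#' = released into the medium, negative = consumed).
#'
#' @param ic50 Tibble with columns `line_id`, `drug_id`, `ic50`.
#' @param phenotypes Optional tibble with `line_id` plus phenotype columns.
#' @return A list of class `"dose_response_panel"` with elements `ic50` and
#'   `phenotypes`.
#' @export
dose_response_panel <- function(ic50, phenotypes = NULL) {
  ic50 <- as_tibble(ic50)
  need <- c("line_id", "drug_id", "ic50")
  if (!all(need %in% names(ic50))) {
    abort("`ic50` needs columns line_id, drug_id, ic50")
  }
  if (any(ic50$ic50 <= 0, na.rm = TRUE)) abort("IC-50 values must be > 0")
  if (anyDuplicated(ic50[, c("line_id", "drug_id")])) {
    abort("duplicate (line_id, drug_id) pairs")
  }
  if (!is.null(phenotypes)) {
    phenotypes <- as_tibble(phenotypes)
    if (!"line_id" %in% names(phenotypes)) abort("`phenotypes` needs line_id")
    if (anyDuplicated(phenotypes$line_id)) abort("duplicate line_id in phenotypes")
  }
  structure(list(ic50 = ic50, phenotypes = phenotypes),
            class = "dose_response_panel")
}

#' @export
print.dose_response_panel <- function(x, ...) {
  cat(sprintf(
    "<dose_response_panel> %d lines x %d drugs%s\n",
    dplyr::n_distinct(x$ic50$line_id), dplyr::n_distinct(x$ic50$drug_id),
    if (is.null(x$phenotypes)) "" else
      sprintf("; phenotypes: %s", paste(setdiff(names(x$phenotypes), "line_id"),
                                        collapse = ", "))
  ))
  invisible(x)
}

#' Extract one drug's IC-50 vector from a panel
#'
#' @param panel A [dose_response_panel()].
#' @param drug Drug identifier.
#' @return Named numeric vector of IC-50 values (names = line ids).
#' @export
panel_ic50 <- function(panel, drug) {
  stopifnot(inherits(panel, "dose_response_panel"))
  sub <- dplyr::filter(panel$ic50, .data$drug_id == drug)
  if (nrow(sub) == 0) abort(sprintf("drug '%s' not present in panel", drug))
  setNames(sub$ic50, sub$line_id)
}

# lines x drugs IC-50 matrix
panel_ic50_matrix <- function(panel) {
  wide <- tidyr::pivot_wider(panel$ic50, names_from = "drug_id",
                             values_from = "ic50")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$line_id
  m
}

#' Write a dose-response panel as TSV
#'
#' Writes `<stem>_ic50.tsv` (long: line_id, drug_id, ic50) and, when present,
#' `<stem>_phenotypes.tsv`.
#'
#' @param panel A [dose_response_panel()].
#' @param stem Path stem for the output files.
#' @return The paths written, invisibly.
#' @export
write_panel_tsv <- function(panel, stem) {
  paths <- paste0(stem, "_ic50.tsv")
  readr::write_tsv(panel$ic50, paths)
  if (!is.null(panel$phenotypes)) {
    p2 <- paste0(stem, "_phenotypes.tsv")
    readr::write_tsv(panel$phenotypes, p2)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
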
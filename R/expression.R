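#' Construct an expression matrix
#'
#' The package's expression container is a plain numeric matrix with genes in
#' rows and samples (tumors or cell lines) in columns, carrying a `"scale"`
#' attribute that records whether the values are raw counts or log2 units.
#' The scale is always declared by the caller (or a config flag at read time),
#' never guessed from the data.
#'
#' @param values Numeric matrix, genes x samples, with unique row and column
#'   names. Missing values are allowed; infinite values are not.
#' @param scale Either `"raw_count"` or `"log2"`.
#' @return The matrix with class `"expression_matrix"` and a `"scale"`
#'   attribute.
#' @export
expression_matrix <- function(values, scale = c("log2", "raw_count")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) abort("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) abort("duplicate sample identifiers")
  if (any(is.infinite(values))) abort("expression values must be finite (NA allowed)")
  structure(values, scale = scale, class = c("expression_matrix", class(values)))
}

expr_scale <- function(m) attr(m, "scale") %||% "log2"

# subset genes while keeping class/scale attributes
keep_genes <- function(m, keep) {
  out <- m[keep, , drop = FALSE]
  expression_matrix(unclass(out), scale = expr_scale(m))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d genes x %d samples (%s scale)\n",
    nrow(x), ncol(x), expr_scale(x)
  ))
  invisible(x)
}

#' Read or write an expression matrix as TSV
#'
#' The on-disk layout is genes in rows: first column `gene_id`, remaining
#' columns one per sample, header row of sample identifiers.
#'
#' @param path File path.
#' @param scale Declared scale of the stored values (`"log2"` or
#'   `"raw_count"`); never inferred from the data.
#' @return `read_expression_tsv()` returns an [expression_matrix()];
#'   `write_expression_tsv()` returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, scale = c("log2", "raw_count")) {
  scale <- match.arg(scale)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(df)[1] != "gene_id") abort("first column must be `gene_id`")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene_id
  expression_matrix(values, scale = scale)
}

#' @param m An [expression_matrix()].
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(m, path) {
  df <- tibble::as_tibble(unclass(m), rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Validate a survival table
#'
#' A survival table is a tibble with one row per sample: `sample_id`,
#' progression-free survival `time` (days), `event` (1 = progression or
#' death, 0 = right-censored at last follow-up), plus any clinical covariate
#' columns (e.g. `tp53_mutant`, `stage`, `age`, `grade`, `nodal_status`).
#'
#' @param surv A data frame with at least `sample_id`, `time`, `event`.
#' @return The validated table as a tibble (invisibly usable in pipes).
#' @export
validate_survival <- function(surv) {
  surv <- as_tibble(surv)
  need <- c("sample_id", "time", "event")
  missing_cols <- setdiff(need, names(surv))
  if (length(missing_cols)) {
    abort(paste0("survival table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(surv$sample_id)) abort("duplicate sample_id in survival table")
  if (any(surv$time < 0, na.rm = TRUE)) abort("survival time must be >= 0")
  if (!all(surv$event %in% c(0, 1))) abort("event must be 0/1")
  surv
}

# align expression columns to survival rows; error with offending IDs
align_samples <- function(m, surv) {
  surv <- validate_survival(surv)
  missing_expr <- setdiff(surv$sample_id, colnames(m))
  if (length(missing_expr)) {
    abort(paste0(
      "samples in survival table absent from expression matrix: ",
      paste(head(missing_expr, 5), collapse = ", ")
    ))
  }
  out <- unclass(m)[, surv$sample_id, drop = FALSE]
  expression_matrix(out, scale = expr_scale(m))
}
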
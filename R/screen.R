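#' Univariate Cox regression of survival on one gene's expression
#'
#' Fits a single-covariate proportional-hazards model of progression-free
#' survival on expression, with Efron handling of tied event times.
#' Expression is standardized to unit SD by default so coefficients are
#' per-SD log-hazards. A gene is "favorable" when its coefficient is
#' negative (high expression, lower hazard).
#'
#' @param expr Numeric expression vector, one value per sample, in the row
#'   order of `surv`.
#' @param surv Survival table (see [validate_survival()]).
#' @param standardize Divide expression by its SD before fitting (default
#'   TRUE).
#' @param p_type `"wald"` (default) or `"lr"` (likelihood-ratio) p-value.
#' @param gene_id Optional identifier copied into the result.
#' @return One-row tibble: `gene_id`, `coefficient`, `hazard_ratio`,
#'   `p_value`, `direction`, `flag` (`"ok"`, `"constant"` or
#'   `"non_convergence"`).
#' @export
cox_univariate <- function(expr, surv, standardize = TRUE,
                           p_type = c("wald", "lr"), gene_id = NA_character_) {
  p_type <- match.arg(p_type)
  surv <- validate_survival(surv)
  if (length(expr) != nrow(surv)) abort("`expr` length must match `surv` rows")
  if (sum(surv$event) < 2) abort("need at least 2 events")
  y <- survival::Surv(surv$time, surv$event)
  fit_one_cox(expr, y, standardize = standardize, p_type = p_type,
              gene_id = gene_id)
}

fit_one_cox <- function(expr, y, standardize, p_type, gene_id) {
  s <- sd(expr, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    return(tibble(
      gene_id = gene_id, coefficient = 0, hazard_ratio = 1, p_value = 1,
      direction = NA_character_, flag = "constant"
    ))
  }
  x <- if (standardize) expr / s else expr
  fit <- tryCatch(
    survival::coxph(y ~ x, ties = "efron"),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(survival::coxph(y ~ x, ties = "efron"))
    }
  )
  if (is.null(fit) || is.na(stats::coef(fit))) {
    return(tibble(
      gene_id = gene_id, coefficient = NA_real_, hazard_ratio = NA_real_,
      p_value = NA_real_, direction = NA_character_, flag = "non_convergence"
    ))
  }
  beta <- unname(stats::coef(fit))
  p <- if (p_type == "wald") {
    se <- sqrt(diag(fit$var))[1]
    2 * stats::pnorm(-abs(beta / se))
  } else {
    stats::pchisq(2 * diff(fit$loglik), df = 1, lower.tail = FALSE)
  }
  tibble(
    gene_id = gene_id, coefficient = beta, hazard_ratio = exp(beta),
    p_value = p,
    direction = if (beta < 0) "favorable" else "unfavorable",
    flag = "ok"
  )
}

#' Genome-wide proportional-hazards screen
#'
#' Runs [cox_univariate()] independently for every gene of a log-scale
#' expression matrix and marks genes with p below `alpha` as hits. No
#' multiple-testing correction is applied at this stage: the screen retains
#' raw p < alpha, and the `alpha` used is recorded as an attribute.
#'
#' @param m An [expression_matrix()] on the log2 scale.
#' @param surv Survival table; its `sample_id`s must all be present as
#'   columns of `m`.
#' @param alpha Raw p-value threshold for the hit list (default 0.05).
#' @inheritParams cox_univariate
#' @return Tibble of class `"screen_result"`, one row per gene: `gene_id`,
#'   `coefficient`, `hazard_ratio`, `p_value`, `direction`, `flag`, `hit`.
#'   Attribute `alpha` records the threshold.
#' @export
screen_genes <- function(m, surv, alpha = 0.05, standardize = TRUE,
                         p_type = c("wald", "lr")) {
  p_type <- match.arg(p_type)
  m <- align_samples(m, surv)
  surv <- validate_survival(surv)
  if (sum(surv$event) < 2) abort("need at least 2 events")
  y <- survival::Surv(surv$time, surv$event)
  vals <- unclass(m)
  res <- purrr::map_dfr(seq_len(nrow(vals)), function(i) {
    fit_one_cox(vals[i, ], y, standardize = standardize, p_type = p_type,
                gene_id = rownames(vals)[i])
  })
  res$hit <- !is.na(res$p_value) & res$p_value < alpha & res$flag == "ok"
  n_bad <- sum(res$flag != "ok")
  if (n_bad > 0) {
    warn(sprintf("%d gene(s) flagged (constant or non-convergent)", n_bad))
  }
  structure(res, alpha = alpha, class = c("screen_result", class(res)))
}

#' Extract the hit list from a screen
#'
#' @param screen A `"screen_result"` tibble from [screen_genes()].
#' @return The rows with `hit == TRUE`.
#' @export
screen_hits <- function(screen) {
  dplyr::filter(as_tibble(screen), .data$hit)
}

#' Remove hits associated with clinical confounders
#'
#' A screened gene is discarded when its expression is associated with any
#' listed covariate: a two-group Wilcoxon rank-sum test for binary
#' covariates (e.g. TP53 mutation status) or a Spearman correlation test for
#' ordinal/continuous covariates (stage, age, grade, nodal status), each at
#' the per-test level `alpha` with no multiplicity correction. Surviving
#' rows are returned unchanged apart from added per-covariate p-value
#' columns; the removed rows are kept in the `"removed"` attribute.
#'
#' @param hits Tibble of screen rows to filter (e.g. [screen_hits()]).
#' @param m The expression matrix the screen was run on.
#' @param surv Survival table containing the covariates.
#' @param binary_covariates,ordinal_covariates Column names in `surv`.
#' @param alpha Per-test association threshold (default 0.05).
#' @return The surviving rows with p-value columns `p_<covariate>` and a
#'   logical `confounded` column (all FALSE among survivors); attributes
#'   `removed` (discarded rows) and `alpha_confounder`.
#' @export
filter_confounders <- function(hits, m, surv,
                               binary_covariates = "tp53_mutant",
                               ordinal_covariates = c("stage", "age", "grade",
                                                      "nodal_status"),
                               alpha = 0.05) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) {
    return(structure(dplyr::mutate(hits, confounded = logical(0)),
                     removed = hits, alpha_confounder = alpha))
  }
  surv <- validate_survival(surv)
  m <- align_samples(m, surv)
  covs <- c(binary_covariates, ordinal_covariates)
  missing_cov <- setdiff(covs, names(surv))
  if (length(missing_cov)) {
    abort(paste0("covariate(s) not in survival table: ",
                 paste(missing_cov, collapse = ", ")))
  }
  usable_binary <- character(0)
  for (cv in binary_covariates) {
    if (length(unique(stats::na.omit(surv[[cv]]))) < 2) {
      warn(sprintf("covariate '%s' has a single level; skipped", cv))
    } else usable_binary <- c(usable_binary, cv)
  }
  usable_ordinal <- character(0)
  for (cv in ordinal_covariates) {
    if (length(unique(stats::na.omit(surv[[cv]]))) < 2) {
      warn(sprintf("covariate '%s' has a single level; skipped", cv))
    } else usable_ordinal <- c(usable_ordinal, cv)
  }

  vals <- unclass(m)
  pcols <- purrr::map(c(usable_binary, usable_ordinal), function(cv) {
    v <- surv[[cv]]
    vapply(hits$gene_id, function(gid) {
      x <- vals[gid, ]
      ok <- !is.na(x) & !is.na(v)
      if (cv %in% usable_binary) {
        suppressWarnings(wilcox.test(x[ok] ~ factor(v[ok]))$p.value)
      } else {
        suppressWarnings(cor.test(x[ok], v[ok], method = "spearman")$p.value)
      }
    }, numeric(1))
  })
  names(pcols) <- paste0("p_", c(usable_binary, usable_ordinal))
  out <- dplyr::bind_cols(hits, tibble::as_tibble(pcols))
  pm <- as.matrix(out[, names(pcols), drop = FALSE])
  out$confounded <- if (ncol(pm) > 0) {
    apply(pm, 1L, function(p) any(!is.na(p) & p < alpha))
  } else rep(FALSE, nrow(out))
  structure(
    dplyr::filter(out, !.data$confounded),
    removed = dplyr::filter(out, .data$confounded),
    alpha_confounder = alpha
  )
}
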
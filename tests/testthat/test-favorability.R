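test_that("expression threshold is median + SD/2 and shift-equivariant", {
  expect_equal(expression_threshold(c(1, 1, 1, 1)), 1)
  expect_equal(expression_threshold(c(0, 2)), 1 + sqrt(2) / 2)
  set.seed(4)
  x <- rnorm(25)
  expect_equal(expression_threshold(x + 3), expression_threshold(x) + 3)
  expect_error(expression_threshold(c(1, NA, Inf)), "at least 2")
})

test_that("patient classing follows the median event time", {
  surv <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    time = c(10, 20, 50, 80, 15, 100),
    event = c(1, 1, 1, 0, 0, 1)
  )
  # median event time among events (10, 20, 50, 100) = 35
  cl <- class_samples_survival(surv, mode = "patient_class")
  expect_identical(
    cl$class,
    c("poor", "poor", "good", "good", "neutral", "good")
  )
  expect_error(class_samples_survival(dplyr::mutate(surv, event = 0)),
               "no events")
  same <- dplyr::mutate(surv, time = 5, event = 1)
  expect_warning(class_samples_survival(same, mode = "patient_class"),
                 "degenerate")
})

test_that("line classing marks IC-50 extremes and is rank-invariant", {
  ic <- setNames(c(1, 2, 3, 4, 5, 6, 7, 8), paste0("L", 1:8))
  cl <- class_lines_sensitivity(ic)
  expect_equal(sum(cl$class == "sensitive"), 2)
  expect_equal(sum(cl$class == "resistant"), 2)
  expect_equal(sum(cl$class == "neutral"), 4)

  cl_log <- class_lines_sensitivity(log(ic))
  expect_identical(cl$class, cl_log$class)

  extreme <- class_lines_sensitivity(ic, lower_q = 0, upper_q = 1)
  expect_equal(sum(extreme$class != "neutral"), 2)

  expect_warning(class_lines_sensitivity(setNames(rep(2, 6), paste0("L", 1:6))),
                 "constant")
  expect_error(class_lines_sensitivity(ic[1:3]), "at least 5")
})

test_that("score_matrix equals the brute-force definition on random fixtures", {
  for (s in 1:3) {
    set.seed(s)
    vals <- matrix(rnorm(100, 6, 2), 10, 10,
                   dimnames = list(paste0("g", 1:10), paste0("p", 1:10)))
    m <- expression_matrix(vals, scale = "log2")
    screen <- tibble::tibble(
      gene_id = rownames(vals),
      direction = sample(c("favorable", "unfavorable"), 10, replace = TRUE)
    )
    Fg <- score_matrix(m, screen = screen, mode = "gene_direction")
    oracle_g <- brute_favorability(vals,
                                   directions = setNames(screen$direction,
                                                         screen$gene_id))
    expect_identical(unclass(Fg)[rownames(oracle_g), colnames(oracle_g)],
                     oracle_g)

    for (anchor_classes in list(c("good", "poor", "neutral"),
                                c("sensitive", "resistant", "neutral"))) {
      cls <- sample(anchor_classes, 10, replace = TRUE)
      classing <- structure(
        tibble::tibble(sample_id = colnames(vals), class = cls),
        class = c("sample_classing", "tbl_df", "tbl", "data.frame")
      )
      anchor <- if ("good" %in% anchor_classes) "survival" else "sensitivity"
      Fs <- score_matrix(m, classing = classing, mode = "sample_class",
                         anchor = anchor)
      oracle_s <- brute_favorability(vals,
                                     classes = setNames(cls, colnames(vals)))
      expect_identical(unclass(Fs)[rownames(oracle_s), colnames(oracle_s)],
                       oracle_s)
    }
  }
})

test_that("scores below threshold are zero and gene columns are sign-coherent", {
  set.seed(9)
  vals <- matrix(rnorm(60, 5, 1), 6, 10,
                 dimnames = list(paste0("g", 1:6), paste0("p", 1:10)))
  m <- expression_matrix(vals, scale = "log2")
  screen <- tibble::tibble(gene_id = rownames(vals),
                           direction = rep(c("favorable", "unfavorable"), 3))
  Fm <- score_matrix(m, screen = screen, mode = "gene_direction")
  thr <- attr(Fm, "thresholds")
  for (g in rownames(vals)) {
    below <- vals[g, ] < thr[[g]]
    expect_true(all(unclass(Fm)[below, g] == 0))
    nz <- unclass(Fm)[, g][unclass(Fm)[, g] != 0]
    if (length(nz)) expect_equal(length(unique(sign(nz))), 1)
  }
})

test_that("swapping good and poor labels negates every nonzero score", {
  set.seed(10)
  vals <- matrix(rnorm(80, 5, 1), 8, 10,
                 dimnames = list(paste0("g", 1:8), paste0("p", 1:10)))
  m <- expression_matrix(vals, scale = "log2")
  cls <- sample(c("good", "poor", "neutral"), 10, replace = TRUE)
  mk <- function(classes) structure(
    tibble::tibble(sample_id = colnames(vals), class = classes),
    class = c("sample_classing", "tbl_df", "tbl", "data.frame")
  )
  swapped <- ifelse(cls == "good", "poor", ifelse(cls == "poor", "good", cls))
  F1 <- score_matrix(m, classing = mk(cls), mode = "sample_class")
  F2 <- score_matrix(m, classing = mk(swapped), mode = "sample_class")
  strip <- function(x) {
    x <- unclass(x)
    attributes(x) <- attributes(x)[c("dim", "dimnames")]
    x
  }
  expect_identical(strip(F2), -strip(F1))
})

test_that("favorability TSV + sidecar round-trips scores and metadata", {
  set.seed(11)
  vals <- matrix(rnorm(40, 5, 1), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("p", 1:10)))
  m <- expression_matrix(vals, scale = "log2")
  screen <- tibble::tibble(gene_id = rownames(vals),
                           direction = rep("favorable", 4))
  Fm <- score_matrix(m, screen = screen, mode = "gene_direction")
  stem <- withr::local_tempfile()
  write_favorability_tsv(Fm, stem)
  back <- readr::read_tsv(paste0(stem, ".tsv"), show_col_types = FALSE)
  expect_equal(as.matrix(back[, -1]), unclass(Fm), ignore_attr = TRUE)
  side <- jsonlite::read_json(paste0(stem, ".json"))
  expect_identical(side$mode, "gene_direction")
  expect_equal(side$thresholds$g1, attr(Fm, "thresholds")[["g1"]])
})
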
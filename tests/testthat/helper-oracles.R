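# Independent straight-line reimplementations used as oracles. Each is a
# direct transcription of the defining formula, kept deliberately naive and
# separate from the package's code paths.

# Kendall tau-b by O(n^2) pair counting
brute_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# two-sample log-rank chi-square by direct hypergeometric accumulation
brute_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- group == unique(group)[1]
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    if (n < 2) next
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# Benjamini-Hochberg step-up from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  adj <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  q[o] <- pmin(adj, 1)
  q
}

# one-sided hypergeometric tail P(X >= k) by direct summation
brute_hyper_tail <- function(overlap, set_size, query_size, universe_size) {
  ks <- overlap:min(set_size, query_size)
  sum(choose(set_size, ks) *
        choose(universe_size - set_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# cell-by-cell favorability scoring from the raw definitions
brute_favorability <- function(vals, directions = NULL, classes = NULL,
                               thresholds = NULL) {
  genes <- rownames(vals)
  samples <- colnames(vals)
  out <- matrix(0L, length(samples), length(genes),
                dimnames = list(samples, genes))
  for (g in genes) {
    thr <- if (is.null(thresholds)) {
      median(vals[g, ]) + sd(vals[g, ]) / 2
    } else thresholds[[g]]
    for (s in samples) {
      if (vals[g, s] >= thr) {
        if (!is.null(directions)) {
          out[s, g] <- if (directions[[g]] == "favorable") 1L else -1L
        } else {
          cls <- classes[[s]]
          out[s, g] <- if (cls %in% c("good", "sensitive")) 1L
          else if (cls %in% c("poor", "resistant")) -1L else 0L
        }
      }
    }
  }
  out
}

# small survival fixture with a clean split used across tests
make_surv_fixture <- function(n = 30, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("P%02d", seq_len(n)),
    time = round(rexp(n, 0.02), 1),
    event = rbinom(n, 1, 0.7)
  )
}
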
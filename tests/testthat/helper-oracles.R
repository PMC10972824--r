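# Independent brute-force oracles used to pin down expected values.
# These deliberately re-derive each quantity from its definition rather
# than reusing any package code path.

# sup |ECDF_a - ECDF_b| by enumerating every pooled breakpoint
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), 0)))
}

# upper-tail hypergeometric P(X >= k) by enumerating all C(N, n) draws
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_set <- seq_len(K)
  hits <- colSums(matrix(draws %in% in_set, nrow = n))
  mean(hits >= k)
}

# AUROC as the all-pairs Mann-Whitney probability with half-credit ties
oracle_auroc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# BH step-up evaluated literally: p_(i) * m / i, cumulative min from the top
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# two-sample pooled-variance t from the textbook formula
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  s2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(s2 * (1 / nx + 1 / ny))
}

# running-sum ES evaluated step by step with an explicit loop
oracle_running_es <- function(stats_desc, flags, p = 1) {
  N <- length(stats_desc)
  K <- sum(flags)
  nr <- sum(abs(stats_desc[flags])^p)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (flags[i]) abs(stats_desc[i])^p / nr else -1 / (N - K)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# random small matrix with dimnames
rand_mat <- function(nr, nc, seed = 1, prefix = c("r", "c")) {
  set.seed(seed)
  matrix(rnorm(nr * nc), nr, nc,
         dimnames = list(paste0(prefix[1], seq_len(nr)),
                         paste0(prefix[2], seq_len(nc))))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
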
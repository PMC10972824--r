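# Gene-set machinery: hypergeometric over-representation, the weighted
# Kolmogorov-Smirnov running-sum enrichment score, preranked permutation
# GSEA (gene-label null), single-sample GSEA, and the signed pathway
# score sign(NES) * -log10(FDR).

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` of drawing at least the observed
#' overlap when `n` genes are sampled from a universe of `N` containing
#' `K` set members. The set is intersected with the universe before
#' testing; a query gene outside the universe is an error.
#'
#' @param query character vector of query genes (e.g. DEGs).
#' @param gene_set character vector of set members.
#' @param universe character vector of all testable genes.
#' @return list with `k`, `K`, `n`, `N`, `p`.
#' @export
hypergeometric_enrichment <- function(query, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop("query contains genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  }
  set_u <- intersect(unique(gene_set), universe)
  k <- length(intersect(query, set_u))
  K <- length(set_u)
  n <- length(query)
  N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = p)
}

#' Over-representation analysis across a collection
#'
#' @param query query gene vector.
#' @param collection named list of gene sets.
#' @param universe universe gene vector.
#' @return data frame with per-set `k`, `K`, `n`, `N`, `p` and BH `fdr`,
#'   ordered by p.
#' @export
ora <- function(query, collection, universe) {
  rows <- lapply(names(collection), function(nm) {
    h <- hypergeometric_enrichment(query, collection[[nm]], universe)
    data.frame(set = nm, k = h$k, K = h$K, n = h$n, N = h$N, p = h$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}

# ES from member positions within a ranked list of length N.
# `w` are the |stat|^p weights at those positions (ignored when the set
# covers the whole list). Candidate extrema occur just before and just
# after each hit; the running sum ends at exactly 0.
es_from_positions <- function(pos, w, N) {
  K <- length(pos)
  o <- order(pos)
  pos <- pos[o]
  w <- w[o]
  if (K == N) return(list(ES = 1, at = N, positive = TRUE))
  cw <- cumsum(w) / sum(w)
  miss <- (pos - seq_len(K)) / (N - K)
  after <- cw - miss
  before <- c(0, cw[-K]) - miss
  cand <- c(rbind(before, after))
  i <- which.max(abs(cand))
  es <- cand[i]
  hit_idx <- ceiling(i / 2)
  list(ES = es, at = if (es >= 0) pos[hit_idx] else pos[hit_idx],
       hit_index = hit_idx, positive = es >= 0)
}

#' Weighted running-sum enrichment score
#'
#' Walking down a ranked list, member genes ("hits") increment the running
#' sum by `|s_i|^p / sum_set |s|^p` and non-members decrement it by
#' `1/(N - K)`; the enrichment score is the signed maximum deviation from
#' zero. The leading edge holds the members up to the extremum (positive
#' ES) or from the extremum onward (negative ES).
#'
#' @param ranked_stats numeric ranking statistics sorted in decreasing
#'   order, named by gene.
#' @param member_flags logical vector aligned with `ranked_stats`.
#' @param weight_p weight exponent (0 = classic unweighted K-S, 1 default).
#' @return list with `ES`, `leading_edge` (gene names) and `running`
#'   (the full running-sum vector).
#' @export
running_sum_es <- function(ranked_stats, member_flags, weight_p = 1) {
  N <- length(ranked_stats)
  stopifnot(length(member_flags) == N, N >= 1)
  if (is.unsorted(rev(ranked_stats))) {
    stop("ranked_stats must be sorted in decreasing order")
  }
  K <- sum(member_flags)
  if (K == 0) stop("no set members in the ranked list")
  w <- abs(ranked_stats)^weight_p
  if (weight_p > 0 && sum(w[member_flags]) == 0) {
    stop("all member statistics are zero: hit weights undefined")
  }
  inc <- numeric(N)
  if (K == N) {
    inc[member_flags] <- w[member_flags] / sum(w[member_flags])
  } else {
    inc[member_flags] <- if (weight_p == 0) {
      1 / K
    } else {
      w[member_flags] / sum(w[member_flags])
    }
    inc[!member_flags] <- -1 / (N - K)
  }
  running <- cumsum(inc)
  i <- which.max(abs(running))
  es <- running[i]
  genes <- names(ranked_stats) %||% as.character(seq_len(N))
  leading <- if (es >= 0) {
    genes[seq_len(i)][member_flags[seq_len(i)]]
  } else {
    genes[seq.int(i, N)][member_flags[seq.int(i, N)]]
  }
  list(ES = es, leading_edge = leading, running = running)
}

#' Preranked permutation GSEA
#'
#' For each set within the size bounds, computes the observed running-sum
#' ES and a gene-label permutation null (random same-size gene draws with
#' the same weighting). The p-value is
#' `(1 + #{same-sign |ES_perm| >= |ES|}) / (1 + #same-sign perms)`, NES is
#' `ES / mean(|ES_perm| of matching sign)`, and FDR is BH across the
#' tested sets. Deterministic given `seed`.
#'
#' @param ranked_stats named statistics (sorted internally, decreasing).
#' @param collection named list of gene sets.
#' @param nperm number of permutations (default 1e5).
#' @param min_size,max_size set-size bounds applied after intersecting
#'   with the ranked universe (defaults 10 and 500).
#' @param weight_p weight exponent.
#' @param seed integer seed for the permutation stream.
#' @return data frame with `set`, `size`, `ES`, `NES`, `p`, `fdr`,
#'   `leading_edge` (comma-joined), `no_same_sign_perm` flag; excluded
#'   sets are listed in the `excluded` attribute.
#' @export
gsea <- function(ranked_stats, collection, nperm = 1e5, min_size = 10,
                 max_size = 500, weight_p = 1, seed = 1) {
  stopifnot(nperm >= 1, !is.null(names(ranked_stats)))
  ord <- order(ranked_stats, decreasing = TRUE)
  ranked_stats <- ranked_stats[ord]
  genes <- names(ranked_stats)
  N <- length(genes)
  w_all <- abs(ranked_stats)^weight_p

  sizes <- vapply(collection, function(s) length(intersect(s, genes)), 0L)
  keep <- sizes >= min_size & sizes <= max_size
  excluded <- data.frame(set = names(collection)[!keep],
                         size = sizes[!keep], stringsAsFactors = FALSE)
  if (nrow(excluded) > 0) {
    message(nrow(excluded), " set(s) outside size bounds [", min_size,
            ", ", max_size, "] excluded")
  }
  tested <- names(collection)[keep]
  rows <- with_seed(seed, lapply(tested, function(nm) {
    pos <- which(genes %in% collection[[nm]])
    K <- length(pos)
    flags <- logical(N)
    flags[pos] <- TRUE
    obs <- running_sum_es(ranked_stats, flags, weight_p)
    es_perm <- vapply(seq_len(nperm), function(i) {
      pp <- sample.int(N, K)
      es_from_positions(pp, w_all[pp], N)$ES
    }, numeric(1))
    same_sign <- if (obs$ES >= 0) es_perm[es_perm >= 0] else es_perm[es_perm < 0]
    if (length(same_sign) == 0) {
      p <- 1 / (nperm + 1)
      nes <- NA_real_
      flag <- TRUE
    } else {
      p <- (1 + sum(abs(same_sign) >= abs(obs$ES))) / (1 + length(same_sign))
      nes <- obs$ES / mean(abs(same_sign))
      flag <- FALSE
    }
    data.frame(set = nm, size = K, ES = obs$ES, NES = nes, p = p,
               leading_edge = paste(obs$leading_edge, collapse = ","),
               no_same_sign_perm = flag, stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(set = character(), size = integer(),
                                      ES = numeric(), NES = numeric(),
                                      p = numeric(),
                                      leading_edge = character(),
                                      no_same_sign_perm = logical())
  out$fdr <- bh_adjust(out$p)
  out <- out[, c("set", "size", "ES", "NES", "p", "fdr", "leading_edge",
                 "no_same_sign_perm")]
  attr(out, "excluded") <- excluded
  out
}

ssgsea_one <- function(x, collection, alpha) {
  N <- length(x)
  ord <- order(-x, seq_len(N))            # ties broken by stable input order
  genes <- names(x)[ord]
  rk <- (N:1)^alpha                        # rank weights, top gene largest
  vapply(names(collection), function(nm) {
    member <- genes %in% collection[[nm]]
    K <- sum(member)
    if (K == 0 || K == N) return(NA_real_)
    p_in <- cumsum(rk * member) / sum(rk[member])
    p_out <- cumsum(!member) / (N - K)
    sum(p_in - p_out)
  }, numeric(1))
}

#' Single-sample GSEA scores
#'
#' Per sample, genes are ranked by expression and each set is scored by
#' the sum over the list of the difference between the rank-weighted
#' member step-CDF (weights `rank^alpha`) and the uniform non-member
#' step-CDF. Optionally the scores are normalised by the (max - min)
#' across all set/sample scores of the run.
#'
#' @param expression genes x samples matrix (e.g. TPM or log2(TPM+1)
#'   profiles), or a single named vector for one sample.
#' @param collection named list of gene sets.
#' @param alpha rank weight exponent (default 0.25).
#' @param normalize divide by the score range across the run (default TRUE).
#' @return sets x samples matrix of scores; sets with no member in the
#'   profile are `NA` and reported via a message.
#' @export
ssgsea <- function(expression, collection, alpha = 0.25, normalize = TRUE) {
  if (!is.matrix(expression)) {
    expression <- matrix(expression, ncol = 1,
                         dimnames = list(names(expression), "sample"))
  }
  stopifnot(!is.null(rownames(expression)))
  scores <- apply(expression, 2, function(col) {
    ssgsea_one(stats::setNames(col, rownames(expression)), collection, alpha)
  })
  scores <- matrix(scores, nrow = length(collection),
                   dimnames = list(names(collection), colnames(expression)))
  if (anyNA(scores)) {
    message(sum(is.na(scores)), " set/sample score(s) absent ",
            "(no set member in the profile)")
  }
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  scores
}

#' Signed pathway score
#'
#' `sign(NES) * -log10(FDR)`, the signed significance summary used to
#' report per-set enrichment direction and strength. The FDR is floored at
#' `fdr_floor` (typically `1/(nperm+1)`) before taking the log.
#'
#' @param nes normalized enrichment score(s).
#' @param fdr FDR value(s) in (0, 1].
#' @param fdr_floor lower floor applied to `fdr`; `NULL` (default) applies
#'   no floor, in which case `fdr` must be positive.
#' @return signed score(s); 0 whenever `fdr` is 1.
#' @export
pathway_score <- function(nes, fdr, fdr_floor = NULL) {
  stopifnot(all(is.finite(nes)), all(fdr <= 1))
  if (!is.null(fdr_floor)) fdr <- pmax(fdr, fdr_floor)
  if (any(fdr <= 0)) stop("FDR must be positive (supply fdr_floor)")
  sign(nes) * (-log10(fdr))
}
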
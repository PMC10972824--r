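# Clustering of genes by drug-induced expression change: per-gene
# z-transformation, complete-linkage hierarchical clustering on Euclidean
# distances cut at a predefined K, per-cluster over-representation, and a
# PCA projection of the samples.

#' Row-wise z-transformation
#'
#' Centers and scales every gene row to mean 0 and unit variance
#' (denominator n - 1). Constant rows (zero variance) cannot be scaled and
#' are dropped with a warning.
#'
#' @param mat genes x samples numeric matrix.
#' @return z-transformed matrix (possibly with fewer rows).
#' @export
z_transform <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  sds <- apply(mat, 1, stats::sd)
  constant <- !is.finite(sds) | sds == 0
  if (any(constant)) {
    warning(sum(constant), " constant gene row(s) dropped before scaling",
            call. = FALSE)
    mat <- mat[!constant, , drop = FALSE]
    sds <- sds[!constant]
  }
  (mat - rowMeans(mat)) / sds
}

#' Average replicate columns by condition
#'
#' @param mat genes x samples matrix.
#' @param condition per-sample condition labels (aligned or named).
#' @return genes x conditions matrix of replicate means, conditions in
#'   first-appearance order.
#' @export
average_replicates <- function(mat, condition) {
  stopifnot(ncol(mat) == length(condition))
  conds <- unique(condition)
  out <- sapply(conds, function(cc) {
    rowMeans(mat[, condition == cc, drop = FALSE])
  })
  dimnames(out) <- list(rownames(mat), conds)
  out
}

#' Hierarchical clustering of genes into K groups
#'
#' Agglomerative complete-linkage clustering on Euclidean distances
#' between gene rows, cut to exactly `k` clusters. Deterministic for a
#' given input (agglomeration ties resolved by the smallest row-index
#' pair, as in the standard implementation).
#'
#' @param mat genes x features numeric matrix (typically z-transformed
#'   replicate-averaged condition profiles).
#' @param k number of clusters (default 5).
#' @return list of class `cluster_assignment` with `assignment` (named
#'   cluster ids 1..k), `merge_heights` (non-decreasing agglomeration
#'   heights) and the `hclust` tree for audit.
#' @export
hierarchical_clusters <- function(mat, k = 5) {
  stopifnot(is.matrix(mat), k >= 2)
  if (nrow(mat) < k) stop("fewer rows (", nrow(mat), ") than k = ", k)
  tree <- stats::hclust(stats::dist(mat, method = "euclidean"),
                        method = "complete")
  assignment <- stats::cutree(tree, k = k)
  structure(list(assignment = assignment, merge_heights = tree$height,
                 hclust = tree, k = k),
            class = "cluster_assignment")
}

#' Per-cluster over-representation analysis
#'
#' Each cluster's genes are tested against every set of the collection
#' with the hypergeometric test, universe = all clustered genes, BH FDR
#' within each cluster.
#'
#' @param assignment a [hierarchical_clusters()] result or a named cluster
#'   id vector.
#' @param collection named list of gene sets.
#' @param top_n keep the `top_n` most significant sets per cluster
#'   (default `Inf` = all).
#' @return data frame with `cluster`, `set`, `k`, `K`, `p`, `fdr`.
#' @export
cluster_enrichment <- function(assignment, collection, top_n = Inf) {
  if (inherits(assignment, "cluster_assignment")) {
    assignment <- assignment$assignment
  }
  universe <- names(assignment)
  stopifnot(!is.null(universe))
  rows <- lapply(sort(unique(assignment)), function(cl) {
    res <- ora(universe[assignment == cl], collection, universe)
    res <- utils::head(res, top_n)
    cbind(cluster = cl, res[, c("set", "k", "K", "p", "fdr")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' PCA projection of samples
#'
#' Centers each gene and projects the samples onto the leading principal
#' components via SVD. The sign of each component is fixed by forcing its
#' largest-magnitude gene loading positive, so projections are
#' deterministic.
#'
#' @param mat genes x samples matrix.
#' @param n_components number of components (<= min(dim)).
#' @return list with `scores` (samples x components), `loadings`
#'   (genes x components) and `explained` (variance fractions, all
#'   components; sums to <= 1).
#' @export
pca_projection <- function(mat, n_components = 2) {
  stopifnot(is.matrix(mat), n_components >= 1,
            n_components <= min(dim(mat)))
  x <- t(mat - rowMeans(mat))           # samples x genes, gene-centered
  sv <- svd(x)
  d2 <- sv$d^2
  explained <- d2 / sum(d2)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  loadings <- sv$v
  for (j in seq_len(n_components)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  scores <- scores[, seq_len(n_components), drop = FALSE]
  loadings <- loadings[, seq_len(n_components), drop = FALSE]
  dimnames(scores) <- list(colnames(mat), paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(rownames(mat), paste0("PC", seq_len(n_components)))
  list(scores = scores, loadings = loadings, explained = explained)
}
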
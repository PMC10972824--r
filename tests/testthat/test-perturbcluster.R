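test_that("z-transform standardizes rows, drops constants, is idempotent", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 10, 20))
  expect_warning(z <- z_transform(m), "constant")
  expect_false("b" %in% rownames(z))
  expect_equal(unname(rowMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(z_transform(z), z, tolerance = 1e-12)  # idempotence
})

test_that("complete-linkage clustering separates planted blobs and orders heights", {
  set.seed(71)
  blob <- rbind(matrix(rnorm(60, 0, 0.1), 20),
                matrix(rnorm(60, 5, 0.1), 20))
  rownames(blob) <- paste0("g", 1:40)
  cl <- hierarchical_clusters(blob, k = 2)
  truth <- rep(1:2, each = 20)
  expect_equal(adjusted_rand_index(cl$assignment, truth), 1)
  expect_true(all(diff(cl$merge_heights) >= -1e-12))  # non-decreasing merges

  rand <- matrix(rnorm(200), 50)
  rownames(rand) <- paste0("r", 1:50)
  cl_r <- hierarchical_clusters(rand, k = 4)
  expect_true(all(diff(cl_r$merge_heights) >= -1e-12))
  expect_identical(length(unique(cl_r$assignment)), 4L)
  expect_error(hierarchical_clusters(rand[1:3, ], k = 5), "fewer rows")
})

test_that("clustering recovers the planted five-cluster perturbation structure", {
  e <- generate_perturbation_experiment(seed = 72)
  prof <- average_replicates(e$expression, e$condition)
  cl <- hierarchical_clusters(z_transform(prof), k = 5)
  ari <- adjusted_rand_index(cl$assignment,
                             e$truth$cluster[names(cl$assignment)])
  expect_gt(ari, 0.9)
  skip_if_not_installed("mclust")
  expect_equal(ari, mclust::adjustedRandIndex(
    cl$assignment, e$truth$cluster[names(cl$assignment)]), tolerance = 1e-12)
})

test_that("clustering is invariant to gene order up to relabeling", {
  e <- generate_perturbation_experiment(n_genes = 100, seed = 73)
  z <- z_transform(average_replicates(e$expression, e$condition))
  set.seed(2)
  perm <- sample(nrow(z))
  a <- hierarchical_clusters(z, 5)$assignment
  b <- hierarchical_clusters(z[perm, ], 5)$assignment
  expect_equal(adjusted_rand_index(a, b[names(a)]), 1)
})

test_that("recovered reversed-by-inhibitor cluster shows the planted profile shape", {
  e <- generate_perturbation_experiment(seed = 74)
  prof <- average_replicates(e$expression, e$condition)
  cl <- hierarchical_clusters(z_transform(prof), k = 5)
  g2 <- names(e$truth$cluster)[e$truth$cluster == e$truth$reversed_cluster]
  rec <- names(which.max(table(cl$assignment[g2])))
  means <- colMeans(prof[names(cl$assignment)[cl$assignment == rec], ])
  # up on drug, reversed by the combination
  expect_gt(means["drug"], means["vehicle"] + 1)
  expect_lt(means["combo"], means["drug"] - 1)
})

test_that("cluster enrichment finds planted sets and stays null under shuffling", {
  e <- generate_perturbation_experiment(seed = 75)
  prof <- average_replicates(e$expression, e$condition)
  cl <- hierarchical_clusters(z_transform(prof), k = 5)
  enr <- cluster_enrichment(cl, e$sets)
  # a cluster equal to its planted set's cluster puts that set at minimal p
  g2 <- names(e$truth$cluster)[e$truth$cluster == 2]
  rec <- names(which.max(table(cl$assignment[g2])))
  sub <- enr[enr$cluster == rec, ]
  expect_identical(sub$set[which.min(sub$p)], "CLUSTER_SET_2")
  expect_lt(sub$fdr[sub$set == "CLUSTER_SET_2"], 0.05)

  # random assignments give super-uniform (conservative, discrete)
  # enrichment p: the sub-0.05 fraction never exceeds the nominal rate
  set.seed(3)
  ps <- unlist(lapply(1:60, function(i) {
    shuf <- setNames(sample(cl$assignment), names(cl$assignment))
    cluster_enrichment(shuf, e$sets["DECOY_A"])$p
  }))
  expect_lte(mean(ps < 0.05), 0.07)
  expect_gt(mean(ps), 0.4)
})

test_that("PCA projection explains rank-1 data fully and preserves distances", {
  set.seed(76)
  u <- rnorm(30); v <- rnorm(8)
  rank1 <- outer(u, v)
  dimnames(rank1) <- list(paste0("g", 1:30), paste0("s", 1:8))
  pc <- pca_projection(rank1, n_components = 2)
  expect_equal(pc$explained[1], 1, tolerance = 1e-9)

  full <- matrix(rnorm(30 * 6), 30, dimnames = list(paste0("g", 1:30),
                                                    paste0("s", 1:6)))
  pc_f <- pca_projection(full, n_components = 6)
  d_orig <- dist(t(full - rowMeans(full)))
  d_proj <- dist(pc_f$scores)
  expect_equal(as.numeric(d_proj), as.numeric(d_orig), tolerance = 1e-9)

  # deterministic sign: largest-magnitude loading entry is positive
  for (j in 1:2) {
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
})
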
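test_that("hypergeometric p matches exact enumeration", {
  # N=10, K=4, n=3, k=3: only C(4,3)=4 of C(10,3)=120 draws are all-in
  h <- hypergeometric_enrichment(paste0("g", 1:3), paste0("g", 1:4),
                                 paste0("g", 1:10))
  expect_equal(h$p, 4 / 120, tolerance = 1e-12)

  # k = 0: the tail from zero is the whole space
  h0 <- hypergeometric_enrichment(paste0("g", 8:10), paste0("g", 1:4),
                                  paste0("g", 1:10))
  expect_identical(h0$p, 1)

  # N=20, K=5, n=5, k=2 against the explicit combinatorial sum
  uni <- paste0("g", 1:20)
  h2 <- hypergeometric_enrichment(c("g1", "g2", "g18", "g19", "g20"),
                                  paste0("g", 1:5), uni)
  expected <- 1 - (choose(5, 0) * choose(15, 5) + choose(5, 1) * choose(15, 4)) /
    choose(20, 5)
  expect_equal(h2$p, expected, tolerance = 1e-12)
  expect_error(hypergeometric_enrichment("g1", "g1", character(0)), "universe")
})

test_that("hypergeometric p equals draw enumeration for all (K, n, k) at N <= 12", {
  for (N in c(8, 12)) {
    uni <- paste0("g", seq_len(N))
    for (K in c(2, 4, N - 2)) {
      for (n in c(2, 5)) {
        for (k in 0:min(K, n)) {
          if (n - k > N - K) next
          # query with exactly k members of the set
          query <- c(if (k > 0) paste0("g", seq_len(k)),
                     if (n - k > 0) paste0("g", K + seq_len(n - k)))
          h <- hypergeometric_enrichment(query, paste0("g", seq_len(K)), uni)
          expect_equal(h$p, oracle_hyper_enum(N, K, n, k), tolerance = 1e-10,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("running-sum ES matches spec cases and the step-by-step oracle", {
  stats <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  es <- running_sum_es(stats, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(es$ES, 1.0)  # sum reaches +1 before any miss
  expect_identical(es$leading_edge, c("g1", "g2"))

  es_all <- running_sum_es(stats, rep(TRUE, 5))
  expect_equal(es_all$ES, 1.0)  # no misses

  set.seed(41)
  for (i in 1:20) {
    s <- sort(rnorm(20), decreasing = TRUE)
    names(s) <- paste0("g", 1:20)
    flags <- seq_len(20) %in% sample(20, 6)
    expect_equal(running_sum_es(s, flags)$ES, oracle_running_es(s, flags),
                 tolerance = 1e-12)
    # reversing the ranking negates ES
    expect_equal(running_sum_es(rev(-s), rev(flags))$ES,
                 -running_sum_es(s, flags)$ES, tolerance = 1e-12)
  }
  expect_error(running_sum_es(setNames(c(0, 0, -1), paste0("g", 1:3)),
                              c(TRUE, TRUE, FALSE)), "zero")
})

test_that("ES agrees with the reference preranked implementation", {
  skip_if_not_installed("fgsea")
  set.seed(42)
  s <- sort(rnorm(50), decreasing = TRUE)
  names(s) <- paste0("g", 1:50)
  for (i in 1:10) {
    idx <- sort(sample(50, 8))
    mine <- running_sum_es(s, seq_len(50) %in% idx)$ES
    ref <- fgsea::calcGseaStat(s, selectedStats = idx)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("permutation GSEA filters sizes, recovers planted sets, is seed-stable", {
  set.seed(43)
  stats <- setNames(rnorm(400), paste0("g", 1:400))
  stats[paste0("g", 1:25)] <- stats[paste0("g", 1:25)] + 2.5
  coll <- list(PLANTED = paste0("g", 1:25),
               TINY = paste0("g", 30:38),            # size 9 < min_size
               RANDOM = paste0("g", 101:140))
  r1 <- quiet(gsea(stats, coll, nperm = 2000, seed = 7))
  expect_false("TINY" %in% r1$set)
  expect_identical(attr(r1, "excluded")$set, "TINY")
  expect_gt(r1$NES[r1$set == "PLANTED"], 0)
  expect_lt(r1$fdr[r1$set == "PLANTED"], 0.05)
  r2 <- quiet(gsea(stats, coll, nperm = 2000, seed = 7))
  expect_identical(r1$p, r2$p)  # identical to the last digit
  expect_true(all(sign(r1$NES) == sign(r1$ES)))
})

test_that("GSEA p-values under a null ranking are not anti-conservative", {
  set.seed(44)
  stats <- setNames(rnorm(300), paste0("g", 1:300))
  coll <- lapply(1:100, function(i) sample(names(stats), 20))
  names(coll) <- paste0("S", 1:100)
  r <- quiet(gsea(stats, coll, nperm = 500, seed = 9))
  expect_lte(mean(r$p < 0.05), 0.09)
})

test_that("ssGSEA is maximal when members fill the top ranks (exhaustive, 8 genes)", {
  x <- setNames(c(8, 7, 6, 5, 4, 3, 2, 1), paste0("g", 1:8))
  subsets <- combn(8, 3)
  scores <- apply(subsets, 2, function(idx) {
    ssgsea(x, list(S = paste0("g", idx)), normalize = FALSE)[1, 1]
  })
  top <- which(apply(subsets, 2, function(idx) all(idx %in% 1:3)))
  expect_identical(which.max(scores), top)
})

test_that("ssGSEA ignores gene input order and rewards upward member swaps", {
  set.seed(45)
  x <- setNames(sample(seq(1, 50)), paste0("g", 1:50))
  coll <- list(S = paste0("g", c(3, 9, 17, 30)))
  s1 <- ssgsea(x, coll, normalize = FALSE)
  perm <- sample(50)
  s2 <- ssgsea(x[perm], coll, normalize = FALSE)
  expect_equal(s1, s2, tolerance = 1e-12)

  # swapping a member upward past an adjacent non-member raises the score
  for (i in 1:10) {
    x2 <- x
    ord <- names(sort(x2, decreasing = TRUE))
    memb_pos <- which(ord %in% coll$S)
    pos <- memb_pos[memb_pos > 1][1]
    if (ord[pos - 1] %in% coll$S) next
    tmp <- x2[ord[pos]]
    x2[ord[pos]] <- x2[ord[pos - 1]]
    x2[ord[pos - 1]] <- tmp
    expect_gt(ssgsea(x2, coll, normalize = FALSE)[1, 1], s1[1, 1])
  }
})

test_that("ssGSEA on the planted panel anticorrelates with AUC", {
  p <- generate_panel(panel_recipe(n_lines = 150, n_genes = 400, seed = 46))
  sc <- ssgsea(p$bundle$expression, p$sets["SENSITIVITY_SIGNATURE"])
  rho <- cor(sc[1, ], p$bundle$responses[, 1], method = "spearman")
  expect_lt(rho, -0.5)
})

test_that("pathway score arithmetic is signed -log10(FDR)", {
  expect_equal(pathway_score(2.0, 0.01), 2.0)
  expect_equal(pathway_score(-1.5, 0.1), -1.0)
  expect_equal(pathway_score(3.0, 1), 0)
  expect_equal(pathway_score(-2, 1e-8, fdr_floor = 1e-4), -4)
  expect_error(pathway_score(1, 0), "positive")
})
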
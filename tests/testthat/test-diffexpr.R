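make_expr <- function(n_genes, n_r, n_s, seed = 1, shift = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n_r + n_s)), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              c(paste0("R", seq_len(n_r)),
                                paste0("S", seq_len(n_s)))))
  if (!is.null(shift)) m[names(shift), seq_len(n_r)] <-
      m[names(shift), seq_len(n_r)] + shift
  m
}

test_that("moderated t collapses to the ordinary pooled t as d0 -> 0", {
  m <- make_expr(100, 6, 5, seed = 2)
  res <- moderated_t_test(m, paste0("R", 1:6), paste0("S", 1:5),
                          prior_df = 0, prior_var = 1)
  plain <- apply(m, 1, function(x) oracle_pooled_t(x[1:6], x[7:11]))
  expect_equal(res$t, unname(plain), tolerance = 1e-6)
})

test_that("moderated t collapses to the prior-SD t as d0 -> Inf", {
  m <- make_expr(50, 4, 4, seed = 3)
  s0 <- 1.7
  res <- moderated_t_test(m, paste0("R", 1:4), paste0("S", 1:4),
                          prior_df = Inf, prior_var = s0^2)
  logfc <- rowMeans(m[, 1:4]) - rowMeans(m[, 5:8])
  expect_equal(res$t, unname(logfc / (s0 * sqrt(1 / 4 + 1 / 4))),
               tolerance = 1e-10)
})

test_that("moderated p agrees with direct formula evaluation to 1e-10", {
  m <- make_expr(300, 5, 7, seed = 4)
  res <- moderated_t_test(m, paste0("R", 1:5), paste0("S", 1:7))
  d0 <- attr(res, "df_prior")
  s0 <- attr(res, "var_prior")
  # independent re-evaluation of the shrinkage and the t/p formulas
  d <- 5 + 7 - 2
  ref <- apply(m, 1, function(x) {
    xr <- x[1:5]; xs <- x[6:12]
    s2 <- ((4) * var(xr) + (6) * var(xs)) / d
    post <- if (is.infinite(d0)) s0 else (d0 * s0 + d * s2) / (d0 + d)
    tt <- (mean(xr) - mean(xs)) / sqrt(post * (1 / 5 + 1 / 7))
    2 * pt(-abs(tt), df = d0 + d)
  })
  expect_equal(res$p, unname(ref), tolerance = 1e-10)
})

test_that("moderated t tracks the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  m <- make_expr(400, 6, 6, seed = 5,
                 shift = setNames(rep(2, 10), paste0("g", 1:10)))
  res <- moderated_t_test(m, paste0("R", 1:6), paste0("S", 1:6))
  design <- cbind(1, rep(c(1, 0), each = 6))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(res, "df_prior"), fit$df.prior, tolerance = 1e-6)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("swapping group labels negates logFC and t, keeps p", {
  m <- make_expr(80, 5, 5, seed = 6)
  a <- moderated_t_test(m, paste0("R", 1:5), paste0("S", 1:5))
  b <- moderated_t_test(m, paste0("S", 1:5), paste0("R", 1:5))
  expect_equal(a$logFC, -b$logFC, tolerance = 1e-12)
  expect_equal(a$t, -b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("zero-variance genes are flagged with p = 1, never dropped", {
  m <- make_expr(20, 3, 3, seed = 7)
  m["g5", ] <- 4
  expect_message(res <- moderated_t_test(m, paste0("R", 1:3), paste0("S", 1:3)),
                 "zero-variance")
  expect_true(res$zero_variance[res$gene == "g5"])
  expect_identical(res$p[res$gene == "g5"], 1)
  expect_identical(nrow(res), 20L)
})

test_that("BH adjustment matches the hand-evaluated step-up and is permutation-stable", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(8)
  p <- runif(57)
  perm <- sample(57)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-15)
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("DEG gates apply the FDR and fold-change thresholds exactly", {
  res <- data.frame(gene = c("a", "b", "c"),
                    logFC = c(1.1, 0.9, -1.2),
                    fdr = c(0.009, 0.009, 0.001))
  sel <- quiet(select_deg(res, fdr = 0.01, fc = 2))
  expect_identical(sel$up, "a")     # logFC 1.1 > log2(2) = 1
  expect_identical(sel$down, "c")
  expect_identical(sel$table$direction[2], "ns")  # 0.9 misses the FC gate
})

test_that("planted signature genes are recovered with the right direction", {
  p <- generate_panel(panel_recipe(n_lines = 80, n_genes = 500, set_size = 40,
                                   beta_sig = 2, frac_classV = 0.1, seed = 9))
  g <- assign_sensitivity_groups(p$bundle$responses[, 1], 0.25)
  res <- moderated_t_test(p$bundle$expression, g$resistant, g$sensitive)
  sel <- quiet(select_deg(res, fdr = 0.01, fc = 2))
  # signature is higher in sensitive lines, hence down in R vs S
  hits <- intersect(sel$down, p$truth$signature_genes)
  expect_gte(length(hits) / length(p$truth$signature_genes), 0.9)
  expect_length(intersect(sel$up, p$truth$signature_genes), 0)
})
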
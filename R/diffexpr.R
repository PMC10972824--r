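# Differential expression between resistant (R) and sensitive (S) groups
# on the log2(TPM+1) scale, with an empirical-Bayes moderated t-statistic:
# per-gene pooled variances are shrunk toward a prior (s0^2, d0) estimated
# by method-of-moments on the log variances (the scaled-F model), and the
# moderated t is referred to a t distribution with d0 + d degrees of
# freedom. One inference engine serves both the transcript and protein
# branches of the analysis.

#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(x) = y`; used by the
#' method-of-moments fit of the variance prior.
#'
#' @param y positive values.
#' @return x with `trigamma(x) = y`.
#' @keywords internal
trigamma_inverse <- function(y) {
  stopifnot(all(y > 0))
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(-dif / x) < 1e-10) break
  }
  x
}

#' Fit a scaled-F prior to per-gene sample variances
#'
#' Method-of-moments on `log(s^2)` (Smyth-style): with
#' `e = log(s2) - digamma(d/2) + log(d/2)`, the prior degrees of freedom
#' solve `trigamma(d0/2) = var(e) - trigamma(d/2)` and the prior variance
#' is `exp(mean(e) + digamma(d0/2) - log(d0/2))`. Genes with zero residual
#' degrees of freedom or zero variance are excluded from the fit.
#'
#' @param s2 per-gene pooled variances.
#' @param d residual degrees of freedom (scalar or per-gene).
#' @return list with `df_prior` (possibly `Inf`) and `var_prior`.
#' @export
fit_variance_prior <- function(s2, d) {
  d <- rep(d, length.out = length(s2))
  ok <- is.finite(s2) & s2 > 0 & d > 0
  if (sum(ok) < 2) stop("need at least 2 genes with positive variance")
  s2 <- s2[ok]
  d <- d[ok]
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(d / 2))
  if (evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- exp(emean)
  }
  list(df_prior = df_prior, var_prior = var_prior)
}

#' Moderated two-sample t-test (resistant vs sensitive)
#'
#' Per gene: `logFC = mean(R) - mean(S)`; the pooled variance is shrunk to
#' `s2_post = (d0*s0^2 + d*s2) / (d0 + d)` and
#' `t = logFC / sqrt(s2_post * (1/nR + 1/nS))` with `d0 + d` degrees of
#' freedom. As `d0 -> 0` this is the ordinary pooled t; as `d0 -> Inf` the
#' denominator is the prior SD. Genes with zero variance in both groups are
#' flagged and their p set to 1 (never silently dropped).
#'
#' @param expression genes x samples matrix on the log2(TPM+1) scale.
#' @param resistant,sensitive column names of the two groups (>= 2 each).
#' @param prior_df,prior_var optional prior overrides; when `NULL` the
#'   prior is estimated with [fit_variance_prior()].
#' @return data frame of class `differential_result` with columns `gene`,
#'   `logFC`, `t`, `p`, `fdr`, `zero_variance`; the fitted prior is stored
#'   in attributes `df_prior` / `var_prior`.
#' @export
moderated_t_test <- function(expression, resistant, sensitive,
                             prior_df = NULL, prior_var = NULL) {
  stopifnot(is.matrix(expression),
            all(resistant %in% colnames(expression)),
            all(sensitive %in% colnames(expression)),
            length(resistant) >= 2, length(sensitive) >= 2,
            length(intersect(resistant, sensitive)) == 0)
  xr <- expression[, resistant, drop = FALSE]
  xs <- expression[, sensitive, drop = FALSE]
  n_r <- length(resistant)
  n_s <- length(sensitive)
  m_r <- rowMeans(xr)
  m_s <- rowMeans(xs)
  v_r <- rowSums((xr - m_r)^2) / (n_r - 1)
  v_s <- rowSums((xs - m_s)^2) / (n_s - 1)
  d <- n_r + n_s - 2
  s2 <- ((n_r - 1) * v_r + (n_s - 1) * v_s) / d
  logfc <- m_r - m_s

  if (is.null(prior_df) || is.null(prior_var)) {
    prior <- fit_variance_prior(s2, d)
    prior_df <- prior_df %||% prior$df_prior
    prior_var <- prior_var %||% prior$var_prior
  }
  s2_post <- if (is.infinite(prior_df)) {
    rep(prior_var, length(s2))
  } else {
    (prior_df * prior_var + d * s2) / (prior_df + d)
  }
  se <- sqrt(s2_post * (1 / n_r + 1 / n_s))
  tstat <- logfc / se
  df_total <- d + prior_df
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  zero_var <- s2 == 0
  p[zero_var] <- 1
  if (any(zero_var)) {
    message(sum(zero_var), " zero-variance gene(s) flagged with p = 1")
  }
  out <- data.frame(
    gene = rownames(expression) %||% as.character(seq_along(logfc)),
    logFC = unname(logfc),
    t = unname(tstat),
    p = unname(p),
    fdr = unname(bh_adjust(p)),
    zero_variance = unname(zero_var),
    stringsAsFactors = FALSE
  )
  attr(out, "df_prior") <- prior_df
  attr(out, "var_prior") <- prior_var
  attr(out, "df_total") <- df_total
  attr(out, "n") <- c(resistant = n_r, sensitive = n_s)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted values of the same length.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Select differentially expressed genes
#'
#' Gates a [moderated_t_test()] result at an FDR threshold and an absolute
#' fold-change threshold (defaults FDR < 0.01, |FC| > 2, i.e.
#' `|logFC| > log2(2) = 1`), assigning each gene a direction label.
#'
#' @param result `differential_result` data frame.
#' @param fdr FDR cut-off.
#' @param fc fold-change cut-off (linear scale, > 1).
#' @return list with `up`, `down` (gene vectors; up = higher in the first,
#'   resistant, group) and `table` (result with a `direction` column).
#' @export
select_deg <- function(result, fdr = 0.01, fc = 2) {
  stopifnot(all(c("gene", "logFC", "fdr") %in% colnames(result)), fc > 1)
  lfc <- log2(fc)
  dir <- rep("ns", nrow(result))
  dir[result$fdr < fdr & result$logFC > lfc] <- "up"
  dir[result$fdr < fdr & result$logFC < -lfc] <- "down"
  result$direction <- dir
  message("DEG selection: ", sum(dir == "up"), " up, ",
          sum(dir == "down"), " down of ", nrow(result), " genes")
  list(up = result$gene[dir == "up"],
       down = result$gene[dir == "down"],
       table = result)
}
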
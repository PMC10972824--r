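# Predictor evaluation: signature-score vs drug-response correlation and
# ROC/AUROC comparison of sensitivity predictors (signature activities vs
# the ordinal mutation score). Positives are the sensitive extreme, whose
# labels come from response data never fed to the predictors.

#' Correlate signature scores with drug response
#'
#' @param scores named per-line signature scores.
#' @param auc named per-line AUC values.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p` (two-sided, t approximation) and `n`.
#' @export
correlate_signature_auc <- function(scores, auc, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  common <- intersect(names(scores), names(auc))
  x <- scores[common]
  y <- auc[common]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0) stop("constant scores: predictor has no variance")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Area under the ROC curve
#'
#' Probability that a random positive outranks a random negative, with
#' ties counted one half (the Mann-Whitney identity, computed from
#' midranks).
#'
#' @param scores numeric predictor values.
#' @param labels binary labels (1/TRUE = positive).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Stepwise (FPR, TPR) curve from the +Inf threshold down; tied scores are
#' grouped so the trapezoidal area equals [auroc()] exactly.
#'
#' @inheritParams auroc
#' @return data frame with `threshold`, `fpr`, `tpr`, starting at (0, 0).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(labels & scores >= t), 0)
  fp <- vapply(thr, function(t) sum(!labels & scores >= t), 0)
  data.frame(threshold = c(Inf, thr),
             fpr = c(0, fp / n0),
             tpr = c(0, tp / n1))
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Compare sensitivity predictors by AUROC
#'
#' Evaluates each predictor column against a shared binary label vector,
#' with a seeded percentile-bootstrap confidence interval. Lines with any
#' missing predictor are dropped listwise (counted in a message).
#'
#' @param predictors lines x predictors numeric matrix or data frame.
#' @param labels named or aligned binary labels (1 = sensitive-extreme
#'   membership).
#' @param n_boot bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return data frame ranked by decreasing AUROC with columns `predictor`,
#'   `auroc`, `ci_lo`, `ci_hi`, `n`.
#' @export
compare_predictors <- function(predictors, labels, n_boot = 1000,
                               conf = 0.95, seed = 1) {
  predictors <- as.matrix(predictors)
  stopifnot(ncol(predictors) >= 1, nrow(predictors) == length(labels))
  ok <- stats::complete.cases(predictors)
  if (any(!ok)) {
    message(sum(!ok), " line(s) with missing predictors dropped listwise")
  }
  predictors <- predictors[ok, , drop = FALSE]
  if (is.null(colnames(predictors))) {
    colnames(predictors) <- paste0("predictor_", seq_len(ncol(predictors)))
  }
  labels <- as.logical(labels)[ok]
  alpha <- (1 - conf) / 2
  rows <- with_seed(seed, lapply(colnames(predictors), function(nm) {
    sc <- predictors[, nm]
    a <- auroc(sc, labels)
    boots <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(sc), replace = TRUE)
      if (length(unique(labels[idx])) < 2) return(NA_real_)
      auroc(sc[idx], labels[idx])
    }, numeric(1))
    ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE,
                          names = FALSE)
    data.frame(predictor = nm, auroc = a, ci_lo = ci[1], ci_hi = ci[2],
               n = length(sc), stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  out[order(-out$auroc, out$predictor), , drop = FALSE]
}
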
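# Stratification of cell lines into sensitive/resistant extremes by
# dose-response AUC, and distributional comparison utilities.

#' Assign cell lines to sensitivity groups by AUC extremes
#'
#' Lines in the lowest `fraction` of the AUC distribution are labelled
#' sensitive (low AUC = strong response), the highest `fraction` resistant,
#' and the remainder middle. Ties at a boundary are broken by a stable
#' sort on the line identifier so the assignment is deterministic.
#'
#' @param auc named numeric vector of per-line AUC values for one drug
#'   (or a drug-averaged AUC). Missing values are excluded and counted.
#' @param fraction decile-style fraction in (0, 0.5]; default 0.10.
#' @return list of class `sensitivity_groups` with elements `sensitive`,
#'   `resistant`, `middle` (line identifier vectors), `fraction`,
#'   `n_scored`, `n_missing`.
#' @export
assign_sensitivity_groups <- function(auc, fraction = 0.10) {
  if (!(fraction > 0 && fraction <= 0.5)) {
    stop("fraction must lie in (0, 0.5], got ", fraction)
  }
  stopifnot(!is.null(names(auc)))
  n_missing <- sum(is.na(auc))
  auc <- auc[!is.na(auc)]
  n <- length(auc)
  k <- floor(fraction * n)
  if (k < 2) stop("fewer than 2 lines per group (n = ", n,
                  ", fraction = ", fraction, ")")
  if (max(auc) == min(auc)) stop("all AUC values equal: no extremes definable")
  ord <- names(auc)[order(auc, names(auc))]
  groups <- list(
    sensitive = ord[seq_len(k)],
    resistant = ord[seq.int(n - k + 1, n)],
    middle = ord[seq.int(k + 1, n - k)],
    fraction = fraction,
    n_scored = n,
    n_missing = n_missing
  )
  if (n_missing > 0) message(n_missing, " line(s) without AUC excluded")
  structure(groups, class = "sensitivity_groups")
}

#' @export
print.sensitivity_groups <- function(x, ...) {
  cat("sensitivity_groups (fraction ", x$fraction, "): ",
      length(x$sensitive), " sensitive / ", length(x$resistant),
      " resistant / ", length(x$middle), " middle\n", sep = "")
  invisible(x)
}

#' Consensus sensitivity groups across several drugs
#'
#' A line is labelled sensitive (resistant) only if it falls in the
#' sensitive (resistant) extreme for every drug in `responses`.
#'
#' @param responses lines x drugs AUC matrix.
#' @param fraction as in [assign_sensitivity_groups()].
#' @return `sensitivity_groups` over the lines scored for all drugs.
#' @export
consensus_sensitivity_groups <- function(responses, fraction = 0.10) {
  stopifnot(is.matrix(responses), ncol(responses) >= 1)
  per_drug <- lapply(seq_len(ncol(responses)), function(j) {
    assign_sensitivity_groups(responses[, j], fraction)
  })
  sens <- Reduce(intersect, lapply(per_drug, `[[`, "sensitive"))
  res <- Reduce(intersect, lapply(per_drug, `[[`, "resistant"))
  all_lines <- Reduce(intersect, lapply(per_drug, function(g) {
    c(g$sensitive, g$middle, g$resistant)
  }))
  structure(list(
    sensitive = sens, resistant = res,
    middle = setdiff(all_lines, c(sens, res)),
    fraction = fraction, n_scored = length(all_lines),
    n_missing = sum(is.na(responses))
  ), class = "sensitivity_groups")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' comes from the asymptotic two-sample K-S distribution.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return list with `D` and `p`.
#' @export
ks_test <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("both samples must be non-empty")
  }
  res <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Pairwise drug-response correlation matrix
#'
#' Pearson correlations of per-line AUC between drugs, pairwise-complete;
#' a pair with fewer than `min_pairs` complete observations is NA with a
#' warning. Diagonal is 1.
#'
#' @param responses lines x drugs AUC matrix.
#' @param drugs drug names to include (default all).
#' @param min_pairs minimum complete pairs per drug pair (default 3).
#' @return symmetric drugs x drugs correlation matrix.
#' @export
drug_response_correlation <- function(responses, drugs = colnames(responses),
                                      min_pairs = 3) {
  stopifnot(is.matrix(responses), all(drugs %in% colnames(responses)))
  x <- responses[, drugs, drop = FALSE]
  d <- length(drugs)
  out <- diag(1, d)
  dimnames(out) <- list(drugs, drugs)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      if (j <= i) next
      ok <- stats::complete.cases(x[, c(i, j)])
      if (sum(ok) < min_pairs) {
        warning("fewer than ", min_pairs, " complete pairs for ",
                drugs[i], " vs ", drugs[j])
        out[i, j] <- out[j, i] <- NA_real_
      } else {
        out[i, j] <- out[j, i] <- stats::cor(x[ok, i], x[ok, j])
      }
    }
  }
  out
}
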
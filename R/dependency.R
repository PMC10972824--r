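# Differential gene dependency: knockout-effect scores (more negative =
# more essential) are compared between sensitive (S) and resistant (R)
# line groups with a per-gene Student t-statistic oriented as
# mean(S) - mean(R), so a low negative t marks a gene essential for
# S-line survival and a high positive t a gene essential for R-line
# survival -- the resistance-target end of the ranking.

#' Viability filter on knockout effects
#'
#' Keeps genes whose mean effect falls below `tau` (i.e. whose knockout
#' costs viability) in at least one of the two groups.
#'
#' @param effects genes x lines effect matrix.
#' @param sensitive,resistant line identifier vectors (non-empty).
#' @param tau effect threshold (default -0.5).
#' @return character vector of retained genes.
#' @export
viability_filter <- function(effects, sensitive, resistant, tau = -0.5) {
  stopifnot(is.matrix(effects), length(sensitive) > 0, length(resistant) > 0,
            all(c(sensitive, resistant) %in% colnames(effects)))
  m_s <- rowMeans(effects[, sensitive, drop = FALSE], na.rm = TRUE)
  m_r <- rowMeans(effects[, resistant, drop = FALSE], na.rm = TRUE)
  rownames(effects)[m_s < tau | m_r < tau]
}

#' Differential dependency between sensitivity groups
#'
#' Per gene, a two-sample t-test of effect scores computed as
#' `(mean_S - mean_R) / SE` (pooled Student variance by default, Welch by
#' flag), two-sided p, and BH FDR across the genes with at least
#' `min_obs` observations per group; genes below that are flagged and
#' excluded from the FDR.
#'
#' @param effects genes x lines effect matrix (missing effects dropped
#'   per gene).
#' @param sensitive,resistant line identifier vectors (>= 2 each).
#' @param welch use Welch's unequal-variance t instead of pooled Student.
#' @param min_obs minimum observations per group per gene (default 2).
#' @return data frame of class `dependency_result` with `gene`, `mean_s`,
#'   `mean_r`, `t`, `df`, `p`, `fdr`, `selectivity` ("S" for t < 0, "R"
#'   for t > 0), `flagged`.
#' @export
differential_dependency <- function(effects, sensitive, resistant,
                                    welch = FALSE, min_obs = 2) {
  stopifnot(is.matrix(effects), length(sensitive) >= 2, length(resistant) >= 2,
            all(c(sensitive, resistant) %in% colnames(effects)))
  xs <- effects[, sensitive, drop = FALSE]
  xr <- effects[, resistant, drop = FALSE]
  n_s <- rowSums(!is.na(xs))
  n_r <- rowSums(!is.na(xr))
  m_s <- rowMeans(xs, na.rm = TRUE)
  m_r <- rowMeans(xr, na.rm = TRUE)
  v_s <- rowSums((xs - m_s)^2, na.rm = TRUE) / pmax(n_s - 1, 1)
  v_r <- rowSums((xr - m_r)^2, na.rm = TRUE) / pmax(n_r - 1, 1)
  if (welch) {
    se2 <- v_s / n_s + v_r / n_r
    tstat <- (m_s - m_r) / sqrt(se2)
    df <- se2^2 / ((v_s / n_s)^2 / (n_s - 1) + (v_r / n_r)^2 / (n_r - 1))
  } else {
    df <- n_s + n_r - 2
    s2p <- ((n_s - 1) * v_s + (n_r - 1) * v_r) / df
    tstat <- (m_s - m_r) / sqrt(s2p * (1 / n_s + 1 / n_r))
  }
  p <- 2 * stats::pt(-abs(tstat), df = df)
  flagged <- n_s < min_obs | n_r < min_obs
  if (any(flagged)) {
    message(sum(flagged), " gene(s) with < ", min_obs,
            " observations in a group flagged and excluded from FDR")
    tstat[flagged] <- NA_real_
    p[flagged] <- NA_real_
  }
  fdr <- rep(NA_real_, length(p))
  fdr[!flagged] <- bh_adjust(p[!flagged])
  out <- data.frame(
    gene = rownames(effects) %||% as.character(seq_along(tstat)),
    mean_s = unname(m_s), mean_r = unname(m_r),
    t = unname(tstat), df = unname(df), p = unname(p), fdr = unname(fdr),
    selectivity = ifelse(is.na(tstat), NA_character_,
                         ifelse(tstat < 0, "S", "R")),
    flagged = unname(flagged),
    stringsAsFactors = FALSE
  )
  class(out) <- c("dependency_result", "data.frame")
  out
}

#' Nominate druggable resistance targets
#'
#' Ranks genes by decreasing dependency t (the R-selective end: genes
#' whose knockout selectively kills resistant lines), takes the top
#' `top_k`, and intersects with a user-supplied druggable-gene list.
#'
#' @param dep_result a [differential_dependency()] result.
#' @param druggable_genes non-empty character vector of druggable genes.
#' @param top_k how many top R-selective genes to consider (default 20).
#' @return data frame of candidates in rank order with `rank` (position
#'   within the top list), `gene`, `t`, `p`, `fdr`, `mean_s`, `mean_r`.
#'   Empty (with a warning) when the intersection is empty.
#' @export
nominate_targets <- function(dep_result, druggable_genes, top_k = 20) {
  stopifnot(inherits(dep_result, "data.frame"), length(druggable_genes) > 0)
  res <- dep_result[!is.na(dep_result$t), , drop = FALSE]
  res <- res[order(-res$t, res$gene), , drop = FALSE]
  if (top_k > nrow(res)) {
    message("top_k (", top_k, ") exceeds gene count (", nrow(res),
            "); considering all genes")
    top_k <- nrow(res)
  }
  top <- res[seq_len(top_k), , drop = FALSE]
  top$rank <- seq_len(nrow(top))
  hit <- top[top$gene %in% druggable_genes, , drop = FALSE]
  if (nrow(hit) == 0) {
    warning("no druggable gene among the top ", top_k,
            " R-selective genes", call. = FALSE)
  }
  rownames(hit) <- NULL
  hit[, c("rank", "gene", "t", "p", "fdr", "mean_s", "mean_r")]
}
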
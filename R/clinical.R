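# Clinical contrasts for altered vs unaltered patient groups: log-rank
# test, Cox proportional-hazards HR with Wald CI, paired tumor/normal
# t-test, and a Fisher-exact recurrence-rate contrast.

as_surv_df <- function(table) {
  stopifnot(all(c("time", "event") %in% colnames(table)))
  grp_col <- intersect(c("altered", "group"), colnames(table))[1]
  if (is.na(grp_col)) stop("survival table needs an 'altered' or 'group' column")
  df <- data.frame(time = table$time, event = table$event,
                   group = table[[grp_col]])
  stopifnot(all(is.finite(df$time)), all(df$time >= 0),
            all(df$event %in% c(0, 1)))
  if (sum(df$event) < 1) stop("at least one event is required")
  if (length(unique(df$group)) != 2) stop("exactly two groups are required")
  if (min(table(df$group)) < 1) stop("a group has zero subjects")
  df
}

#' Log-rank test between two survival groups
#'
#' Mantel-Haenszel observed-minus-expected statistic over the distinct
#' event times, referred to a chi-square with 1 df.
#'
#' @param table data frame with columns `time`, `event` (1 = event,
#'   0 = censored) and `altered` (or `group`).
#' @return list with `chi_square` and `p`.
#' @export
log_rank_test <- function(table) {
  df <- as_surv_df(table)
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chi <- unname(fit$chisq)
  list(chi_square = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards hazard ratio
#'
#' Partial-likelihood fit of a single binary covariate (Efron tie
#' handling by default, Breslow by flag); returns `HR = exp(beta)` with a
#' Wald confidence interval and p-value. Monotone-likelihood (complete
#' separation) fits are flagged rather than silently returned.
#'
#' @param table as in [log_rank_test()].
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf confidence level (fixed default 0.95).
#' @return list with `hr`, `ci` (length 2), `p`, `beta`, `se`, `flagged`.
#' @export
cox_hr <- function(table, ties = c("efron", "breslow"), conf = 0.95) {
  ties <- match.arg(ties)
  df <- as_surv_df(table)
  df$group <- as.numeric(factor(df$group)) - 1
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ group, data = df,
                    ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (!is.finite(beta)) stop("Cox fit did not converge")
  list(hr = exp(beta),
       ci = exp(c(beta - z * se, beta + z * se)),
       p = 2 * stats::pnorm(-abs(beta / se)),
       beta = beta, se = se, flagged = flagged)
}

#' Paired t-test
#'
#' One-sample t on the within-pair differences, two-sided. Zero-variance
#' nonzero differences are degenerate and raised as an error; identical
#' vectors give t = 0, p = 1.
#'
#' @param values_a,values_b paired numeric vectors of equal length (>= 2).
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t_test <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d <= 1e-12 * max(abs(d), 1)) {
    if (max(abs(d)) <= 1e-12) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    stop("zero-variance nonzero differences: paired t undefined")
  }
  tstat <- mean(d) / (sd_d / sqrt(n))
  list(t = tstat, df = n - 1,
       p = 2 * stats::pt(-abs(tstat), df = n - 1),
       mean_diff = mean(d))
}

#' Recurrence-rate contrast between two groups
#'
#' Per-group event rates for a binary outcome and the exact two-sided
#' Fisher p from the 2x2 table (the split rule that defines the groups --
#' e.g. a median split on expression -- is the caller's parameter).
#'
#' @param binary_outcome 0/1 outcome vector (e.g. recurrence).
#' @param group two-level group vector.
#' @return list with `rates` (named per-group), `table` (2x2) and `p`.
#' @export
recurrence_rate_contrast <- function(binary_outcome, group) {
  stopifnot(length(binary_outcome) == length(group),
            all(binary_outcome %in% c(0, 1)))
  group <- factor(group)
  if (nlevels(group) != 2) stop("exactly two groups are required")
  tab <- table(group, factor(binary_outcome, levels = c(0, 1)))
  rates <- tab[, "1"] / rowSums(tab)
  list(rates = stats::setNames(as.numeric(rates), levels(group)),
       table = tab,
       p = stats::fisher.test(tab)$p.value)
}

#' Median-split expression grouping
#'
#' Utility for expression-based patient grouping: labels subjects
#' `"high"`/`"low"` by comparison with a quantile cut (default median).
#'
#' @param values named numeric vector (e.g. one gene's expression).
#' @param probs quantile of the cut point (default 0.5).
#' @return named character vector of `"high"`/`"low"`.
#' @export
median_split <- function(values, probs = 0.5) {
  cut_at <- stats::quantile(values, probs, na.rm = TRUE)
  stats::setNames(ifelse(values > cut_at, "high", "low"), names(values))
}
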
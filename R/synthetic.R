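# Synthetic cancer-cell-line panels, perturbation experiments and survival
# cohorts with planted ground truth, so every downstream stage of the
# analysis can be scored against known answers.

#' Recipe for a synthetic cell-line panel
#'
#' Defines the statistical structure planted into [generate_panel()]: a
#' latent per-line drug-sensitivity trait drives both the dose-response AUC
#' (lower AUC = more sensitive) and the expression of a planted signature
#' gene set; in-domain oncogenic ("class V") mutations are preferentially
#' assigned to the sensitive tail; selected genes are planted as knockout
#' dependencies of the resistant or sensitive extreme.
#'
#' @param n_lines number of cell lines.
#' @param n_genes number of genes.
#' @param set_size size of the planted sensitivity-signature set.
#' @param n_decoy_sets number of decoy sets (same size, non-signature genes).
#' @param beta_sig effect size coupling signature expression to the latent
#'   sensitivity (expression decreases by `beta_sig` per latent SD as lines
#'   get more resistant).
#' @param auc_noise_sd SD of the AUC measurement noise around `0.5 * latent`.
#' @param expr_noise_sd SD of per-gene expression noise on the
#'   `log2(TPM+1)` scale.
#' @param frac_classV fraction of lines given an in-domain oncogenic
#'   (class-V) receptor mutation.
#' @param mut_ppv probability a class-V line is drawn from the sensitive
#'   (low-AUC) tail rather than uniformly.
#' @param background_mut_rates named per-line probabilities of background
#'   class II / III / IV mutations.
#' @param dep_depth depth (positive number) by which planted dependency
#'   genes are depressed in their designated group.
#' @param effect_noise_sd SD of baseline knockout-effect noise.
#' @param drugs drug names; all share the latent trait with independent noise.
#' @param seed integer seed fixing the full output.
#' @return a list of class `panel_recipe`.
#' @export
panel_recipe <- function(n_lines = 300, n_genes = 1000, set_size = 50,
                         n_decoy_sets = 20, beta_sig = 1,
                         auc_noise_sd = 0.3, expr_noise_sd = 1,
                         frac_classV = 0.1, mut_ppv = 0.3,
                         background_mut_rates = c(II = 0.15, III = 0.02, IV = 0.02),
                         dep_depth = 1, effect_noise_sd = 0.2,
                         drugs = c("EGFRi_1", "EGFRi_2", "EGFRi_3"),
                         seed = 1) {
  stopifnot(frac_classV > 0, frac_classV < 1, beta_sig >= 0,
            mut_ppv >= 0, mut_ppv <= 1, dep_depth >= 0,
            auc_noise_sd >= 0, expr_noise_sd >= 0)
  if (set_size > n_genes) stop("planted set larger than n_genes")
  structure(as.list(environment()), class = "panel_recipe")
}

classify_planted <- function(v, iii, iv, ii) {
  # precedence V > III > IV > II, matching the default ordinal mapping
  ifelse(v, "V", ifelse(iii, "III", ifelse(iv, "IV", ifelse(ii, "II", "none"))))
}

#' Generate a synthetic cell-line panel with planted structure
#'
#' Draws a latent sensitivity trait `s ~ N(0,1)` per line; each drug's AUC
#' is `0.5*s + noise` so low AUC means high sensitivity. Genes of the
#' planted signature set have expression `mu_g - beta_sig*s + noise` on the
#' `log2(TPM+1)` scale (higher expression in sensitive lines); all other
#' genes are pure noise around their baseline. Class-V mutations (in-domain,
#' oncogenic) are assigned to the low-AUC tail with probability `mut_ppv`,
#' otherwise uniformly; background class II/III/IV mutations are uniform.
#' Knockout-effect scores are near-zero noise except for the planted
#' dependency genes, depressed by `dep_depth` in their designated extreme
#' decile (resistant for the R-selective gene, sensitive for the
#' S-selective "EGFR-like" gene).
#'
#' @param recipe a [panel_recipe()].
#' @return a list of class `synthetic_panel` with elements `bundle`
#'   (a `panel_bundle`), `sets` (planted + decoy gene sets), `druggable`
#'   (gene list containing the planted R-selective target), and `truth`
#'   (latent trait, signature genes, dependency genes, per-line mutation
#'   class, sensitive/resistant tail line ids).
#' @export
generate_panel <- function(recipe = panel_recipe()) {
  stopifnot(inherits(recipe, "panel_recipe"))
  r <- recipe
  with_seed(r$seed, {
    genes <- sprintf("g%04d", seq_len(r$n_genes))
    lines <- sprintf("CL%04d", seq_len(r$n_lines))
    s <- stats::setNames(stats::rnorm(r$n_lines), lines)

    auc <- sapply(r$drugs, function(d) {
      0.5 * s + stats::rnorm(r$n_lines) * r$auc_noise_sd
    })
    dimnames(auc) <- list(lines, r$drugs)

    sig_genes <- genes[seq_len(r$set_size)]
    mu <- stats::runif(r$n_genes, 2, 8)
    expr <- matrix(mu, r$n_genes, r$n_lines) +
      matrix(stats::rnorm(r$n_genes * r$n_lines, sd = r$expr_noise_sd),
             r$n_genes, r$n_lines)
    expr[seq_len(r$set_size), ] <- expr[seq_len(r$set_size), , drop = FALSE] +
      matrix(-r$beta_sig * s, r$set_size, r$n_lines, byrow = TRUE)
    dimnames(expr) <- list(genes, lines)

    non_sig <- setdiff(genes, sig_genes)
    sets <- c(list(SENSITIVITY_SIGNATURE = sig_genes),
              stats::setNames(
                lapply(seq_len(r$n_decoy_sets), function(i) {
                  sample(non_sig, min(r$set_size, length(non_sig)))
                }),
                sprintf("DECOY_%02d", seq_len(r$n_decoy_sets))))

    # mutation planting: class V from the sensitive tail of drug 1
    auc1 <- auc[, 1]
    n_v <- round(r$frac_classV * r$n_lines)
    tail_size <- max(ceiling(0.1 * r$n_lines), n_v)
    low_tail <- lines[order(auc1, lines)][seq_len(tail_size)]
    is_v <- stats::setNames(logical(r$n_lines), lines)
    from_tail <- stats::runif(n_v) < r$mut_ppv
    pool_tail <- sample(low_tail)
    picked_tail <- pool_tail[seq_len(min(sum(from_tail), length(pool_tail)))]
    is_v[picked_tail] <- TRUE
    n_rest <- n_v - length(picked_tail)
    if (n_rest > 0) {
      is_v[sample(lines[!is_v], n_rest)] <- TRUE
    }
    rates <- r$background_mut_rates
    is_ii <- stats::runif(r$n_lines) < (rates[["II"]] %||% 0)
    is_iii <- stats::runif(r$n_lines) < (rates[["III"]] %||% 0)
    is_iv <- stats::runif(r$n_lines) < (rates[["IV"]] %||% 0)

    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    mk_change <- function(n, residues) {
      paste0(sample(aa, n, TRUE), sample(residues, n, TRUE), sample(aa, n, TRUE))
    }
    outside <- c(30:687, 876:1200)
    inside <- 688:875
    classV_changes <- c("L858R", "S768I", "L861Q", "G719S")
    rec_df <- function(which_lines, changes, onc) {
      n <- sum(which_lines)
      data.frame(cell_line = lines[which_lines],
                 gene = rep("EGFR", n),
                 protein_change = changes,
                 oncogenic = rep(onc, n), stringsAsFactors = FALSE)
    }
    recs <- rbind(
      rec_df(is_v, sample(classV_changes, sum(is_v), TRUE), TRUE),
      rec_df(is_ii, mk_change(sum(is_ii), outside), FALSE),
      rec_df(is_iii, mk_change(sum(is_iii), outside), TRUE),
      rec_df(is_iv, mk_change(sum(is_iv), inside), FALSE)
    )
    recs <- recs[order(recs$cell_line, recs$protein_change), , drop = FALSE]
    rownames(recs) <- NULL
    line_class <- stats::setNames(classify_planted(is_v, is_iii, is_iv, is_ii),
                                  lines)

    # knockout effects with planted selective dependencies
    k_tail <- floor(0.1 * r$n_lines)
    ord <- order(auc1, lines)
    sens_tail <- lines[ord][seq_len(k_tail)]
    resist_tail <- lines[rev(ord)][seq_len(k_tail)]
    dep_pool <- setdiff(non_sig, unlist(sets))
    if (length(dep_pool) < 2) dep_pool <- non_sig
    dep_genes <- data.frame(
      gene = sample(dep_pool, 2),
      selective = c("R", "S"),
      depth = r$dep_depth,
      stringsAsFactors = FALSE
    )
    effects <- matrix(stats::rnorm(r$n_genes * r$n_lines, sd = r$effect_noise_sd),
                      r$n_genes, r$n_lines, dimnames = list(genes, lines))
    effects[dep_genes$gene[1], resist_tail] <-
      effects[dep_genes$gene[1], resist_tail] - r$dep_depth
    effects[dep_genes$gene[2], sens_tail] <-
      effects[dep_genes$gene[2], sens_tail] - r$dep_depth

    druggable <- unique(c(dep_genes$gene[1],
                          sample(non_sig, min(30, length(non_sig)))))

    metadata <- data.frame(cell_line = lines, latent_sensitivity = unname(s),
                           mutation_class = unname(line_class),
                           stringsAsFactors = FALSE)
    bundle <- suppressMessages(
      intersect_bundle(expr, auc, mutations = recs, effects = effects,
                       metadata = metadata)
    )
    structure(list(
      bundle = bundle,
      sets = sets,
      druggable = druggable,
      truth = list(
        latent = s,
        signature_genes = sig_genes,
        dep_genes = dep_genes,
        mutation_class = line_class,
        sensitive_tail = sens_tail,
        resistant_tail = resist_tail
      ),
      recipe = r
    ), class = "synthetic_panel")
  })
}

#' Generate a synthetic drug-perturbation expression experiment
#'
#' Emulates an RNA-seq experiment on a resistant cell model under three
#' conditions (vehicle, drug, drug + co-inhibitor) where genes fall into
#' `k_clusters` planted clusters with distinct condition-mean profiles.
#' Cluster 2 is always the "up on drug, reversed by the co-inhibitor"
#' pattern and cluster 1 its mirror ("down on drug, reversed"), the two
#' patterns of principal biological interest; further clusters are
#' monotone or combination-only responses.
#'
#' @param n_genes number of genes (split evenly across clusters).
#' @param conditions condition names, in profile order.
#' @param n_rep replicates per condition.
#' @param k_clusters number of planted clusters (>= 2).
#' @param effect_size amplitude of the condition-mean profiles (z units).
#' @param noise_sd replicate noise SD.
#' @param set_coverage fraction of each cluster's genes included in its
#'   planted annotation set (for enrichment recovery).
#' @param seed integer seed.
#' @return list of class `perturbation_experiment` with `expression`
#'   (genes x samples), `condition` (per sample), `truth` (cluster per gene,
#'   index of the reversed-by-inhibitor cluster), and `sets` (per-cluster
#'   annotation sets plus decoys).
#' @export
generate_perturbation_experiment <- function(n_genes = 500,
                                             conditions = c("vehicle", "drug", "combo"),
                                             n_rep = 3, k_clusters = 5,
                                             effect_size = 2, noise_sd = 0.5,
                                             set_coverage = 0.6, seed = 1) {
  stopifnot(k_clusters >= 2, n_rep >= 2, length(conditions) == 3,
            n_genes >= k_clusters)
  with_seed(seed, {
    base_profiles <- rbind(
      c(0, -effect_size, 0),              # 1: down on drug, reversed
      c(0, effect_size, 0),               # 2: up on drug, reversed
      c(0, effect_size, effect_size),     # 3: up on drug, sustained
      c(0, -effect_size, -effect_size),   # 4: down on drug, sustained
      c(0, 0, effect_size)                # 5: combination-only induction
    )
    profiles <- if (k_clusters <= 5) {
      base_profiles[seq_len(k_clusters), , drop = FALSE]
    } else {
      rbind(base_profiles,
            matrix(stats::rnorm(3 * (k_clusters - 5), sd = effect_size),
                   k_clusters - 5, 3))
    }
    genes <- sprintf("pg%04d", seq_len(n_genes))
    cluster <- sort(rep(seq_len(k_clusters), length.out = n_genes))
    names(cluster) <- genes
    cond <- rep(conditions, each = n_rep)
    samples <- paste(cond, rep(seq_len(n_rep), times = length(conditions)),
                     sep = "_")
    mean_mat <- profiles[cluster, , drop = FALSE]        # genes x conditions
    expr <- mean_mat[, rep(seq_along(conditions), each = n_rep), drop = FALSE] +
      matrix(stats::rnorm(n_genes * length(samples), sd = noise_sd),
             n_genes, length(samples))
    dimnames(expr) <- list(genes, samples)
    sets <- lapply(seq_len(k_clusters), function(k) {
      g <- genes[cluster == k]
      sample(g, max(2, round(set_coverage * length(g))))
    })
    names(sets) <- sprintf("CLUSTER_SET_%d", seq_len(k_clusters))
    sets <- c(sets, list(DECOY_A = sample(genes, 30), DECOY_B = sample(genes, 30)))
    structure(list(
      expression = expr,
      condition = stats::setNames(cond, samples),
      truth = list(cluster = cluster, reversed_cluster = 2L,
                   profiles = profiles),
      sets = sets
    ), class = "perturbation_experiment")
  })
}

#' Generate a synthetic survival cohort
#'
#' Exponential event times with the hazard multiplied by `hr` for altered
#' subjects, and independent exponential censoring calibrated so that a
#' fraction `censor_rate` of the unaltered group is censored
#' (`censor_rate = 0` yields all events exactly).
#'
#' @param n cohort size.
#' @param hr hazard ratio of altered vs unaltered subjects (> 0).
#' @param alteration_freq fraction of altered subjects, in (0, 1).
#' @param censor_rate target censoring probability in the unaltered group.
#' @param baseline_hazard baseline exponential hazard rate.
#' @param seed integer seed.
#' @return data frame (class `survival_table`) with columns `subject`,
#'   `time`, `event` (1 = event, 0 = censored), `altered` (0/1), and an
#'   attribute `truth` holding the generating parameters.
#' @export
generate_survival_cohort <- function(n = 500, hr = 3, alteration_freq = 0.3,
                                     censor_rate = 0.2, baseline_hazard = 0.1,
                                     seed = 1) {
  stopifnot(hr > 0, alteration_freq > 0, alteration_freq < 1,
            censor_rate >= 0, censor_rate < 1, n >= 4)
  with_seed(seed, {
    altered <- stats::rbinom(n, 1, alteration_freq)
    t_event <- stats::rexp(n, rate = baseline_hazard * hr^altered)
    if (censor_rate > 0) {
      c_rate <- baseline_hazard * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(n, rate = c_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    tab <- data.frame(
      subject = sprintf("P%04d", seq_len(n)),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      altered = altered
    )
    attr(tab, "truth") <- list(hr = hr, alteration_freq = alteration_freq,
                               censor_rate = censor_rate,
                               baseline_hazard = baseline_hazard)
    class(tab) <- c("survival_table", "data.frame")
    tab
  })
}
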
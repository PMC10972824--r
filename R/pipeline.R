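# End-to-end orchestration: simulate (or ingest) a panel, stratify,
# differential expression, enrichment, per-sample scoring, predictor
# comparison, dependency nomination, perturbation clustering, survival
# contrast. Stages communicate through on-disk TSV/GMT artifacts and a
# JSON manifest records parameters, digests and warnings, so each stage
# is independently inspectable and a run is reproducible from its
# manifest.

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_all()]; any element
#' can be overridden. Thresholds follow the analysis conventions
#' (sensitivity decile fraction 0.10; DEG gates FDR < 0.01 and |FC| > 2;
#' GSEA set-size bounds 10-500). `gsea_nperm` defaults to 2000 for the
#' simulated demo panel; raise it for production rankings.
#'
#' @param seed integer master seed.
#' @return named list of class `depresist_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    fraction = 0.10,
    drug = NULL,                 # NULL = first drug column
    de_fdr = 0.01,
    de_fc = 2,
    gsea_nperm = 2000,
    gsea_min_size = 10,
    gsea_max_size = 500,
    gsea_weight = 1,
    ssgsea_alpha = 0.25,
    dep_tau = -0.5,
    dep_top_k = 20,
    cluster_k = 5,
    survival_n = 400,
    survival_hr = 3,
    survival_alteration_freq = 0.3,
    survival_censor_rate = 0.2,
    recipe = list()              # panel_recipe() overrides
  ), class = "depresist_config")
}

#' Validate a pipeline configuration
#'
#' @param config list as from [default_config()] (possibly edited) or a
#'   YAML/JSON file path.
#' @return the validated config, invisibly.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    base <- default_config()
    base[names(config)] <- config
    config <- base
  }
  check <- function(ok, field, why) {
    if (!ok) stop("invalid config field '", field, "': ", why, call. = FALSE)
  }
  check(is.numeric(config$fraction) && config$fraction > 0 &&
          config$fraction <= 0.5, "fraction", "must lie in (0, 0.5]")
  check(is.numeric(config$gsea_nperm) && config$gsea_nperm >= 100,
        "gsea_nperm", "must be >= 100")
  check(is.numeric(config$cluster_k) && config$cluster_k >= 2,
        "cluster_k", "must be >= 2")
  check(is.numeric(config$de_fdr) && config$de_fdr > 0 && config$de_fdr <= 1,
        "de_fdr", "must lie in (0, 1]")
  check(is.numeric(config$de_fc) && config$de_fc > 1,
        "de_fc", "must exceed 1")
  check(is.numeric(config$seed) && config$seed == round(config$seed),
        "seed", "must be an integer")
  invisible(config)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on a simulated panel
#'
#' Executes, in dependency order: panel simulation, sensitivity
#' stratification, moderated-t differential expression, DEG
#' over-representation, preranked GSEA on the t ranking with signed
#' pathway scores, per-line ssGSEA signature scoring with AUC correlation
#' (on the middle lines, excluding both extremes), AUROC predictor
#' comparison (signature scores vs ordinal mutation score), viability
#' filtering + differential dependency + druggable-target nomination,
#' perturbation-experiment clustering with per-cluster enrichment and
#' PCA, and a survival contrast (log-rank + Cox). Every stage writes its
#' artifact under `out_dir` and the manifest records config, digests and
#' timings. A stage failure aborts the run naming the stage.
#'
#' @param config a [default_config()]-style list (or YAML/JSON path).
#' @param out_dir output directory (created if missing).
#' @return the manifest (invisibly), also written to
#'   `out_dir/manifest.json`.
#' @export
run_all <- function(config = default_config(), out_dir = tempfile("depresist_")) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config[setdiff(names(config), "recipe")],
                   seed = config$seed, stages = list(), warnings = list())
  t_run <- function(stage, expr) {
    t0 <- Sys.time()
    value <- tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[stage]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    value
  }

  # -- simulate ---------------------------------------------------------
  panel <- t_run("simulate", {
    recipe <- do.call(panel_recipe, c(list(seed = config$seed), config$recipe))
    p <- generate_panel(recipe)
    write_matrix(p$bundle$expression, file.path(out_dir, "expression.tsv"))
    write_matrix(p$bundle$responses, file.path(out_dir, "responses.tsv"))
    write_matrix(p$bundle$effects, file.path(out_dir, "effects.tsv"))
    write_tsv(p$bundle$mutations, file.path(out_dir, "mutations.tsv"))
    write_gmt(p$sets, file.path(out_dir, "sets.gmt"))
    write_gene_list(p$druggable, file.path(out_dir, "druggable.txt"))
    jsonlite::write_json(
      list(signature_genes = p$truth$signature_genes,
           dep_genes = p$truth$dep_genes,
           mutation_class = as.list(p$truth$mutation_class)),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    p
  })
  bundle <- panel$bundle

  # -- stratify ---------------------------------------------------------
  groups <- t_run("stratify", {
    drug <- config$drug %||% colnames(bundle$responses)[1]
    g <- assign_sensitivity_groups(bundle$responses[, drug], config$fraction)
    tab <- data.frame(
      cell_line = c(g$sensitive, g$middle, g$resistant),
      group = rep(c("sensitive", "middle", "resistant"),
                  c(length(g$sensitive), length(g$middle), length(g$resistant))))
    write_tsv(tab[order(tab$cell_line), ], file.path(out_dir, "groups.tsv"))
    g
  })

  # -- differential expression -----------------------------------------
  de <- t_run("de", {
    res <- moderated_t_test(bundle$expression,
                            resistant = groups$resistant,
                            sensitive = groups$sensitive)
    sel <- select_deg(res, fdr = config$de_fdr, fc = config$de_fc)
    write_tsv(sel$table, file.path(out_dir, "de.tsv"))
    sel
  })

  # -- over-representation of DEGs -------------------------------------
  t_run("ora", {
    universe <- rownames(bundle$expression)
    res <- ora(unique(c(de$up, de$down)), panel$sets, universe)
    write_tsv(res, file.path(out_dir, "ora.tsv"))
    res
  })

  # -- GSEA on the t ranking -------------------------------------------
  gsea_res <- t_run("gsea", {
    stats_ranked <- stats::setNames(de$table$t, de$table$gene)
    res <- gsea(stats_ranked, panel$sets, nperm = config$gsea_nperm,
                min_size = config$gsea_min_size,
                max_size = config$gsea_max_size,
                weight_p = config$gsea_weight, seed = config$seed)
    res$pathway_score <- pathway_score(ifelse(is.na(res$NES), 0, res$NES),
                                       res$fdr,
                                       fdr_floor = 1 / (config$gsea_nperm + 1))
    write_tsv(res, file.path(out_dir, "gsea.tsv"))
    res
  })

  # -- ssGSEA signature scores + AUC correlation -----------------------
  sig_scores <- t_run("ssgsea", {
    sc <- ssgsea(bundle$expression, panel$sets, alpha = config$ssgsea_alpha)
    write_matrix(sc, file.path(out_dir, "ssgsea.tsv"))
    drug <- config$drug %||% colnames(bundle$responses)[1]
    mid <- groups$middle
    cors <- lapply(rownames(sc), function(nm) {
      ct <- correlate_signature_auc(sc[nm, mid],
                                    bundle$responses[mid, drug],
                                    method = "spearman")
      data.frame(set = nm, rho = ct$r, p = ct$p, n = ct$n)
    })
    write_tsv(do.call(rbind, cors), file.path(out_dir, "signature_auc.tsv"))
    sc
  })

  # -- predictor comparison --------------------------------------------
  t_run("predict", {
    lines <- bundle$lines
    mut_class <- cell_line_classes(bundle$mutations, lines)
    predictors <- cbind(t(sig_scores[c("SENSITIVITY_SIGNATURE",
                                       utils::head(setdiff(rownames(sig_scores),
                                                           "SENSITIVITY_SIGNATURE"), 2)),
                                     lines, drop = FALSE]),
                        mutation_score = mutation_score(mut_class[lines]))
    labels <- as.integer(lines %in% groups$sensitive)
    res <- compare_predictors(predictors, labels, n_boot = 200,
                              seed = config$seed)
    write_tsv(res, file.path(out_dir, "predictors.tsv"))
    rc <- roc_curve(predictors[, "SENSITIVITY_SIGNATURE"], labels)
    write_tsv(rc, file.path(out_dir, "roc_signature.tsv"))
    res
  })

  # -- dependency -------------------------------------------------------
  t_run("dependency", {
    keep <- viability_filter(bundle$effects, groups$sensitive,
                             groups$resistant, tau = config$dep_tau)
    dep <- differential_dependency(bundle$effects[keep, , drop = FALSE],
                                   groups$sensitive, groups$resistant)
    write_tsv(dep, file.path(out_dir, "dependency.tsv"))
    nom <- nominate_targets(dep, panel$druggable, top_k = config$dep_top_k)
    write_tsv(nom, file.path(out_dir, "targets.tsv"))
    nom
  })

  # -- perturbation clustering -----------------------------------------
  t_run("cluster", {
    exp_p <- generate_perturbation_experiment(k_clusters = config$cluster_k,
                                              seed = config$seed)
    prof <- average_replicates(exp_p$expression, exp_p$condition)
    z <- z_transform(prof)
    cl <- hierarchical_clusters(z, k = config$cluster_k)
    write_tsv(data.frame(gene = names(cl$assignment),
                         cluster = unname(cl$assignment)),
              file.path(out_dir, "clusters.tsv"))
    write_tsv(data.frame(step = seq_along(cl$merge_heights),
                         height = cl$merge_heights),
              file.path(out_dir, "linkage.tsv"))
    enr <- cluster_enrichment(cl, exp_p$sets)
    write_tsv(enr, file.path(out_dir, "cluster_enrichment.tsv"))
    pca <- pca_projection(z_transform(exp_p$expression), n_components = 2)
    write_tsv(data.frame(sample = rownames(pca$scores), pca$scores,
                         condition = exp_p$condition[rownames(pca$scores)]),
              file.path(out_dir, "pca.tsv"))
    cl
  })

  # -- survival ---------------------------------------------------------
  t_run("survival", {
    cohort <- generate_survival_cohort(n = config$survival_n,
                                       hr = config$survival_hr,
                                       alteration_freq = config$survival_alteration_freq,
                                       censor_rate = config$survival_censor_rate,
                                       seed = config$seed)
    write_tsv(cohort, file.path(out_dir, "survival_cohort.tsv"))
    lr <- log_rank_test(cohort)
    cx <- cox_hr(cohort)
    write_tsv(data.frame(statistic = c("logrank_chi_square", "logrank_p",
                                       "cox_hr", "cox_ci_lo", "cox_ci_hi",
                                       "cox_p"),
                         value = c(lr$chi_square, lr$p, cx$hr, cx$ci, cx$p)),
              file.path(out_dir, "survival.tsv"))
    list(logrank = lr, cox = cx)
  })

  # -- manifest ---------------------------------------------------------
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest$outputs <- stats::setNames(
    as.list(unname(tools::md5sum(outputs))), basename(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
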
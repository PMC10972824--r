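# depresist

Integrative pharmacogenomics for cancer cell line (CCL) panels:
discover transcriptomic signatures that predict sensitivity to a
targeted inhibitor beyond mutation status, and nominate druggable genes
whose knockout selectively kills the inhibitor-resistant lines.

## Who this is for

Computational biologists working with DepMap/CTRP/GDSC-style panel data:
a drug-response table (cell line x drug AUC, **lower AUC = more
sensitive**), an expression matrix on the `log2(TPM+1)` scale, a
mutation table with curated oncogenicity annotations, and a CRISPR
gene-effect matrix (**more negative = more essential**). A synthetic-data
generator reproduces the statistical shape of such a panel with planted
ground truth, so the whole pipeline runs and is testable with no
download.

## What it computes

- **Stratification** — sensitive (S) and resistant (R) extremes as the
  lowest/highest AUC deciles, deterministic under ties.
- **Mutation classes** — variants crossed by kinase-domain location
  (residue interval, default 688–875) and oncogenicity into classes
  II–V (`V` = in-domain + oncogenic, e.g. L858R), collapsed per line to
  an ordered score `none=0 < II=1 < IV=2 < III=3 < V=4`.
- **Moderated t differential expression** between R and S: per-gene
  pooled variance `s2` shrunk by an empirical-Bayes prior `(s0^2, d0)`
  fitted on the log variances,
  `t = logFC / sqrt(s2_post (1/nR + 1/nS))` on `d0 + d` df, BH FDR,
  gates FDR < 0.01 and |FC| > 2.
- **Enrichment** — exact hypergeometric ORA; preranked permutation GSEA
  (running-sum ES, gene-label null, NES, BH FDR; defaults
  nperm = 1e5, set sizes 10–500); ssGSEA per-sample activity scores
  (rank-weighted ECDF difference, `alpha = 0.25`); signed pathway score
  `sign(NES) * -log10(FDR)`.
- **Predictor comparison** — ROC/AUROC (Mann–Whitney, half-credit ties)
  of signature scores vs the ordinal mutation score for predicting
  S-membership, with bootstrap CIs.
- **Differential dependency** — per-gene Student t on knockout effects
  oriented `(mean_S - mean_R)/SE`, so the positive extreme marks genes
  essential specifically in resistant lines; top-k intersected with a
  druggable-gene list nominates resistance targets.
- **Perturbation clustering** — z-scored condition profiles, Euclidean
  complete-linkage clustering at K = 5, per-cluster ORA, PCA.
- **Clinical contrasts** — log-rank, Cox HR (Efron ties) with 95% CI,
  paired t, exact Fisher recurrence contrast.

## Worked example

```r
library(depresist)

panel  <- generate_panel(panel_recipe(seed = 1))     # 300 lines x 1000 genes
groups <- assign_sensitivity_groups(panel$bundle$responses[, "EGFRi_1"])
#> sensitivity_groups (fraction 0.1): 30 sensitive / 30 resistant / 240 middle

de  <- moderated_t_test(panel$bundle$expression,
                        groups$resistant, groups$sensitive)
deg <- select_deg(de, fdr = 0.01, fc = 2)
#> DEG selection: 0 up, 50 down of 1000 genes

scores <- ssgsea(panel$bundle$expression, panel$sets["SENSITIVITY_SIGNATURE"])
ct <- correlate_signature_auc(scores[1, groups$middle],
                              panel$bundle$responses[groups$middle, "EGFRi_1"],
                              method = "spearman")
c(rho = ct$r, p = ct$p, n = ct$n)
#>           rho             p             n
#> -7.152372e-01  6.685181e-39  2.400000e+02

lab <- panel$bundle$lines %in% groups$sensitive
mut <- mutation_score(cell_line_classes(panel$bundle$mutations,
                                        panel$bundle$lines))
auroc(scores[1, panel$bundle$lines], lab)   # 0.93
auroc(mut, lab)                             # 0.63

dep <- differential_dependency(panel$bundle$effects,
                               groups$sensitive, groups$resistant)
nominate_targets(dep, panel$druggable)
#>   rank  gene        t            p          fdr      mean_s    mean_r
#> 1    1 g0075 21.05343 7.621337e-29 3.810669e-26 0.008308492 -1.006512
```

Reading the output: the 50 planted signature genes are all recovered as
down-in-resistant DEGs; their ssGSEA activity score anticorrelates with
AUC (rho = −0.72), i.e. high signature activity marks sensitive lines;
as a predictor of the sensitive decile the signature (AUROC 0.93) beats
the ordinal mutation score (0.63), because only 30% of the planted
class-V mutations sit in the sensitive tail; and the planted druggable
R-essential gene (`g0075`, mean effect −1.0 in resistant lines vs ~0 in
sensitive) is nominated at rank 1.

`run_all(default_config(seed = 1), out_dir = "run/")` executes every
stage on a simulated panel, writing TSV/GMT artifacts plus a
`manifest.json` with config, seed and per-file digests; re-running with
the same seed reproduces every artifact byte-for-byte.

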
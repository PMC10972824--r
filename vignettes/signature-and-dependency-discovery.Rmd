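---
title: "Discovering drug-sensitivity signatures and resistance targets in cell-line panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering drug-sensitivity signatures and resistance targets in cell-line panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depresist)
```

## The analysis

`depresist` implements an integrative pharmacogenomic workflow for cancer
cell line (CCL) panels built around one question: what, beyond receptor
mutation status, marks a cell line as sensitive to a targeted kinase
inhibitor, and which genes could be drugged to kill the lines that resist
it? The workflow chains together:

1. **Stratification.** Per-line dose-response AUC values (lower AUC =
   greater sensitivity) define a sensitive extreme S (lowest decile by
   default) and a resistant extreme R (highest decile).
2. **Mutation classing.** Protein-changing variants are crossed by
   location (inside/outside a kinase-domain residue interval) and a
   curated oncogenicity flag into classes II–V; a line's class is
   collapsed to an ordered score.
3. **Differential expression.** A moderated t-test contrasts R vs S on
   `log2(TPM+1)` expression.
4. **Enrichment.** Hypergeometric over-representation of the gene lists,
   preranked permutation GSEA of the t ranking, single-sample GSEA
   (ssGSEA) activity scores per line, and a signed pathway score
   `sign(NES) * -log10(FDR)`.
5. **Prediction.** Signature scores and the ordinal mutation score are
   compared as predictors of S-membership by ROC/AUROC.
6. **Dependency.** CRISPR knockout effect scores (more negative = more
   essential) are contrasted between S and R per gene; the R-selective
   extreme of the t ranking, intersected with a druggable-gene list,
   nominates resistance targets.
7. **Perturbation clustering.** Genes are clustered (complete-linkage,
   Euclidean, K = 5) by their z-scored expression response to
   vehicle/drug/drug-plus-co-inhibitor treatment, and each cluster is
   annotated by over-representation.
8. **Clinical contrasts.** Log-rank and Cox proportional-hazards tests on
   altered vs unaltered survival cohorts; paired tumor/normal and
   Fisher-exact recurrence contrasts.

Every stage runs against synthetic panels with planted ground truth, so
recovery, calibration and determinism are testable end-to-end with no
external download.

## Models and estimators

### Sensitivity groups

For a drug with per-line AUC values, `assign_sensitivity_groups()` takes
the lowest `floor(f*n)` lines as S and the highest as R (`f = 0.10` by
default). Ties at a boundary are broken by a stable sort on the line
identifier, making the partition deterministic and invariant to any
order-preserving transform of AUC. Panels with several chemically similar
inhibitors can be stratified per drug or by consensus
(`consensus_sensitivity_groups()`, a line must reach the same extreme for
every drug); single-drug is the default because no canonical pooling rule
exists.

### Mutation classes and the ordered score

The kinase domain is a residue interval parameter (default 688–875,
approximating exons 18–21 of EGFR), not a hard-coded constant, because
domain definitions are annotation-dependent. A record inside the domain
with an oncogenic annotation is class V; inside without is IV; outside
with is III; outside without is II. Oncogenicity is always an input
column (OncoKB-style curated knowledge), never inferred. Lines with
several records take the class with the highest ordinal score; the
default mapping `none=0 < II=1 < IV=2 < III=3 < V=4` puts annotated
oncogenicity above location and is itself a configuration table, since
the ordering of the two middle classes is a modelling choice rather than
a biological fact. Widening the domain can only promote II→IV or III→V,
which the tests assert as a monotonicity property.

### Moderated t

With `nR`, `nS` samples and per-gene pooled variance `s2` on `d = nR +
nS - 2` degrees of freedom, the prior `(s0^2, d0)` is fitted by
method-of-moments on `log(s2)` under the scaled-F model, and

```
s2_post = (d0 * s0^2 + d * s2) / (d0 + d)
t       = logFC / sqrt(s2_post * (1/nR + 1/nS)),   df = d0 + d
```

with `logFC = mean(R) - mean(S)`. As `d0 -> 0` this reduces to the
ordinary pooled t, as `d0 -> Inf` to a prior-SD z-like statistic; both
limits are tested, and the full fit is cross-checked against the
reference empirical-Bayes implementation in limma. The same engine serves
transcript and protein inputs: working on `log2(TPM+1)` with a moderated
t (rather than a count-model Wald test) keeps one inference path for both
data types, at the cost of ignoring count-level mean-variance structure —
acceptable here because the downstream consumers (enrichment, signature
scoring) use only ranks and thresholded lists. Zero-variance genes are
flagged with `p = 1` and never dropped silently; genes with no residual
degrees of freedom are excluded from the prior fit. DEG gates default to
FDR < 0.01 and |fold change| > 2.

### Enrichment statistics

*ORA.* Upper-tail hypergeometric `P(X >= k)` with the set intersected
with the declared universe first. The implementation is exact and tested
against complete draw enumeration for small universes.

*GSEA.* The running-sum kernel weights hits by `|s|^p / sum |s|^p`
(default `p = 1`) and misses by `-1/(N-K)`; the ES is the signed maximum
deviation. Significance uses a gene-label permutation null (random
same-size gene draws re-weighted the same way), matching preranked-mode
practice: `p = (1 + #{same-sign |ES*| >= |ES|}) / (1 + #same-sign)`,
`NES = ES / mean(|ES*| same sign)`. Sets with no same-sign permutation
get `p = 1/(nperm+1)` and a flag. FDR is Benjamini–Hochberg across the
tested sets — simpler and better-defined than the original ES-pooling
scheme, and consistent with how FDR thresholds are applied elsewhere in
the pipeline; this divergence is deliberate. Default parameters are
`nperm = 1e5`, set sizes 10–500. The demo pipeline (`run_all()`) lowers
`nperm` to 2000, which changes only the granularity of permutation
p-values, not any ES/NES.

*ssGSEA.* Per sample, genes are ordered by decreasing expression (ties
broken by stable input order, which is logged behaviour rather than an
accident); members accumulate a rank-weighted step CDF with weights
`rank^alpha` (`alpha = 0.25`), non-members a uniform one, and the score
is the summed difference. Scores are optionally normalised by the
(max − min) over the run. A set occupying the top ranks achieves the
maximal score among same-size sets, verified exhaustively on small
profiles.

*Pathway score.* `sign(NES) * -log10(FDR)`, with the FDR floored at
`1/(nperm+1)` before the log so that permutation granularity, not a zero,
bounds the score.

### Predictor comparison

AUROC is computed from midranks (the Mann–Whitney identity, ties counted
one half), so `auroc(s) + auroc(-s) = 1` holds exactly and the stepwise
`roc_curve()` integrates to the same number. Positives are the sensitive
extreme; the labels come from response data that is never fed to any
predictor. `compare_predictors()` adds a seeded percentile bootstrap CI
(default 1000 replicates) because point AUROCs on a few dozen positives
are noisy.

### Differential dependency

Per gene, a Student (pooled) t oriented as `(mean_S - mean_R)/SE`, so a
negative t means the knockout selectively costs sensitive lines (the
"EGFR-like" end) and a positive t marks genes whose loss selectively
kills resistant lines. Welch's t is available by flag. A viability filter
(mean effect < `tau` in at least one group, default `tau = -0.5` — the
threshold is a knob, since no canonical value exists) removes genes whose
knockout is inert everywhere. `nominate_targets()` takes the top-k
(default 20) R-selective genes and intersects them with a user-supplied
druggable list; druggability is a membership test against that list, with
no network lookups.

### Perturbation clustering

Replicate columns are averaged per condition (raw-replicate input also
works), rows are z-scored (constant rows dropped with a warning; the
transform is idempotent), and genes are clustered by complete-linkage
hierarchical clustering on Euclidean distances, cut at K = 5. The
agglomeration is deterministic for a given input, with distance ties
resolved by the smallest row-index pair as in the standard
implementation. PCA of the samples uses centered SVD with each
component's sign fixed by its largest-magnitude loading.

### Survival contrasts

`log_rank_test()` is the Mantel–Haenszel statistic on 1 df;
`cox_hr()` fits the partial likelihood with Efron tie handling (Breslow
by flag; the two agree to 1e-8 without ties) and reports `exp(beta)` with
a 95% Wald CI. Monotone-likelihood fits are flagged. The paired
tumor/normal contrast is a plain paired t-test; recurrence contrasts use
the exact Fisher test on the 2x2 table, with the expression split rule
(median by default) exposed as a parameter.

## What the synthetic generators emulate

`generate_panel()` draws a latent sensitivity trait `s ~ N(0,1)` per line
and builds every data type from it:

- AUC per drug: `0.5*s + noise` (`auc_noise_sd = 0.3`), so the latent
  trait explains about three quarters of AUC variance — a deliberately
  clean but not noise-free panel. AUC is left unbounded because the
  pipeline only ever uses it ordinally.
- Expression: baseline `mu_g ~ U(2, 8)` on the `log2(TPM+1)` scale with
  unit noise; the 50 genes of the planted signature set additionally move
  by `-beta_sig * s` (default `beta_sig = 1`), i.e. they are higher in
  sensitive lines. Twenty decoy sets of the same size are drawn from the
  remaining genes. Expression is generated directly on the log scale
  rather than via counts, matching the scale the inference operates on.
- Mutations: a fraction `frac_classV = 0.1` of lines receives a canonical
  in-domain oncogenic variant (L858R, S768I, L861Q or G719S); each such
  line is drawn from the lowest-AUC decile with probability `mut_ppv`
  (default 0.3 — mutation status is an informative but imperfect marker,
  which is exactly the regime in which expression signatures add value).
  Background class II/III/IV variants are placed uniformly at rates
  0.15/0.02/0.02 per line.
- Knockout effects: near-zero noise (sd 0.2) except for one planted
  R-selective druggable gene and one planted S-selective gene, each
  depressed by `dep_depth = 1` in its extreme decile.

Defaults (300 lines, 1000 genes) are the package's desk-scale study
conditions; all recovery tests and the acceptance script run at or near
them. The generator does **not** emulate copy number, proteome-specific
noise, lineage structure, batch effects, or the correlated gene-gene
covariance of real expression panels — so passing recovery tests
demonstrates the correctness and calibration of the estimators under the
stated model, not their field performance on DepMap-scale data, where
printed metrics (e.g. published AUROC values) depend on the versioned
external databases themselves.

`generate_perturbation_experiment()` plants K condition-mean profiles
over vehicle/drug/combination (amplitude 2 z-units, replicate noise
0.5, 3 replicates): cluster 1 "down on drug, reversed by the
co-inhibitor", cluster 2 "up on drug, reversed", then sustained and
combination-only patterns. Per-cluster annotation sets cover 60% of each
cluster's genes so enrichment recovery is non-trivial.
`generate_survival_cohort()` uses exponential event times with the hazard
multiplied by `hr` for altered subjects and *independent* exponential
censoring calibrated so a fraction `censor_rate` of the unaltered group
is censored; independence matters, since censoring correlated with event
times would bias the Cox recovery experiments.

All generators restore the caller's RNG state and are pure functions of
their seed.

## Numerical choices and degenerate inputs

- Missing matrix cells read as missing, never zero; lines with missing
  AUC are excluded from stratification and counted.
- All-equal AUC has no extremes and is an error, as are fractions outside
  (0, 0.5] and groups smaller than 2.
- The trigamma inversion in the prior fit is a Newton iteration converged
  to 1e-10; a non-positive moment estimate yields an infinite prior df
  (complete shrinkage), the standard limiting case.
- Unparseable protein changes are routed to an "unparsed" report, not
  dropped.
- Permutation p-values use the +1 convention and are therefore never
  zero; GSEA determinism is per-seed exact.
- ORA p-values are discrete and conservative; under a random assignment
  their sub-0.05 fraction stays at or below the nominal rate, but they
  are not uniform, so null checks assert super-uniformity rather than a
  K-S match to the continuous uniform.
- `read_matrix` preserves trailing empty fields (a sentinel guards
  against delimiter-splitting dropping them) and reports ragged rows by
  line number and duplicate identifiers by name.

## Problem sizes

The shipped tests and the acceptance script use panels of 120–300 lines
and 300–2000 genes, 40–200 simulation seeds per recovery or calibration
experiment, GSEA at 300–2000 permutations, and survival cohorts of
80–500 subjects. These sizes were chosen so the full suite exercises
every planted-signal condition in a few minutes on one CPU while leaving
all recovery margins wide; production analyses would raise `nperm` to the
1e5 default and use the real panel dimensions.

## Known limitations

- The moderated-t substitution means count-level dispersion modelling
  (and therefore low-count shrinkage behaviour) is out of scope.
- GSEA supports gene-label permutation only; sample-label permutation
  (which preserves gene-gene correlation) is not implemented, and the
  BH-based GSEA FDR is a documented divergence from the ES-pooling
  original.
- Druggability is a static list membership; no target-tractability
  scoring.
- The survival module is univariate (single binary covariate); no
  multivariate Cox, competing risks, or KM plot rendering.
- Identifier handling is opaque-string, case-sensitive; no cell-line
  name harmonisation layer.
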
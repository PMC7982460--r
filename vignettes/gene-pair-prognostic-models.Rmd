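---
title: "Rank-based gene-pair prognostic models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair prognostic models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

`irgpairs` implements a prognostic modelling strategy for bulk tumour
transcriptomes in which the features are not gene expression values but
*within-sample binary comparisons of gene pairs*: the indicator for pair
(A, B) is 1 in a sample when A's expression exceeds B's, and 0 otherwise.
Because only the ordering of two genes inside one sample enters, the
feature is invariant to any monotone per-sample transformation —
normalisation pipelines, platform differences and library-size effects
cancel, which is what lets a model fitted on one cohort be applied
unchanged to another. Around that core the package provides the stages an
immune-focused study of this kind needs: moderated differential expression
between two anatomical groups (here labelled `left` and `right`),
single-sample immune/stromal scoring, a compact weighted co-expression
network to find the immune-correlated gene module, a module-membership /
gene-significance screen, Cox-based pair selection with an L1 penalty,
time-dependent ROC for the score cutoff, Kaplan–Meier validation, immune
deconvolution, and preranked gene-set enrichment.

## The model

For screened genes $g_1, \dots, g_m$, all $m(m-1)/2$ unordered pairs are
formed. The indicator for pair $k = (a, b)$ in sample $j$ is
$I_{kj} = \mathbf{1}\{x_{aj} > x_{bj}\}$, with ties scored 0. Pairs whose
minority class occurs in less than 20% of samples are removed (the closed
boundary keeps a pair at exactly 20%); a constant pair has median absolute
deviation 0 and is always removed. Each surviving pair is screened by a
univariate Cox proportional-hazards fit (Efron tie handling) at
$p < 0.05$; the retained indicators enter an L1-penalised Cox model whose
penalty is chosen by cross-validated partial-likelihood deviance averaged
over repeated random fold assignments. The risk score of sample $j$ is the
selected linear predictor

$$\mathrm{RS}_j = \sum_{k \in \text{model}} \beta_k I_{kj},$$

and patients with $\mathrm{RS} >$ cutoff are called high-risk (strictly
greater; a sample exactly at the cutoff is low-risk). The packaged
`published_prsm()` instance carries 16 pairs with printed coefficients and
the published cutoff 0.968, derived from a 5-year ROC curve.

## Parameters that matter

* `fc_threshold = 0.5`, `alpha = 0.05` (differential expression): absolute
  log2 fold-change and BH-adjusted p cut-offs. Fold change is the
  difference of group means on the log2 scale, oriented `right − left` by
  default and configurable via `reference`.
* `exponent = 0.25` (single-sample scoring): the rank-weight exponent of
  the original single-sample enrichment statistic; 0 gives the unweighted
  walk. Scores are reported unnormalised because only between-group
  contrasts and correlations are consumed downstream.
* `powers = 1:20`, `r2_target = 0.9` (network): the soft threshold is the
  smallest power whose connectivity distribution reaches the scale-free
  fit target, falling back to the best-fitting power with a warning.
* `min_module_size = 30`, `cut_height = NULL` (modules): undersized
  clusters are relabelled `grey`; see the cut-rule note below.
* `mm_min = 0.5`, `gs_min = 0.5` (gene screen): absolute module-membership
  and gene-significance thresholds.
* `min_minority_fraction = 0.2` (pair filter): closed lower bound on the
  minority-class frequency.
* `n_repeats`, `n_folds = 10`, `rule` (penalty selection): the deviance
  curve is averaged over `n_repeats` fold randomisations.
  `rule = "min"` (default) takes the deviance-minimising penalty and is
  deliberately permissive — the published model kept 16 of 69 screened
  pairs, which a sparser rule would not reproduce; `rule = "1se"` takes
  the sparsest model within one standard error and is the right choice
  when the goal is support recovery rather than prediction.
* `horizon` (time-dependent ROC): evaluation time in the unit of the
  survival table; the pipeline defaults to the median follow-up time. The
  optimal cutoff maximises Youden's J, ties resolved to the lower
  threshold.

## Numerical and design choices

**Moderated differential expression** delegates to limma's
empirical-Bayes variance shrinkage — shrinkage is the defining computation
of that method and re-deriving it would add nothing. Completely constant
genes are reported with fold change 0 and p 1 rather than as errors.

**Single-sample scores** are computed from average ranks (descending, top
gene carries the largest rank); the score is the summed difference between
the weighted in-set ECDF and the uniform out-of-set ECDF over the whole
ranking. When a set covers every gene the out-of-set ECDF is empty and
defined as 0.

**Scale-free fit binning.** The connectivity histogram uses ten
equal-width bins with log10(frequency) regressed on log10(mean
connectivity) over non-empty bins. Equal-count (quantile) bins are
unusable here: by construction every bin then has the same frequency and
the regression is degenerate.

**Static cut placement.** Average-linkage trees of `1 − TOM` separate
tight modules from the merges that join them by a pronounced gap in merge
heights. Cutting at a fixed fraction of the height range (e.g. 0.995)
fails in the realistic soft-power regime — between-module merges routinely
sit below 99.5% of the range, so everything collapses into one cluster.
The default is therefore a largest-gap rule: the cut is placed midway
across the biggest gap between consecutive merge heights. A fixed
fractional cut remains available through `cut_height` for users who want
the classical behaviour.

**Eigengene orientation.** The first principal component of a module's
gene-standardised expression has an arbitrary sign; it is oriented to
correlate positively with the module's mean expression profile so that
module membership has a stable interpretation.

**Gene significance** is the signed gene-trait correlation, screened on
absolute value. A signed −log10 p variant is stored alongside
(`gs_type = "logp"`), but a 0.5 threshold on a log-p scale is not
comparable to a 0.5 threshold on a correlation scale, so the correlation
definition is the default.

**Tie handling** in pair indicators is a literal "greater than": equal
expression scores 0 in both orientations. Canonical pair order is
lexicographic; a published model's own (irg1, irg2) orientation is
honoured as stored, because flipping a pair changes the meaning of its
coefficient's sign (`build_model_pairs()` constructs indicators in model
orientation).

**Time-dependent ROC** uses the cumulative-case / dynamic-control
definition with inverse probability-of-censoring weights from the
Kaplan–Meier estimate of the censoring distribution (left limits at case
times). This estimator is monotone by construction and collapses to the
empirical ROC when no observation is censored; both properties are
asserted in the tests. The subgroup-KM plug-in used by some older
implementations guarantees neither.

**Maximally selected cutpoints** scan every observed marker value inside
a quantile window (default 10%–90%) and return the split maximising the
two-group log-rank chi-square, ties to the lower cutpoint. No p-value
approximation for the maximal statistic is provided; downstream use only
needs the cutpoint.

**Deconvolution** solves a non-negative least-squares problem per sample
on the linear (un-logged) scale and renormalises the coefficients to
fractions; confidence is a Monte-Carlo permutation p (expression values
permuted across genes, add-one smoothing). NNLS is used in place of
ν-support-vector regression: it is deterministic, has no tuned
hyper-parameters, and recovers noise-free mixtures exactly, which makes
the estimator fully auditable.

**Preranked enrichment** implements the weighted Kolmogorov–Smirnov-style
running sum directly (evaluated only at hit-adjacent positions, which is
exact), with a gene-label permutation null, sign-matched normalisation and
tail p-values, and BH FDR across sets. The independent `fgsea`
implementation is used in the test suite as a cross-check of the
statistic, never as the computation.

**Single-predictor penalised fits**: the coordinate-descent path requires
at least two columns, so a one-pair input is fitted by the unpenalised
partial likelihood.

## The synthetic cohort generator

`cohort_spec()` / `generate_cohort()` produce cohorts with exactly the
structure the analysis assumes, with full ground truth:

* expression on the log2 scale from a latent-factor model — module $m$'s
  genes are $\mu_g + \sigma(\sqrt{\rho}\, f_m + \sqrt{1-\rho}\,\epsilon)$,
  so `within_module_cor` $\rho$ is the exact within-module correlation;
  one module's factor is recorded as the true immune score;
* a differential block: the first `n_de_genes` genes gain `de_log2fc` in
  group `right`, so with the defaults every module gene is differential —
  the structure the module-screening stage assumes;
* survival from an exponential proportional-hazards law whose linear
  predictor is a sum over planted pair indicators, evaluated with the same
  tie rule as the inference code, with uniform administrative censoring on
  $(0, 2/\texttt{censoring\_rate})$.

Two generator choices deserve emphasis. First, planted pairs are drawn
only among immune-module gene pairs whose baseline means differ by at most
a quarter of the noise standard deviation and whose members share DE
status: baseline-mismatched pairs yield near-constant indicators that the
imbalance filter would discard before any model could see them, and
mixed-DE pairs would confound the planted hazard with the group contrast.
Second, the cohort *design* — baseline means and planted-pair identity —
is drawn under a separate `design_seed`, so cohorts generated from the
same spec with different `seed`s share their prognostic truth. That is
precisely the setting needed to fit a model on one cohort and validate it
on an independent one.

Default study conditions: 200 samples per arm, 1,000 genes, 300
differential, four modules of 50 genes at $\rho = 0.7$, three planted
pairs with log-hazards (1.5, 1, −1), baseline hazard 0.05 events per time
unit, censoring intensity 0.02, unit noise. These are deliberately
desk-scale; the recovery experiments in the test suite run 5–20 seeds of
cohorts of this size (400 samples, up to 5,000 genes for the null
calibration) so the whole suite completes in minutes on one CPU.

What the generator does *not* emulate: count-level noise (everything is
generated directly on log2 scale, avoiding commitment to a count model),
batch or platform effects, real gene identifiers, non-proportional
hazards, and informative censoring. Passing recovery tests therefore
demonstrates that the implementation is correct under its stated
assumptions, not that the biological claims of any particular cohort
transfer.

## What the recovery experiments show

* Differential expression: ≥ 90% sensitivity at ≤ 10% empirical FDR over
  10 seeds at fold change 1.0 and noise 0.5 with 100 samples per arm.
* Module detection: the four planted modules are recovered essentially
  perfectly (adjusted Rand ≥ 0.7; in practice 1.0) at $\rho = 0.8$.
* Support recovery: with three planted pairs among 200 candidates and 400
  samples, repeated-CV lasso-Cox under the `1se` rule returns all three
  pairs in most seeds with almost no false positives. The `min` rule
  recovers the planted pairs at least as often but admits roughly ten
  additional pairs — the permissive behaviour expected of
  deviance-minimising selection and the reason it remains the pipeline's
  prediction default.
* Transfer: a model fitted and thresholded on one cohort separates
  high- from low-risk patients on an independent cohort of the same
  design (log-rank p < 0.01 in ≥ 18/20 seeds).
* Calibration: the univariate screen retains ≈ 5% of permuted null pairs,
  and moderated-t p-values are uniform on a no-effect cohort.

## Known limitations

* The co-expression core is deliberately compact: unsigned networks only,
  no eigengene-similarity module merging, no blockwise mode for very large
  gene sets, and a static (gap-based) cut rather than the full hybrid
  dynamic tree cut.
* The deconvolution stage ships with synthetic signatures for testing; any
  real analysis must supply a curated signature matrix.
* Survival handling assumes right censoring, proportional hazards and a
  single event type; no competing risks or time-varying covariates.
* Enrichment FDR is BH across sets, not the NES-stratified resampling FDR
  of the original GSEA.
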
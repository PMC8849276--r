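---
title: "Methods: matched case-control multi-omics discovery with csmomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched case-control multi-omics discovery with csmomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`csmomics` implements a discovery workflow for 1:1 matched case-control
multi-omics studies of inpatient mortality in complicated severe
malnutrition: cohort matching, targeted-platform quality control,
matched univariate screening, bootstrap stability selection, multilevel
discriminant modelling, differential correlation networks, and
unsupervised similarity-network fusion. This vignette documents the
statistical models, the tunable parameters and their defaults, the
synthetic-data model the test suite relies on, and the numerical and
design choices a maintainer should know about.

## The matched design

All supervised stages respect the pairing. Survivors (S) are matched
1:1 to nonsurvivors (NS) on admission age, HIV status and MUAC via
logistic propensity scores; `nearest_neighbor_match()` pairs greedily on
the *logit* of the score (distances on the probability scale compress
near 0/1; the logit is standard practice — the matching literature does
not dictate a unique choice). Cases are processed in descending
propensity order (hardest to match first) with lexicographic tie-breaks,
which makes the pairing deterministic and invariant to row order. No
caliper is applied by default; `caliper =` is available. Balance is
reported as standardized mean differences,
SMD = (mean_case − mean_control)/√((var_case + var_control)/2),
before and after matching, with categorical covariates expanded to
indicator proportions.

## Conditional logistic screening

For a 1:1 matched pair with case-minus-control difference vector
\(d_i\) on the autoscaled log concentrations, the conditional likelihood
contribution is \(\sigma(\beta^\top d_i)\) — algebraically an
intercept-free logistic regression on the differences with all
responses 1. `fit_clogit_1to1()` maximizes it by Newton-Raphson
(convergence when max |score| < 1e-8, at most 50 iterations, steps
capped at 5 per coordinate to keep separated likelihoods from
overshooting). Complete separation is detected by coefficient
divergence (|β| past 10 without score convergence); the estimate is
flagged and the p-value falls back to the score test at β = 0, which
remains well-defined. The test suite checks the fitter against a
brute-force grid maximization of the same likelihood and against
`survival::clogit`.

Per block, p-values are Benjamini-Hochberg adjusted (one family per
block, because the flagging criteria are block-specific: q < 0.01 for
metabolites, p < 0.05 for proteins and cytokines). Fold change is the
NS/S ratio of arithmetic group means on the raw concentration scale; a
geometric-mean option exists because the field uses both and the choice
is not canonical. Covariate adjustment (admission edema or WHZ) enters
the conditional likelihood as an additional difference term rather than
by residualizing, keeping the matched-design interpretation; the
residualization route (`residualize()`, OLS per analyte then
re-autoscaling) is used for the multivariable sensitivity analysis.

Metabolite ratios are derived analytes: sum(numerator)/sum(denominator)
per subject on raw concentrations. Four ratios are built in (Fischer's
ratio BCAA/(Tyr+Phe), the urea-cycle amino acid pool as a plain sum,
C2/C0, kynurenine/tryptophan); others are user-configurable. Only these
four are hard-coded because they are the ones named in the main
analyses this workflow supports; larger ratio panels differ per study.

## Stability selection

The multivariable screen is an elastic-net penalized logistic
regression (glmnet; mixing α = 0.75, the value used in this design)
wrapped in a bootstrap: matched pairs (not subjects) are resampled with
replacement B = 200 times, preserving the 1:1 structure and the 50%
case fraction in every resample. Within each bootstrap, λ is tuned on a
100-point log-spaced grid from λ_max down to 10⁻³ λ_max by 5-fold CV
misclassification at the 0.5 threshold, with whole pairs assigned to
folds and ties resolved to the largest (most parsimonious) λ. The
refit's nonzero support is recorded; analytes selected in strictly more
than 70% of the B fits are *influential*. Per-iteration RNG streams are
derived from the master seed, so the profile is reproducible and
order-independent. The differential set is the union of univariate
top-significant and influential analytes, with provenance labels.

Pair-level resampling is a design choice: subject-level resampling
would break pairs and reintroduce the confounding the matching removed.

## Multilevel PLS-DA

Between-pair variation is removed by `within_pair_decompose()`: each
row becomes its value minus its pair mean (± half the pair difference),
so column sums are exactly zero. `fit_plsda()` is NIPALS PLS1 against
the ±1-coded outcome: unit-norm weights \(w \propto X^\top y\), scores
\(t = Xw\), deflation by \(t p^\top\). Scores are mutually orthogonal
and deflation conserves the Frobenius norm — both asserted in tests.

Cross-validation assigns whole pairs to 10 folds; held-out pairs are
decomposed with *their own* pair means, which needs no label
information and is therefore legitimate at prediction time. Per repeat
(pooling its folds) we report AUC, misclassification at the 0
threshold, the training discounted R² (DR²) and the held-out
discriminant Q²,
\(DQ^2 = 1 - \sum e_{disc}^2 / \sum (y - \bar y)^2\), where the
residual of a prediction already past its correct class label
(\(y\,\hat y \ge 1\)) is discounted to zero — overshooting a correct
classification is not an error. DR² uses the same discounting on the
training side, which is what makes the reported DR² ≥ DQ² ordering
meaningful: both measure discriminant fit, one in-sample, one
out-of-sample. Summaries are mean ± SD over 50 repeats by default
(20 in the orchestrated pipeline, a runtime compromise at full cohort
scale). Components are fixed at 2 for reporting; the fit accepts any
`n_components` up to the rank.

## Differential correlation networks

Pearson correlations are computed per group over the differential
analytes plus all analyzed inflammatory mediators; within-group
significance is the t test on n−2 df, BH-adjusted over all pairs
*within each group separately* (the "significant in either group" gate
then ORs the two families). Group differences use the Fisher
z-statistic with per-group complete-observation counts. An edge
requires both the within-group gate (FDR < 0.05 in NS or S) and the
difference test (p < 0.05, unadjusted — the screening convention for
this secondary analysis; no additional multiplicity control is applied,
and the calibration test verifies the ~5% null edge rate). Edge
attributes: direction (strengthened/weakened in NS by |r|), sign of the
significant correlation, width |r_NS − r_S|; node degree counts
differential edges only.

The cross-block heatmap clusters analytes by average-linkage
agglomeration on 1 − r over pooled subjects (single linkage is exposed
for outlier inspection). The pooled-SCFA analysis sums propionate,
isobutyrate and butyrate per subject and correlates the pool with IL8
on the log10 scale, also reporting the above/below-median 2×2 table.

## Similarity network fusion

Per view, the affinity is the scaled exponential kernel
\(W_{ij} = \exp(-d_{ij}^2 / (\mu\,\varepsilon_{ij}))\) with the locally
adaptive bandwidth \(\varepsilon_{ij} = (\bar d_{i,K} + \bar d_{j,K} +
d_{ij})/3\). Omic views use standardized Euclidean distance on the
processed matrices; the clinical view (age, MUAC, WHZ, HIV, edema,
danger-sign flags) uses Gower distance to handle mixed types. Fusion
iterates \(P^{(v)} \leftarrow S^{(v)} \bar P^{(-v)} S^{(v)\top}\) with
re-symmetrization and re-normalization each step (row sums stay 1;
diagonal mass 1/2), K = 20 neighbours, μ = 0.5, t = 20 iterations —
conventional values for cohorts of ~200 subjects, all configurable.
Convergence (Frobenius change < 1e-4 at t) is checked and warned about,
not silently assumed.

Clustering is normalized-cut spectral clustering (top-k eigenvectors of
D^{-1/2} W D^{-1/2}, row-normalized, k-means with a fixed seed and 50
restarts) at k = 2 and k = 4.

Concordance of a view with the fused network is the normalized mutual
information between their spectral-cluster labels. Raw single-view
affinities are first *self-diffused* (the view's own K-NN kernel applied
t times) before clustering: on high-dimensional omic views, distances
concentrate and spectral clustering of the raw kernel is dominated by
noise, whereas the same local smoothing that fusion applies makes the
view's own cluster structure recoverable — without it, every view scores
near zero and concordance is uninformative. The pipeline also reports an
aggregate *biomolecular* concordance — the omics-only fusion versus the
full fusion — which is the quantity comparable to a combined
"biomolecular vs clinical" contribution statement; in the synthetic
cohort it consistently dominates the clinical concordance.

Deviation profiles stratify nonsurvivors by time to death (≤3, 4–7,
>7 days) and report Z = (mean_stratum − mean_S)/sd_S per analyte.

## The synthetic cohort generator

The generator is a first-class module: it defines the conditions under
which every statistical property of the pipeline is tested. Analyte
concentrations are log10-normal:

log10 x = m_g + b_pair + 1{NS}·δ_g·σ + ε,

with per-analyte baselines m_g (uniform on realistic per-block ranges:
1–300 µM metabolites, 10⁴–10⁷ reporter intensity, 3–300 pg/mL
cytokines), a pair-shared latent effect (ICC 0.3 of the within-group
variance — matched children share severity and exposure), within-group
SD σ = 0.25 log10 units (≈ 1.8-fold coefficient of variation, typical
of serum metabolites), and residuals correlated at ρ = 0.2 within
analyte class via a shared class factor. Differential analytes carry a
standardized shift δ drawn from ±[0.4, 1.0]: published fold changes for
analytes surviving FDR in studies of this size are ~1.3–1.6×, i.e.
|log10 FC| ≈ 0.1–0.2, which at σ = 0.25 is δ ≈ 0.4–0.8; the range was
fixed from that reasoning, not fitted to any test. Defaults follow the
study structure: 92 pairs; 206/229/29 analytes per block with 32/25/8
differential.

Missingness is mechanism-specific: metabolites are left-censored at a
per-analyte LOD (2% quantile; a configurable 8% of analytes are
censored at their median and thus fail the 80% detection rule by
construction), proteins get per-analyte Beta(2, 23)-distributed dropout
rates (mean 8%, so a realistic minority exceeds the 20% removal
threshold), and a third of cytokines are poorly detected (50% censored),
mirroring multiplex panel sensitivity limits. Proteins additionally
receive per-batch mean shifts (4 batches, SD 0.3 log10 units).
Differential-correlation ground truth is planted through group-specific
bivariate Gaussian copulas (r_S = 0.7, r_NS = 0 by default), hosted on
differential analytes when enough exist so the shifts are visible to the
differential-analyte network; host analytes keep their mean shift but
trade the pair effect for an exactly controlled group-wise correlation.
QC replicates are drawn so each analyte's *sample* CV equals its target
exactly (affine rescaling of the draws, with a positivity guard), making
the CV filter's behaviour deterministic given the drawn pass/fail mix
(25% failing by default).

What the generator does **not** emulate: instrument-level artifacts
(drift, isotope interference, peak-integration error), non-log-normal
heavy tails, informative missingness beyond left-censoring,
subject-level confounding of analytes with clinical covariates, and any
pathway-level structure beyond class correlation. Green tests therefore
certify the statistical machinery under a clean generative model — they
do not certify performance claims on real serum/plasma data, where
effect sizes are smaller and noise is structured.

## Numerical choices and degenerate inputs

- QC CV is computed on raw (not log) replicate values, sample SD over
  mean — the platform convention; zero-mean replicates give an
  undefined CV and the analyte is removed with reason `cv_fail`.
- "LOD/2" imputes half the limit of detection. Blocks without
  calibrated LODs (cytokines) fall back to half the minimum observed
  value, the common multiplex convention.
- kNN imputation uses Euclidean distance on shared observed analytes,
  RMS-normalized by the number of shared analytes so subjects with
  different missingness patterns are comparable; ties in distance break
  by subject order.
- Batch correction standardizes against the grand mean and the pooled
  within-batch variance, then applies parametric empirical-Bayes
  shrinkage of per-batch location/scale (normal / inverse-gamma priors,
  method-of-moments hyperparameters, iterated to 1e-8). Non-parametric
  shrinkage is intentionally out of scope. Without shrinkage, singleton
  batches are an error.
- Autoscaling drops zero-variance columns with a warning rather than
  erroring (synthetic edge cases and exact-fit residuals should not
  kill a pipeline run); "zero" is relative (sd ≤ 1e-10 · max|x|).
- The one imputation path is kNN for all blocks; the bagged-tree
  imputation sometimes used for a handful of samples in comparable
  studies is deliberately replaced by the same kNN imputer for
  uniformity and determinism.
- Elastic-net fits ride glmnet's coordinate descent along a path ending
  at the requested λ (single-λ fits are unreliable with warm starts);
  λ = 0 recovers the unpenalized MLE to 1e-4.
- Spectral clustering fixes the k-means seed (default 42) with 50
  restarts; given the seed the labels are deterministic.
- All stage seeds derive from one master seed via a fixed affine map
  mod 2³¹ − 1; bootstrap iterations and CV repeats get independent
  derived streams, so results are invariant to execution order.

## Pipeline orchestration

`run_pipeline()` executes simulate (or load) → preprocess → summarize →
univariate (+ ratios) → stability → union → PLS-DA → differential
network → SNF, writing each stage's artifact as flat TSV/JSON and
finishing with a manifest of parameters and MD5 hashes. Re-running with
the same seed reproduces every artifact byte-identically. Resumption is
coarse: a completed run with the same seed is recognized by its
manifest and not recomputed; per-stage resumption was considered and
dropped as complexity not paid for by the package's run times (the full
default-scale pipeline is ~40 s). Cytokines are filtered by the
detection rule only (they have no QC replicates in the default design)
and are screened univariately but excluded from stability selection,
which operates on the metabolite and protein blocks.

The cohort summary table reports mean ± SD with Welch t-tests for
continuous variables and n (%) with chi-square tests *without*
continuity correction for categorical ones (Fisher's exact test when a
2×2 cell is zero) — the uncorrected chi-square reproduces the
percentages-and-p-values style of admission tables most closely.

## Problem sizes in the test suite

Unit tests run on small cohorts (6–45 pairs, 8–100 analytes) so the
default suite completes in about three minutes. The deeper
property checks use the sizes at which their claims are stated: type-I
calibration pools three 1000-analyte null screens at 90 pairs;
stability-selection recovery runs ten seeds of the 90-pair, 100-analyte
planted design at B = 200; the permutation-null PLS-DA uses 20 label
permutations; network power uses ten seeds of 90-pair cohorts;
determinism runs the full default-scale pipeline twice. These sizes are
the package's own statement of where its guarantees are evaluated.

## Known limitations

- The conditional-logistic screen is exact only for 1:1 matching; m:n
  sets and exact conditional inference are out of scope.
- Stability selection reports selection frequencies, not
  Meinshausen-Bühlmann error bounds.
- The elastic-net stage models case/control labels unconditionally; the
  matched structure is honored through pair-level resampling and fold
  assignment, not through a conditional likelihood.
- SNF hyperparameters (K, μ, t) follow the canonical recommendations
  and are not tuned; the number of clusters is taken as given (2 and 4)
  rather than estimated by eigen-gap.
- Concordance values are NMI-based and comparable only within a run;
  they are ordering statements, not calibrated effect sizes.
- Pathway/overrepresentation analyses against external databases are
  intentionally outside the package; the univariate and ratio outputs
  are formatted so such tools can consume them.
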
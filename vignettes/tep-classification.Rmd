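---
title: "Classifying tumor-educated platelet RNA profiles: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tumor-educated platelet RNA profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Blood platelets take up tumor-derived RNA and alter their splicing programs
in the presence of a tumor ("tumor education"), so the platelet
transcriptome of a cancer patient differs measurably from that of a
cancer-free person. `tepclassify` implements a complete, testable pipeline
for developing and honestly evaluating platelet-RNA cancer classifiers from
a transcript-level read-count matrix and clinical metadata, in the setting
of a head-and-neck squamous cell carcinoma (HNSCC) case/control study with
propensity-matched controls: preprocessing, matching diagnostics, and two
independent classifier-development strategies — a particle-swarm-optimized
RBF-kernel SVM (PSO-SVM) and an iterated LASSO logistic-regression ensemble
with stability selection.

Because real platelet RNA-seq cohorts of this kind are controlled-access
clinical data, the package ships a first-class synthetic cohort generator
with known ground truth. Every claim the test suite makes about the
pipeline is a claim about its behavior on those synthetic cohorts.

## The synthetic cohort model

`generate_cohort()` draws a transcripts × samples count matrix from a
negative-binomial model,

    count[t, s] ~ NB(mu[t, s], dispersion)
    mu[t, s] = L_s * pi_t * 2^(case_s * beta_t) * 2^(male_s * gamma_t)

with `L_s` a log-normal library size, `pi_t` a softmax-normalized log-normal
baseline abundance, `beta_t` the planted case/control log2 fold-change
(nonzero on `n_informative` transcripts) and `gamma_t` a planted sex effect
on a disjoint transcript set. Variance follows the standard bulk RNA-seq
parameterization `mu + dispersion * mu^2`.

Defaults encode the emulated study design, chosen once and fixed:

* **101 matched pairs** — the cohort size after quality control in the
  emulated study design.
* **6,500 transcripts, `baseline_log_sd = 0.6`** — at the scaled-down median
  library size of 10⁶ reads (one tenth of a realistic sequencing depth, for
  desk-scale runtimes), the ">30 reads in >90% of samples" coverage filter
  retains roughly 5.5k transcripts, the expressed-transcript count the
  emulated study design calls for. The spread was calibrated empirically
  against the filter (larger spreads are more realistic for genome-wide
  annotation but, at a fixed mean depth per transcript, push far more of
  the catalogue below the coverage floor than a pre-filtered 6.5k-transcript
  universe should lose).
* **70% male cases vs 35% male controls** — the spouse-control design makes
  sex the one covariate matching cannot fix, so the RUV stage is genuinely
  exercised; 200 sex-effect transcripts at log2FC 1.5 by default.
* **35% early-stage cases, `stage_effect_scale = 0.5`** — early-stage tumors
  perturb platelets less; halving the planted effect for stage I/II cases
  reproduces the stage-dependent detectability that a real cohort shows.
* **Dispersion 0.2** — a typical bulk RNA-seq overdispersion magnitude.
* Clinical covariates (age, smoking status, pack-years, alcohol use) are
  drawn per *pair*: the control inherits the case's values plus small noise,
  emulating a cohort that was already matched on them.
  `generate_matching_pool()` instead draws an oversized, deliberately
  shifted control pool so the matching stage has real work to do.

What the generator does **not** emulate: read-level artifacts (mapping,
duplicates, intron-spanning read selection), transcript-transcript
correlation beyond what planted factors induce, batch structure, and any
real platelet biology of effect-size distributions — the planted spike
model is a stand-in, not a biological claim. Passing tests therefore show
that the pipeline's statistics behave correctly and leak no information,
not that any particular AUC is attainable on real platelets.

Null cohorts (`generate_null_cohort()`) force the case/control effect to
zero. The leakage-guard tests run them with `sex_lfc = 0` as well: given
the 70/35 sex imbalance, a sex expression effect is a *true* signal for
case status, not leakage, so leaving it in would invalidate a chance-level
band; sex handling is tested separately.

## Preprocessing

The filter chain follows the order: transcript coverage filter (count
strictly greater than 30 in strictly more than 90% of samples), sample
filters (fewer than 750 detected transcripts, or mean reads per transcript
below 1 — computed over the transcripts present in the matrix at that
point), then matched-pair enforcement (a sample whose partner failed QC is
dropped too). Both boundary behaviors are pinned by unit tests.

Normalization is TMM (`edgeR::calcNormFactors`) with the standard trims
(0.30 on M, 0.05 on A) and the upper-quartile-closest-to-mean reference
rule, followed by the log2-CPM transform
`log2((count + prior) / (libsize * factor + 2 * prior) * 1e6)` with
`prior_count = 1`. A straight-line implementation of the published TMM
formula lives in the test helpers and must agree to 1e-8.

### Removing unwanted variation (sex and library size)

`ruv_correct()` is a two-stage, known-covariate correction:

1. **Screen.** The top `k_max = 5` singular vectors of the row-centered
   matrix are tested for association with each nuisance covariate (Welch t
   for sex, Pearson correlation for log library size) at
   `assoc_alpha = 0.01`. Each factor's *partial* association with the
   protected covariate (group, adjusting for the nuisance covariates) is
   recorded for audit.
2. **Regress.** If any leading factor is contaminated, the flagged
   covariates' per-transcript contributions are removed by a joint linear
   fit that *includes the protected covariate in the design*, and only the
   nuisance terms are subtracted.

The regression stage is deliberate. In this study design sex and disease
status are correlated (70/35), so the sex direction in sample space is not
orthogonal to the group contrast. Deflating whole singular vectors would
either skip the sex factor (whenever its partial group association crosses
the screening threshold by the correlation just described) or strip the
correlated component of the disease contrast from every transcript —
measured as a 0.06–0.12 loss of downstream ensemble AUC against a sex-free
twin cohort. Group-protected regression removes exactly the
sex-attributable variation, preserves the group contrast by construction,
and is structurally idempotent: a second application finds no contaminated
factor and returns its input unchanged. When no factor is contaminated the
matrix is returned untouched, so nuisance-free data pass through exactly.

The protected-covariate test is partial rather than marginal for the same
reason: a purely sex-driven factor *is* marginally group-associated here,
and a marginal guard would protect precisely the factor the correction
exists to remove.

## Matching

`estimate_propensity()` is a plain logistic regression of case status on
age, smoking status, pack-years and alcohol use (ridge-stabilized via a
small L2 penalty if separation occurs). `match_nearest()` performs greedy
1:1 nearest-neighbor matching without replacement on the logit propensity,
with a caliper of 0.2 standard deviations of the logit score — the cited
matching convention. Cases are processed hardest-first (descending
propensity) and ties break by control identifier, making runs reproducible;
the original protocol does not state its processing order, so it is logged
and testable. Sex is deliberately excluded from the matching model,
mirroring the study design; it is handled by RUV downstream.
`balance_diagnostics()` reports pre/post standardized mean differences
(pooled-SD denominator; categorical covariates by level codes) plus t or
Wilcoxon p-values chosen by a Shapiro-Wilk normality check.

## PSO-SVM arm

Pairs are shuffled and split 40/30/30 into training/evaluation/validation
(floor per set, remainder to training — reproducing 41/30/30 and 67/34 from
101 pairs). Differential expression on the *training samples only* uses a
two-factor ANOVA (group + sex, no interaction; sex is the second factor
because it is the known residual confounder); the group main-effect F test
is computed for all transcripts through one shared QR decomposition, and
p-values are BH-adjusted.

The particle swarm searches (log10 FDR threshold, log2 cost, log2 gamma) in
the box 10⁻⁶..0.5 × 2⁻⁵..2¹⁵ × 2⁻¹⁵..2³, 50 particles × 10 iterations,
inertia 0.72, cognitive = social = 1.49, velocities clamped to half the box,
reflective boundaries — standard global-best constants at a desk-scale
budget (the source protocol does not state its swarm constants). A
particle's fitness is the evaluation-set AUC of an RBF-SVM trained on the
panel `q < threshold`; an empty panel scores 0. The best settings are then
locked and the SVM is refit on the training set and scored once on the
validation set. If the locked panel is empty — which happens on genuinely
null data, where no transcript clears any threshold in the box — the locked
classifier is the constant (prevalence) predictor, whose tied scores give
AUC exactly 0.5; this keeps the leakage guard well-defined instead of
erroring. Standardization uses training-set means and population SDs
(population, so that duplicating training samples provably changes
nothing); probability calibration is a sigmoid fit on training decision
values. Accuracy uses a fixed 0.5 threshold.

`cluster_enrichment()` reproduces the unsupervised check: Ward clustering
on 1 − Pearson correlation over the panel, cut at two clusters, two-sided
Fisher exact test of cluster vs case/control.

## Iterated LASSO arm

Each iteration re-splits the pairs 66/34 (iteration *i* uses seed
`base_seed + i`, so the ensemble is order-insensitive and reproducible),
fits an L1-penalized logistic regression on all preprocessed transcripts —
no FDR pre-filter — with λ chosen by 10-fold pair-preserving
cross-validation maximizing the pooled out-of-fold AUC over a 100-point
log-spaced grid from the data-derived λ_max down to 10⁻⁴λ_max (ties favor
the sparser model), refits at the chosen λ, and scores the held-out 34%.
Intercept-only iterations are recorded, never dropped. CV folds are
assigned at pair level, stratified by pair composition, and the fold count
shrinks with a warning if a stratum is too small.

Stability selection counts, per transcript, the models with a nonzero
coefficient and compares each count against a Binomial(n_iter, p₀) null
with p₀ = mean panel size / pool size — the "random selection" null made
explicit — using exact binomial tails, BH adjustment across the pool, and a
flag at FDR < 0.001. The summary also reports the smallest flagged count,
the analogue of a "selected at least 16 times" rule.

## Evaluation

AUC is the tie-aware rank statistic (Mann-Whitney, ties ½), with the ROC
staircase built at unique thresholds so its trapezoid area equals the rank
AUC to machine precision. Single-model confidence intervals use DeLong's
variance (via pROC); ensemble uncertainty is the 2.5–97.5 percentile range
of per-iteration AUCs, and per-sample "mean prediction scores" average each
sample's validation scores over the iterations that held it out. Subgroup
accuracy tables split cases by stage (I/II early vs III/IV advanced) or HPV
status, with controls as their own row; both single-model and
mean-score-ensemble inputs are accepted. `predict_covariate()` re-targets
the full LASSO machinery at a clinical covariate (HPV status among
oropharyngeal cases, each sample its own unit), and
`downsample_experiment()` reruns the ensemble on a random pair-preserving
subcohort.

## Numerical and testing choices

* Problem sizes in the test suite: leakage and signal-recovery checks run
  100 pairs × 2,000 transcripts with 100-iteration ensembles and 50×10
  swarms; confounder checks run 60 pairs × 1,200 transcripts with
  25-iteration ensembles; oracle checks run on toys. These sizes keep a
  full run on one CPU in the tens of minutes while leaving the sampling
  distributions tight enough for the property bands.
* All randomness flows through explicit seeds; generators and ensembles
  restore the caller's RNG state.
* Independent oracles (a straight-line TMM implementation, exhaustive
  pairwise AUC, closed-form BH, hypergeometric Fisher enumeration, an IRLS
  + coordinate-descent LASSO solver, a brute-force greedy matcher, a grid
  search over the swarm's box, Monte-Carlo binomial tails) live in the test
  helpers and share no code with the package.
* Monte-Carlo comparisons use the standard error implied by the exact
  probability being checked, so the bound cannot collapse when the empirical
  tail count is zero.

## Known limitations

* **The binomial stability null is anticonservative under resampling.**
  The 66/34 iterations share most of their training samples, so transcripts
  that are accidentally group-correlated in the *fixed* cohort are
  re-selected far more often than independent random selection predicts. On
  pure-null cohorts the flagged set at FDR < 0.001 is orders of magnitude
  larger than the nominal expectation, even though held-out AUC stays at
  chance. Flagged counts should therefore be read as "selected more often
  than independent random choice", not as FDR-controlled discoveries; a
  permutation-based null (relabeling within pairs) would be the rigorous
  alternative and is out of scope here.
* The CV-AUC-maximizing λ rule almost always selects a non-empty, overfit
  panel on null data (the held-out evaluation is what keeps the pipeline
  honest); a one-standard-error rule would be more conservative but is not
  what the emulated protocol specifies.
* The RUV stage corrects only *known* nuisance covariates; latent batch
  structure is out of scope.
* Greedy matching is not optimal matching; with a hostile pool the
  unmatched-case list should be inspected.
* Accuracies at the fixed 0.5 threshold depend on the sigmoid calibration
  being sensible; AUCs do not.
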
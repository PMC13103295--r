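---
title: "Connectome-based predictive modeling with cpmtools: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based predictive modeling with cpmtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmtools)
```

## The model

Connectome-based predictive modeling (CPM) predicts a continuous behavioral
score — here an Internet Addiction Test-like severity scale bounded to
[20, 100] — from resting-state functional connectivity. The pipeline is:

1. **Edges.** For each subject, functional connectivity is the Pearson
   correlation between the time courses of every pair of atlas nodes,
   variance-stabilized with Fisher's transform $z = \operatorname{atanh}(r)$.
   An $N$-node symmetric matrix becomes a vector of $N(N-1)/2$ edges in a
   fixed row-major upper-triangle order; self-connections are never features.
2. **Selection.** Within a training set, each edge is correlated with the
   behavioral score; edges with a two-sided $p$ below a threshold (default
   $p < 0.01$) are retained and routed by the sign of $r$ into a *positive
   network* and a *negative network*. With covariates $X$ (age, sex, mean
   framewise displacement) the association is the partial correlation given
   $X$: both edge and behavior are residualized against $(1, X)$ and the
   residuals correlated, with $p$ from
   $t = r\sqrt{\mathrm{df}/(1-r^2)}$, $\mathrm{df} = n - 2 - k$.
3. **Strength and regression.** Each subject's selected edges are collapsed
   to a *network strength* — the sum (default) or mean of the masked edge
   values — and behavior is regressed on strength by ordinary least squares:
   positive-only, negative-only, and a combined model with both strengths as
   independent variables.
4. **Evaluation.** Leave-one-out cross-validation repeats selection *and*
   fitting inside every fold; out-of-fold predictions are scored by the
   Pearson correlation $r$ with observed scores (parametric two-sided $p$),
   and RMSE. Headline significance comes from a permutation test that
   shuffles behavior and reruns the entire cross-validated pipeline.
5. **Transfer.** External validation applies a stored model — masks and
   coefficients frozen — to an independent sample, with no reselection.
6. **Anatomy.** Selected edges are summarized over ten canonical networks
   (MF, FP, DMN, Mot, VI, VII, Vas, SAL, SC, CBL): a symmetric 10×10
   within/between count matrix, incidence-based per-network totals, and node
   degrees with a strict display threshold (default degree > 30).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold_p` | 0.01 | edge-selection threshold on the two-sided p-value |
| `covariate_mode` | `"partial"` | partial correlation given age/sex/motion, or `"none"` |
| `aggregate` | `"sum"` | strength aggregation; `"mean"` only rescales the predictor, and refit predictions are unchanged (a tested invariance) |
| `scheme` | `"loocv"` | cross-validation scheme; `kfold` with `k = n` reproduces LOOCV exactly |
| `n_perm` | 1000 | permutations for the significance test |
| `min_degree` | 30 | strict node-degree display threshold |

Motion QC excludes subjects with maximum translation > 2.5 mm, maximum
rotation > 2.5°, or mean framewise displacement > 0.2 mm — strict
inequalities, OR-combined, so values exactly at a threshold are kept.

Design choices that were genuinely open, and how they were settled:

* **Selection sidedness.** Two-sided p-values with sign routing: selecting
  "significantly positive" and "significantly negative" edges separately is
  exactly a two-sided test split by sign, and keeps one threshold parameter.
* **Covariate handling.** Adjustment enters at the *selection* stage as
  partial correlation (the standard covariate-aware CPM variant); the
  strength regression itself is not residualized. Both selection modes are
  exposed; `"partial"` is the default.
* **Combined model.** A two-predictor OLS on (positive, negative) strengths,
  not the pos-minus-neg difference variant.
* **Cross-validation scheme.** LOOCV is the default; k-fold is exposed. (A
  "1000-fold" scheme is not realizable for cohorts smaller than 1000; LOOCV
  is the canonical CPM protocol.)
* **Empty-mask folds.** A fold whose mask is empty predicts the training-set
  behavior mean for that model, and the event is counted, so a
  cross-validation result always covers every subject. When *all* folds are
  empty the predictions are constant and their correlation with observed
  scores is undefined; `evaluate_predictions()` then reports $r = 0$,
  $p = 1$ by convention.
* **Permutation p.** One-sided (the alternative is positive predictive
  correlation) with the add-one formula
  $p = (1 + \#\{r_{null} \ge r_{obs}\})/(1 + n_{perm})$, which never returns 0.
  Covariates stay attached to the imaging data; only behavior labels move.
* **Network totals.** Incidence counting: a between-network edge credits
  both endpoint networks, so totals across networks may exceed the mask
  size. This is the convention under which a single hub network can hold the
  large majority of a tail's connections; partition-style within-network
  counting is available via `rank_networks(count = "within")`.
* **Tie-breaks.** Network rankings break ties by the fixed canonical label
  order, so output is deterministic.

## Numerical choices

* Fisher transform: input clipped to $\pm(1 - 10^{-7})$ with a warning
  before `atanh`, so degenerate correlations cannot produce infinities.
* Matrix symmetry is validated at $10^{-8}$; edge vectorization is a
  bijection on symmetric zero-diagonal matrices.
* Zero-variance edges are excluded from selection with a warning and can
  never enter a mask; collinear positive/negative strengths
  ($|r| > 1 - 10^{-10}$) make the combined model fall back to positive-only.
* The LOOCV engine with `covariate_mode = "none"` uses exact
  sufficient-statistic downdating (the held-out subject's contribution is
  subtracted from globally centered full-sample sums) and applies the
  selection rule as $|r| > r_{crit}$ with
  $r_{crit} = t_c/\sqrt{\mathrm{df} + t_c^2}$,
  $t_c = \mathrm{qt}(1 - p/2, \mathrm{df})$ — the same decision boundary as
  $p < $ threshold, at a fraction of the cost. A test verifies fold-by-fold
  agreement with a naive re-select/re-fit loop (masks identical,
  predictions to $10^{-10}$).

## What the generator emulates — and what it does not

The synthetic generator (`generator_config()` / `generate_dataset()`)
defines the study conditions all tests run under. Behavior is drawn from
Normal(60.34, 16.31) truncated to [20, 100] by rejection — the severity
distribution of a large discovery cohort on this scale. Edges are generated
*directly in Fisher-z space*: each edge has a population baseline
(Normal(0.25, 0.10) across edges) plus independent Gaussian subject noise
(SD 0.3 z-units, a typical between-subject spread for resting-state FC).
Planted positive edges add $\beta \cdot \tilde{b}$ (standardized behavior),
negative edges $-\beta$, with
$\beta = \sigma \rho / \sqrt{1 - \rho^2}$ so the population edge-behavior
correlation is exactly the configured `effect_r`. Covariates are always
generated (age ≈ Normal(22.3, 2), sex ≈ Bernoulli(0.69) loosely matching a
predominantly male cohort, motion summaries kept under the QC thresholds);
with `confound_strength > 0` a latent linear combination of them couples to
behavior *and* to a disjoint confound-only edge set, producing spurious
marginal correlations that vanish under partial correlation — the scenario
covariate-adjusted selection exists for.

Deliberately not modeled: hemodynamics and autocorrelated BOLD noise,
spatial autocorrelation between neighboring parcels, edge-edge dependence
beyond the shared behavioral factor, scanner/site effects, and any claim
about *which* anatomical edges carry real-world severity signal. Passing
recovery and power tests therefore shows the pipeline is correct and well
calibrated under an idealized independent-edge world — not that any
particular empirical effect size is attainable on real fMRI data. A small
latent-factor time-series mode (`simulate_timeseries()`) exists for
connectivity round-trip testing only.

`effect_r` is a free simulation parameter: no per-edge empirical effect size
is available to estimate it from, so recovery results are reported as a
function of it rather than as a claim about any real cohort.

## Problem sizes used by the test suite

Edge counts must be triangular numbers $N(N-1)/2$, so the suite uses
32 nodes (496 edges) for its "≈500-edge" problems and 25 nodes (300 edges
exactly) elsewhere. The standing conditions are: selection calibration on
20 null cohorts of n = 100; recovery on 20 cohorts of n = 300 with 20 + 20
edges planted at `effect_r = 0.4`; permutation calibration on 100 null
cohorts of n = 80 with 200 permutations each; power at n = 300 over 20
seeds; transfer with discovery n = 400 / external n = 70 over 20 seed
pairs. The acceptance script (`scripts/acceptance.R`) recomputes the same
quantities at moderately reduced replicate counts.

## A worked miniature

```{r example}
cfg <- generator_config(n_subjects = 120, n_nodes = 25, effect_r = 0.4,
                        seed = 7)
sim <- generate_dataset(cfg)
cv <- run_cv(sim$dataset, threshold_p = 0.01, covariate_mode = "partial")
cv
masks <- select_edges(sim$dataset, 0.01, "partial")
rank_networks(summarize_mask(masks, sim$dataset$atlas, "positive"))
```

## Known limitations

* LOOCV correlation is a noisy, slightly pessimistic estimator under the
  null (its expectation is below zero); the permutation test, which reruns
  the full pipeline, is the calibrated significance reference.
* Partial-correlation selection assumes linear covariate effects.
* The generator's independent-edge noise makes selection behave close to
  its nominal calibration; correlated edges in real data inflate the
  effective number of discoveries per true source.
* No nested tuning of `threshold_p`: it is a fixed protocol parameter, and
  no familywise correction is applied across the three models.
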
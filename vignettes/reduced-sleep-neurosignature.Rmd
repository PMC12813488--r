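---
title: "Methods: building and transporting a reduced-sleep neurosignature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and transporting a reduced-sleep neurosignature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage assumes, which parameters matter, what
the synthetic cohorts do and do not emulate, and where the design was
genuinely open.

## 1. From time series to connectomes

A subject contributes one or more resting-state runs, each a volumes ×
parcels matrix with a framewise-displacement (FD) trace and a nuisance
regressor table. The cleaning model is a single multiple regression per
parcel whose design contains: an intercept, a linear trend, the nuisance
columns, a discrete-cosine basis spanning frequencies below the high-pass
cutoff, and one spike regressor per censored volume. Running everything in
one step avoids the order-dependence of sequential regression/filtering,
and the spike regressors guarantee censored volumes carry exactly zero
residual; those rows are additionally excluded from the correlation.

Tunable parameters, with defaults:

* `threshold_mm = 0.5` — FD censoring threshold (mm). A volume exactly at
  the threshold is kept: the rule censors volumes *exceeding* it.
* `min_minutes = 4` — minimum retained duration for a run to count.
  Retention is `sum(mask) * TR >= 240 s`, so a run whose nominal length
  equals the floor is discarded by a single censored frame — cohort
  configurations should leave margin above the floor.
* `highpass_hz = 0.008` — cutoff of the cosine basis. The basis size is
  `floor(2 * T * TR * f)`; for short runs it can be empty, which simply
  disables filtering.

Per run, Pearson correlations over retained volumes are Fisher-transformed
(`atanh`) and averaged across eligible runs. Edges live in a single fixed
row-major upper-triangle order; every persisted table carries the parcel
count, ordering tag, and network labels in its header, and every dot
product checks them first. Global signal regression is deliberately
absent. Correlations of magnitude one are clipped to 1 − 1e−7 before the
transform, with a warning, since they otherwise map to infinity.

## 2. The latent sleep-duration factor

Three duration indicators — parent-reported, child-reported, and a
wearable-device measure — load on a single latent factor. With three
indicators the model is just-identified: loadings follow the closed form
λ₁ = √(r₁₂·r₁₃/r₂₃) (and rotations), the fitted model reproduces the
observed correlations exactly, and no fit indices exist. All pairwise
correlations must be positive; an implied loading ≥ 1 aborts with a
Heywood error naming the triad. `stats::factanal` gives the same loadings
on this model and serves as an independent cross-check in the tests.

Open choices we fixed:

* **Scoring.** The scoring method was open; we use regression (Thurstone)
  scores, w = R⁻¹λ, the default of the standard factor-analysis lineage.
  Their ceiling correlation with the truth is the determinacy
  √(λᵀR⁻¹λ), which the recovery tests use as their reference.
* **Orientation.** The modeling target is *reduced* sleep: the negated
  duration score, so that positive signature expression means a
  shorter-sleep-like connectome.
* **Weighted averages.** Where weekday/weekend durations are combined we
  use the standard 5:2 school-day convention.

## 3. Principal component regression with the 1-SE rule

Edges enter PCA centered but not per-edge scaled — all edges already share
the Fisher-z scale, and rescaling would inflate low-variance edges. OLS on
the first K orthogonal component scores gives betas independent of K, so
the inner cross-validation evaluates the whole component grid from one
decomposition per fold.

* **Component grid**: powers-of-2 style (1, 2, 4, …) capped at
  min(n/10, 250) and always including 21, the count used by the paired
  contrast signature for parity.
* **Inner CV**: 5 folds, grouped by site when the training sites allow,
  mean squared error as the loss. The selected K is the smallest grid
  value whose mean error is within one standard error (taken at the
  argmin) of the minimum.
* **Outer evaluation**: leave-one-site-out. Covariates (sex, age, age²,
  mean FD, mean FD²) are residualized with coefficients fitted on the
  training sites only, then applied to the held-out site; fitting them
  jointly would leak held-out covariate means into training. Whether the
  *features* should also be residualized (not only the target) was open;
  both are supported (`residualize_X`), default residualizes both.
* **Final signature**: refit on the full sample with K equal to the
  rounded (half-up) mean of the per-fold counts; weights = V_K β collapse
  the model into one edge map. For interpretation the Haufe transform
  converts these decoding weights into an activation pattern,
  Cov(X)w / Var(Xw) — equal, per edge, to its covariance with the
  predicted score.

## 4. Permutation inference

Significance of the multivariate association uses Freedman–Lane: fit the
reduced (covariates-only) model, permute its residuals, add back the
fitted values, and recompute the statistic on each pseudo-outcome. The
permutations respect a nested block tree — subjects never cross sites,
families swap positions only with same-sized families within their site,
and members (including twins) shuffle within families. The p-value uses
(b+1)/(B+1) counting, so B = 10,000 can report at best p ≈ 0.0001.

The permuted statistic was an open choice: refitting the entire LOSO
pipeline per permutation is faithful but expensive. The default statistic
keeps the pipeline fixed — features, PCA basis, and K are held at their
observed values; only the component betas are refit against each
pseudo-outcome — and measures the in-sample multivariate r. Any callable
statistic can be substituted, including a full LOSO refit.

## 5. Expression transport

An expression score is the raw dot product of signature weights with a
connectome's edge vector; it is linear and only meaningful under an
identical edge ordering, which is enforced, never silently repaired.

* **Longitudinal model**: change-score formulation — Δexpression on
  Δsleep with a site random intercept, controlling for age difference
  (linear, quadratic), motion at each timepoint (linear, quadratic), and
  sex. Both sides are z-scored on the analysis sample first, so the
  reported coefficient is a standardized beta and is invariant to affine
  rescaling of the raw units. A singular random-effect fit falls back to
  OLS with site-clustered robust errors, flagged in the output. We chose
  the change-score model over a two-timepoint random-slope model because
  the outcome of interest is itself the within-subject change.
* **Deprivation contrast**: per-subject difference (deprived − typical)
  regressed on an intercept plus mean-centered covariates (sex, age
  group, motion on each scan); the intercept is the covariate-adjusted
  mean difference and its t statistic is the reported test.

## 6. Spatial correspondence

The paired-design contrast signature residualizes every connectome against
sex, age group, and per-scan motion, runs one PCA on the stacked
(both-session) residuals, takes per-subject differences of component
scores, and multiplies the mean difference through the first K = 21
loadings. The correspondence statistic is the Pearson correlation across
edges between this map and the cross-sectional signature's Haufe pattern
(pattern-vs-pattern was our default since both are covariance-scale maps;
the raw weight map is switchable).

The null rebuilds both maps at each of B iterations: target scores
shuffled across subjects on the cross-sectional side (PCA basis fixed;
betas refit), session labels coin-flipped within pair on the paired side
(which negates that subject's score-difference contribution — an algebraic
identity the tests assert). The p-value is one-sided (greater) by default;
sidedness was unstated in the design space, and a two-sided option is
provided.

## 7. What the synthetic cohorts emulate

The generators exist because the analysis must be testable end-to-end
without restricted data. They emulate, by construction:

* community-structured connectomes — parcel time series drawn from a
  network-block correlation matrix (within-network r = 0.35, between
  r = 0.08 by default), so the connectome-construction code path is
  exercised for real, not bypassed with matrices sampled directly;
* a planted sleep effect confined to within-somatomotor (+0.10 z per SD
  of reduced sleep) and within-visual (−0.08) edges — the ground-truth
  map every recovery test compares against;
* a one-factor measurement model with loadings (0.8, 0.6, 0.5);
* site/family/twin nesting (default twin fraction 0.2) with a
  family-shared component in the latent variable;
* motion confounding — mean FD rises as latent sleep falls, and FD
  inflates global signal variance volume-wise (strength 0.2), with
  high-FD spike volumes that must be censored;
* two-timepoint and paired-deprivation variants sharing the same planted
  pattern.

Effect sizes were set once to be clearly detectable at the hundreds-of-
subjects scale the examples use: the synthetic r_cv (≈ 0.8 at n = 600) is
intentionally stronger than anything plausible in real cohort data, where
true effects are diluted by measurement breadth, scanner heterogeneity,
and behavioral noise the generator does not model. Passing tests therefore
demonstrate the *machinery* — recovery of planted structure, calibration
of nulls, direction of transported effects — not the field-realistic
magnitude of sleep-connectivity associations. Other non-goals: no
hemodynamics, spatial maps, volumetric images, or realistic indicator
marginals (the duration indicators are Gaussian on an hour-like scale).

One modeling note: the latent-to-motion coupling and variance-inflation
confound make connectivity correlate with sleep through motion even under
a null planted effect; null-calibration tests therefore switch the
confound off, while covariate-control tests leave it on.

For the longitudinal stage, the standardized coupling cannot be planted
exactly through the imaging path (connectome sampling noise attenuates it
by an amount that depends on scan length), so the mixed-model recovery
check uses a score-level generator that fixes the true standardized
coefficient by construction (residual variance chosen so the outcome has
unit variance); the imaging path is validated separately for direction
and null behavior.

## 8. Numerical choices and degenerate inputs

* Correlation clipping at |r| = 1 − 1e−7 before `atanh`.
* Rank checks everywhere K meets data: requested components beyond the
  numerical rank (singular values below 1e−10 of the largest) are errors.
* Collinear cleaning-design columns are dropped with a warning; collinear
  covariates are an error (they indicate a misspecified model rather than
  an over-rich scrub).
* Non-positive-definite subject correlation matrices (possible after
  planting large effects) are repaired by eigenvalue clipping at 1e−6
  followed by re-normalization to unit diagonal.
* Degenerate LOSO folds (zero-variance predictions, empty grids) yield NA
  for that site with a warning rather than aborting the whole evaluation.
* Mean-K rounding is half-up; ties go to the larger model.
* Every generator derives child seeds deterministically from one master
  seed, so identical configurations are byte-identical.

## 9. Problem sizes used by the tests and scripts

The test suite and the acceptance script size their cohorts to what the
statistical property under test needs: 600 subjects × 30 parcels × 6
sites for signature recovery; 400 replicates at B = 200 for type-I
calibration of the permutation test; n = 1500 for recovering a 0.10
standardized coupling (SE ≈ 0.026); 76 pairs for the deprivation
contrast; B = 500–2000 for permutation p-values; and compact acquisitions
(one or two 120-volume runs at TR = 2.4 s) where the full 4 × 375-volume
layout adds nothing to the property being checked.

## 10. Known limitations

* The generator's Gaussianity and block-uniform effects are idealized;
  real edge distributions are heavier-tailed and effects graded.
* The permutation statistic default (fixed pipeline, in-sample r) is
  anti-conservative relative to refitting component selection per
  permutation only insofar as selection adapts to the outcome; with the
  1-SE rule and site-grouped folds this adaptation is weak, but the
  conservative route remains available.
* The family permutation policy treats all family members as
  exchangeable; designs with mixed twin/non-twin families needing
  distinct within-family policies would require extending the block tree
  by one level.
* Expression scores are raw dot products (no centering), so their
  absolute level is arbitrary; only within-sample contrasts and
  associations are interpretable.
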
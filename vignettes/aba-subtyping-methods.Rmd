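---
title: "Methods: brain-age models, ABA/RBA stratification, and polytope subtyping"
author: "abasubtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-age models, ABA/RBA stratification, and polytope subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in **abasubtypes**, the
assumptions behind them, the tunable parameters, and the design choices made
where the methodology was genuinely open. It states no empirical result that
the package's tests and `scripts/acceptance.R` do not themselves compute.

## 1. The scientific problem

Brains age at different rates. The brain-age paradigm fits a regression model
predicting chronological age from imaging-derived phenotypes (IDPs) in a
reference population; the residual deviation of a new subject — the brain-age
gap (BrainAGE = predicted age − chronological age) — indexes whether that
brain looks older or younger than expected. Subjects whose BrainAGE is
positive in *all three* MRI modalities (structural, diffusion,
resting-state-functional) are labelled **accelerated brain aging (ABA)**;
consistently negative subjects are **resilient (RBA)**; everything else is
MIXED and excluded. Accelerated aging is heterogeneous: the package's core is
a semi-supervised clustering (HYDRA) that subdivides the ABA group into
subtypes by contrasting it against the RBA reference with a convex polytope
of linear max-margin classifiers, each face capturing one multivariate
pattern of accelerated aging.

## 2. Brain-age prediction

One model per modality (`fit_brainage()`), trained on its own IDP block only:

* Features are standardized with training means/SDs (constant features are
  dropped and recorded by name). Standardization makes the fit invariant to
  affine rescaling of any input.
* The predictor is Lasso regression (via **glmnet**; with a Gaussian loss the
  glmnet `lambda` equals the conventional Lasso `alpha` on the
  `(1/2n)·RSS + alpha·l1` scale). The penalty is selected from the grid
  `0.001, 0.01, 0.1, 1, 10, 100` by 5-fold cross-validation minimizing mean
  absolute error (MAE). The fold count for the grid search is a convention:
  the selection rule is not fixed by the methodology we follow, so we use the
  same 5-fold scheme as the clustering stage, with ties broken toward the
  larger penalty (more regularization).
* **Age-bias correction.** Predicted age regresses toward the training mean,
  so the raw gap correlates negatively with age. The correction fits, on the
  training set only, an ordinary least-squares line of raw predictions on
  chronological age (intercept `alpha`, slope `beta`) and forms
  `raw − alpha − beta·age`. As printed, this quantity is a regression
  residual, not an age on the original scale; whether it is used directly as
  the corrected BrainAGE or first rescaled to an age is ambiguous in the
  source methodology. Both behaviours are implemented behind
  `correction_mode`:
  * `"residual"` (default): the residual *is* the corrected BrainAGE. This
    matches the magnitude of reported subtype BrainAGE values (±6–11 years)
    and is all the stratification needs, since only the sign enters.
  * `"rescale"`: `(raw − alpha)/beta` is a corrected predicted age;
    BrainAGE is then that value minus age. Requires `beta` bounded away
    from 0.
  * `"none"`: no correction.

  By OLS orthogonality, residual-mode corrected values have exactly zero mean
  and zero correlation with age on the training set; on held-out data the
  correlation is small but not exactly zero.

## 3. Stratification

`stratify()` labels a subject ABA iff BrainAGE > 0 in all three modalities
and RBA iff BrainAGE < 0 in all three, using strict inequalities: an exact
zero (a measure-zero event for continuous predictors) maps to MIXED, since
the methodology says only "positive"/"negative" without a tie rule.
Stratification is applied to the test set only; the brain-age models never
see those subjects during training. Useful laws, asserted in the tests: the
three labels partition the input; negating all BrainAGE vectors swaps the
ABA and RBA counts exactly; and with independent symmetric errors across
modalities the expected ABA fraction is (1/2)³ = 0.125.

## 4. HYDRA: convex-polytope subtyping

`hydra()` separates the reference group from the target (ABA) group with `K`
linear max-margin classifiers whose positive half-space intersection forms a
convex polytope enclosing the reference; each face defines one subtype.

**Covariate residualization** (`residualize_covariates()`): each IDP is
regressed on age, sex and years of education by OLS *fitted on the reference
group only*; residuals are computed for everyone with those coefficients and
standardized by the reference residual SD. The source methodology states
both that covariates were "regressed out" and "considered during the
process"; we implement residualization as preprocessing (flag-controlled),
the reading that keeps the clustering objective unchanged. Education enters
as years directly.

**Base classifier.** Each face is a weighted squared-hinge soft-margin
linear classifier
`0.5·||w||² + C · Σ s_i · max(0, 1 − y_i(w·x_i + b))²`,
solved by a damped Newton method with conjugate-gradient inner steps over
the active (positive-margin) rows — the standard algorithm for squared-hinge
linear classification — with an L-BFGS route kept for cross-checking.
Controls carry weight `1/K` on every face so their total influence is
constant in `K`; targets assigned to a face carry weight 1.

**Alternating optimization** (`fit_polytope()`): estimation (fit each face on
controls + its assigned targets, warm-started from the previous hyperplane)
alternates with assignment (each target moves to the face with the largest
decision value; ties to the lowest index) until assignments are stable.
Warm starts make the recorded objective non-increasing. An emptied face is
reseeded with the target worst explained by all faces; this is flagged on
the model because a reseed can in principle interrupt monotonicity.

**`C` default.** `C` is meaningful only relative to the feature scale; with
residuals standardized to unit reference SD we default to `C = 0.01`. The
choice is about search dynamics, not the final decision rule: small `C`
keeps hyperplane norms small, so margins stay active for most subjects and
the assignment step behaves like a regularized nearest-centroid update,
which reliably amplifies weak initial cluster enrichment. At `C = 1` on this
scale, well-separated cohorts reach full separation early, target losses
vanish, and the alternation locks into whatever partition the
initialization suggested — in our experiments run-to-run recovery of planted
subtypes was visibly worse. Users can pass any `C`.

**Initialization** (`dpp_initialize()`): candidate aging directions are
unit-normalized differences between randomly sampled targets and the control
centroid; a size-`K` subset is chosen to maximize the determinant of the
similarity kernel `(1 + cosine)/2` over the candidates (greedy selection
plus single-swap ascent — a deterministic approximation of k-DPP sampling,
which favours mutually diverse directions). The affine shift of the
linear-kernel Gram matrix matters: a raw Gram determinant treats a direction
and its negative as collinear, whereas two *antipodal* aging directions are
exactly the kind of diversity the initialization should seek; under the
shifted kernel they are maximally diverse. Targets are then assigned to the
selected direction of largest cosine similarity.

**Multi-initialization consensus** (`hydra()`): `n_init` runs from different
DPP seeds are fused through the co-assignment matrix (fraction of runs in
which two targets share a cluster), clustered by average-linkage on
`1 − co-assignment`, and the polytope is refitted from the fused labels.
Because the joint problem is non-convex, the returned solution is the
best-objective candidate among the fused refit and the individual runs;
ties prefer the fused refit. This keeps the fusion's robustness while never
returning a demonstrably worse local optimum.

**Model selection** (`cluster_stability()`): for each `K` in 2…5, the
targets are split into five folds; a fused model is fitted on each fold's
training portion (all controls are shared across folds) and stability is the
mean pairwise adjusted Rand index (ARI) between fold solutions on their
shared targets (3/5 of targets for any fold pair). The pairing scheme is our
design: the methodology names "ARI with five-fold cross-validation" without
defining the pairing. `selected_k` maximizes mean ARI, ties toward smaller
`K`. `K = 1` is excluded — ARI against a one-cluster partition is undefined.
Final labels come from a full-data fused fit at `selected_k`, chosen for
determinism over pooling fold solutions (both paths are available: the fold
assignments are returned on the `stability_curve`).

## 5. Subtype characterization

`characterize_subtypes()` produces three tables:

* **IDPs**: values are first adjusted for age, sex and education by pooled
  OLS (`adjust_covariates_glm()`, flag-controlled), then compared across
  RBA + subtypes by one-way ANOVA per IDP. Multiplicity is controlled by
  Bonferroni at family threshold `q = 0.01`: an IDP is flagged iff
  `p < q/m`, `m` = number of IDPs (561 in the default schema, giving a
  per-test cutoff of about 1.78e-5). "q < 0.01 with Bonferroni" is read as
  Bonferroni-adjusted p below 0.01, not FDR. Per-subtype Z-scores are
  computed against the RBA mean and SD, so the RBA baseline is Z = 0 by
  construction; the plotted/tabulated 95% CI half-width is
  `1.96·SD(Z)/sqrt(n)` per subtype (the source plots CIs without defining
  them).
* **Cognitive scores**: the two time-valued tests (reaction time,
  trail-making) are log-transformed (values must be strictly positive);
  one-way ANOVA across the four groups, then Dunnett-style many-to-one
  contrasts of each subtype against the reference plus all pairwise subtype
  contrasts, tested jointly with single-step multivariate-t adjustment
  (**multcomp**) at `alpha = 0.05`. Which group anchored the published
  pairwise contrasts is not stated, so the reference is a parameter
  (default RBA). Multivariate-t p-values are quasi-Monte-Carlo; the package
  pins a local RNG seed around the call (and restores the caller's stream)
  so reports are deterministic.
* **Qualitative lifestyle variables**: group × category contingency tables
  with Pearson chi-square tests (no continuity correction, matching the
  textbook `Σ(O−E)²/E` statistic).

## 6. The synthetic cohort generator

Real multimodal IDP cohorts of this kind are access-controlled, so the
package ships a seeded generator (`generate_cohort()`) that emulates the
*structure* the analysis relies on; it makes no attempt to reproduce real
marginal distributions, atlas spatial structure, or scanner effects.

Per subject `i` and IDP `f` (on a standardized scale, later mapped through a
per-IDP center and scale):

`z_if = slope_f · (age_i − 64 + delta_i) + sex/education effects + noise_if`

* `age_i ~ U(45, 83)`; `slope_f ~ N(0, age_slope_scale²)` with
  `age_slope_scale = 0.02` SD/year.
* `delta_i` is a latent brain-age deviation shared by all modalities:
  `N(0, 5²)` years for ordinary subjects; planted-ABA subjects carry a
  uniform `+7`-year acceleration instead (`aba_acceleration_sd = 0` by
  default). This makes BrainAGE agree in sign across modalities (so ABA/RBA
  groups are sizable), puts per-modality brain-age MAE in the 4–5-year range
  typical of IDP-based models, and gives planted ABA subjects the strongly
  positive gaps reported for real ABA groups. The acceleration is uniform
  *within* the ABA group on purpose: the latent deviation points along the
  age-slope direction for every subject, so any within-ABA spread plants a
  reproducible extra cluster axis (cross-validation folds then agree on
  splitting subtypes into high/low-acceleration halves and the cohort
  genuinely contains more than the `n_subtypes` intended clusters, defeating
  the generator's "exactly K planted subtypes" contract). A nonzero
  `aba_acceleration_sd` remains available for robustness experiments.
* `noise_if` is Gaussian with total SD `noise_sd = 0.1`, of which a fraction
  `block_noise_cor = 0.2` of variance is a per-modality-block common factor.
* Each planted ABA subject belongs to one of `n_subtypes = 3` subtypes
  (equal fractions; `aba_fraction = 1/3` of subjects are ABA) and receives
  `subtype_effect_size = 1.5` SD along its subtype's unit direction;
  directions are random orthonormal vectors (`plant_subtypes()`), with a
  flag for correlated directions in robustness experiments.
* Cognitive scores decline linearly in subtype severity (severity `k/K` for
  subtype `k`); reaction time and trail-making are generated on a positive
  (power-of-ten) scale so the log transform is exercised. Lifestyle
  variables shift with severity; walking pace (ordinal 1–3) and diabetes
  (binary) provide the chi-square targets. A flag couples sex/education to
  subtype to stress covariate residualization.

**Calibration note.** With 561 IDPs and `noise_sd = 0.1`, a 1.5-SD offset
vector corresponds to per-IDP Z-offsets of roughly 0.4–0.6 reference-SD
units — the magnitude range reported for real ABA subtype Z-profiles — and
planted subtypes are identifiable from the k-DPP initialization, which the
generator module exists to guarantee ("identifiable planted subtypes" is its
design goal, since every downstream stage is tested against it). An early
calibration with `noise_sd = 0.5` made individual target-minus-centroid
directions noise-dominated (cosine with the true direction ≈ 0.06), leaving
initial cluster enrichment near zero: no variant of the prescribed
initialization could recover the planted structure even though a
truth-initialized polytope fit sat at a far better objective. That regime
corresponds to per-IDP Z-offsets of ~0.1 SD, well below the reported
profiles, so it was rejected as the wrong emulation, not merely an
inconvenient one. `null_cohort()` zeroes the subtype offsets *and* the ABA
acceleration and severity effects: a nonzero acceleration would leave
ABA/RBA distributions different, defeating the generator's null contract.

What passing tests on this generator do **not** show: robustness to
non-Gaussian or heavy-tailed IDP noise, site/scanner batch structure,
non-linear age trajectories, missing-not-at-random data, or subtype effects
expressed in the correlation structure rather than the mean. Conclusions
about real cohorts need the real cohorts.

## 7. Numerical choices and degenerate inputs

* Exact zeros in BrainAGE stratify to MIXED (strict signs).
* Penalty-grid CV ties go to the larger penalty; stability ties to the
  smaller `K`; face-assignment ties to the lowest face index.
* Constant IDPs: dropped (recorded) by `fit_brainage()`; dropped with a
  warning by `residualize_covariates()`; an IDP perfectly explained by
  covariates residualizes to exact zeros and is kept.
* A face emptied during assignment is reseeded with the worst-explained
  target; `K = 1` polytopes reduce exactly to a single weighted classifier.
* Newton solver: gradient max-norm tolerance `1e-6` by default (`1e-4` in
  the large stability sweeps, where assignment argmaxes are insensitive to
  the last digits); warm starts are clamped so a refit can never return a
  worse objective than its starting point.
* Cohort files serialize doubles with 17 significant digits, so
  write→read round-trips are value-exact; missing values are empty cells
  (or `NA` on input).

## 8. Problem sizes used by the tests and acceptance script

The packaged checks run the full method at reduced but honest sizes, chosen
as the package's own study conditions: the subtype-recovery check uses the
full 561-IDP schema at n = 3000 with three seeds, five folds, `n_init = 5`
fused initializations per fold fit (5 in the cross-validated stability sweeps, 6 for the final full-data fit); the
polytope-vs-enumeration oracle uses 8 targets and K = 2 so all 2⁸
assignments can be scored exactly; the family-wise-error simulation uses 200
replicates of a 120-subject null cohort with the full 561-IDP battery. Unit
tests use a compact 31-IDP schema. The methods are identical at every size;
only the Monte-Carlo resolution changes.

## 9. Known limitations

* The polytope objective is non-convex in the joint assignment/hyperplane
  space; the multi-init + fusion + best-objective strategy is a heuristic
  without global guarantees (the enumeration oracle verifies it only at toy
  sizes).
* Dunnett-style contrast p-values rely on quasi-Monte-Carlo multivariate-t
  integration (deterministic here only because the RNG is pinned).
* The stability criterion compares fold solutions on shared *training*
  targets; out-of-fold assignment transfer is available via
  `assign_clusters()` but is not part of the selection rule.
* `fit_brainage()` assumes linear age effects; no nonlinear learners are
  provided by design.
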
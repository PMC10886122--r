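# abasubtypes

Dissecting the heterogeneity of **accelerated brain aging (ABA)** from
tabular imaging-derived phenotypes (IDPs), for researchers who work with
multimodal brain-age models on population imaging cohorts.

## What it does

The brain-age paradigm predicts chronological age from imaging features; the
gap between predicted and chronological age,

```
BrainAGE = predicted age − chronological age,
```

indexes whether a brain looks older (positive) or younger (negative) than
expected. The package implements the full subtyping pipeline around that
idea:

1. **Brain-age models** — one Lasso regression per modality block
   (sMRI: 207 features, dMRI: 144, rsfMRI: 210; 561 IDPs in the default
   schema), penalty chosen from the grid {0.001, 0.01, 0.1, 1, 10, 100} by
   5-fold cross-validated MAE, trained on a 40% split.
2. **Age-bias correction** — `corrected = raw − α − β·age`, with α, β the
   intercept and slope of the training-set regression of predicted on
   chronological age (removes regression-to-the-mean bias; corrected
   training BrainAGE has exactly zero mean and zero age correlation).
3. **Stratification** — test-set subjects with positive BrainAGE in all
   three modalities are ABA, all-negative are RBA (resilient), the rest
   MIXED.
4. **HYDRA subtyping** — a semi-supervised convex polytope of `K` weighted
   squared-hinge max-margin linear classifiers separates ABA from the RBA
   reference on covariate-residualized IDPs; each face is one subtype.
   Diverse k-DPP initializations are fused by co-assignment consensus, and
   `K ∈ {2,…,5}` is selected by the mean pairwise adjusted Rand index (ARI)
   of five-fold cross-validated solutions.
5. **Characterization** — per-IDP Z-scores against the RBA reference with
   covariate-adjusted ANOVA under Bonferroni control (q < 0.01 over 561
   tests), cognitive comparisons with Dunnett-style multivariate-t
   contrasts (time-valued scores log-transformed), and chi-square tests for
   categorical lifestyle variables.

Real cohorts of this kind are access-controlled, so the package includes a
seeded synthetic cohort generator (`generate_cohort()`) that emulates the
table schema, linear age effects, modality-block noise, a latent brain-age
deviation shared across modalities, and `K` planted orthogonal subtype
offsets — every stage of the pipeline is testable end to end without any
download. See the methods vignette
(`vignettes/aba-subtyping-methods.Rmd`) for the models, assumptions, and
design decisions.

## Worked example

```r
library(abasubtypes)

## a synthetic cohort with the default 561-IDP schema and 3 planted subtypes
cfg <- generator_config(n_subjects = 3000, seed = 101)
sim <- generate_cohort(cfg)
cohort <- sim$cohort
split <- split_cohort(cohort, train_fraction = 0.40, seed = 1)

## per-modality brain age with bias correction
fit <- fit_brainage(split$train, "dMRI", seed = 1)
print(fit)
pred <- predict(fit, split$test)
evaluate_mae(pred$predicted_raw, pred$age)

## stratify the test set by BrainAGE sign across all three modalities
preds <- lapply(c("sMRI", "dMRI", "rsfMRI"), function(m) {
  p <- predict(fit_brainage(split$train, m, seed = 1), split$test)
  setNames(p$brainage, p$subject_id)
})
strat <- stratify(preds[[1]], preds[[2]], preds[[3]])
print(strat)

## HYDRA subtyping of the planted ABA group against everyone else
ids <- subject_ids(cohort)
is_target <- unname(sim$truth$aba_flag[ids])
x <- as.matrix(cohort$data[, idp_columns(cohort$schema)])
covs <- cbind(age = cohort$data$age, sex = cohort$data$sex,
              education = cohort$data$education_years)
res <- residualize_covariates(x, covs, reference_mask = !is_target)
curve <- cluster_stability(res, is_target, k_range = 2:5, n_folds = 5,
                           n_init = 5, seed = 101, svm_gtol = 1e-4)
print(curve)
h <- hydra(res, is_target, K = curve$selected_k, n_init = 6, seed = 101,
           svm_gtol = 1e-4)
adjusted_rand_index(h$assignments,
                    unname(sim$truth$subtype_label[ids])[is_target])
```

Output from this exact script (timings aside):

```
brain-age model [dMRI]: 144 features (59 nonzero), penalty = 0.1
  bias correction: alpha = 8.482, beta = 0.867 (mode residual); training MAE 2.935 y
[1] 3.160452
stratification of 1800 subjects: ABA 700, RBA 594, MIXED 506
cluster-stability curve (mean pairwise ARI across CV folds)
   K=2    K=3    K=4    K=5 
0.4762 0.9955 0.9592 0.8647 
selected K = 3
[1] 1
```

The dMRI brain-age MAE of a few years reflects the generator's latent
brain-age deviation (SD 5 y): the model recovers each subject's *apparent*
brain age almost exactly, so the residual error is dominated by how far each
brain genuinely deviates from its chronological age. The stability curve
peaks at K = 3 — the number of planted subtypes — and the final fused labels
agree with the planted ones (ARI 1 means a perfect partition match up to
label renaming).

A one-shot pipeline (simulate → brain age → stratify → cluster →
characterize, with every artifact written to disk plus a checksummed
manifest) is available as `run_pipeline(run_config(...))`, or from a shell
via the thin wrapper `inst/scripts/aba-subtypes.R`.

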
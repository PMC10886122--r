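test_that("split_cohort gives a disjoint deterministic 40/60 partition", {
  sim <- generate_cohort(small_config(n = 100, seed = 1))
  sp <- split_cohort(sim$cohort, 0.40, seed = 3)
  expect_equal(n_subjects(sp$train), 40)
  expect_equal(n_subjects(sp$test), 60)
  expect_length(intersect(subject_ids(sp$train), subject_ids(sp$test)), 0)
  expect_setequal(c(subject_ids(sp$train), subject_ids(sp$test)),
                  subject_ids(sim$cohort))
  sp2 <- split_cohort(sim$cohort, 0.40, seed = 3)
  expect_identical(subject_ids(sp2$train), subject_ids(sp$train))
  # both sets nonempty down to n = 2 (floor for train, remainder test)
  two <- abasubtypes:::subset_cohort(sim$cohort, 1:2)
  sp3 <- split_cohort(two, 0.40, seed = 1)
  expect_equal(n_subjects(sp3$train), 1)
  expect_equal(n_subjects(sp3$test), 1)
  expect_error(split_cohort(sim$cohort, 1.2), class = "config_error")
})

test_that("the default penalty grid is the six-point grid", {
  expect_equal(sort(formals(fit_brainage)$alpha_grid |> eval()),
               c(0.001, 0.01, 0.1, 1, 10, 100))
})

test_that("an exact linear age signal is recovered with near-zero training MAE", {
  co <- exact_linear_cohort(n = 200, seed = 2)
  fit <- fit_brainage(co, "sMRI", seed = 1)
  pred <- predict(fit, co)
  expect_lt(evaluate_mae(pred$predicted_raw, pred$age), 0.1)
  expect_lte(fit$penalty, 0.01)
})

test_that("a very large penalty shrinks predictions to the training mean age", {
  sim <- generate_cohort(small_config(n = 150, seed = 4))
  co <- sim$cohort
  fit <- fit_brainage(co, "sMRI", alpha_grid = c(1e5), cv_folds = 3, seed = 1)
  pred <- predict(fit, co)
  expect_lt(max(abs(pred$predicted_raw - mean(co$data$age))), 1e-6)
  expect_true(all(fit$coefficients == 0))
})

test_that("number of nonzero coefficients is non-increasing in the penalty", {
  sim <- generate_cohort(small_config(n = 200, seed = 6))
  fit <- fit_brainage(sim$cohort, "sMRI", seed = 2)
  nz <- vapply(fit$alpha_grid, function(lam) {
    sum(as.matrix(coef(fit$glmnet_fit, s = lam))[-1, 1] != 0)
  }, numeric(1))
  # alpha_grid is stored in decreasing order: counts must be non-decreasing
  expect_true(all(diff(nz) >= 0))
})

test_that("predictions are invariant to affine rescaling of an input feature", {
  sim <- generate_cohort(small_config(n = 200, seed = 8))
  co <- sim$cohort
  fit <- fit_brainage(co, "sMRI", seed = 5)
  co2 <- co
  co2$data$smri_004 <- 10 * co2$data$smri_004 - 100
  fit2 <- fit_brainage(co2, "sMRI", seed = 5)
  p1 <- predict(fit, co)
  p2 <- predict(fit2, co2)
  expect_lt(max(abs(p1$predicted_raw - p2$predicted_raw)), 1e-6)
})

test_that("bias correction follows the stated arithmetic", {
  model <- structure(list(bias_alpha = 10, bias_beta = 0.5,
                          correction_mode = "residual"),
                     class = "brainage_model")
  expect_equal(apply_bias_correction(model, 60, 65), 60 - 10 - 0.5 * 65)
  model0 <- structure(list(bias_alpha = 0, bias_beta = 0,
                           correction_mode = "residual"),
                      class = "brainage_model")
  expect_equal(apply_bias_correction(model0, c(50, 60), c(55, 70)), c(50, 60))
  # rescale mode inverts the regression line
  expect_equal(apply_bias_correction(model, 60, 65, mode = "rescale"),
               (60 - 10) / 0.5)
  model_flat <- structure(list(bias_alpha = 1, bias_beta = 0),
                          class = "brainage_model")
  expect_error(apply_bias_correction(model_flat, 60, 65, mode = "rescale"),
               class = "numeric_error")
})

test_that("residual-mode corrected values are exactly uncorrelated with training age", {
  sim <- generate_cohort(small_config(n = 300, seed = 10))
  sp <- split_cohort(sim$cohort, 0.4, seed = 2)
  fit <- fit_brainage(sp$train, "dMRI", seed = 3)
  tr <- predict(fit, sp$train)
  expect_lt(abs(mean(tr$corrected)), 1e-8)
  expect_lt(abs(cor(tr$corrected, tr$age)), 1e-8)
})

test_that("compute_brainage follows the sign and mode conventions", {
  expect_equal(compute_brainage(70, 65, mode = "none"), 5)
  expect_equal(compute_brainage(c(50, 60), c(50, 60), mode = "none"), c(0, 0))
  # residual mode passes the (already corrected) deviation through
  expect_equal(compute_brainage(c(-2, 3), c(60, 70), mode = "residual"),
               c(-2, 3))
  expect_error(compute_brainage(1:3, 1:2), class = "alignment_error")
})

test_that("evaluate_mae averages absolute errors", {
  expect_equal(evaluate_mae(c(61, 57), c(60, 60)), 2)
  expect_equal(evaluate_mae(c(55, 60), c(55, 60)), 0)
  expect_error(evaluate_mae(numeric(0), numeric(0)), class = "config_error")
})

test_that("model MAE beats the mean-age predictor on training data", {
  sim <- generate_cohort(small_config(n = 250, seed = 12))
  sp <- split_cohort(sim$cohort, 0.4, seed = 1)
  fit <- fit_brainage(sp$train, "sMRI", seed = 1)
  tr <- predict(fit, sp$train)
  mean_mae <- evaluate_mae(rep(mean(tr$age), nrow(tr)), tr$age)
  expect_lte(evaluate_mae(tr$predicted_raw, tr$age), mean_mae)
})

test_that("constant features are dropped and an all-constant block errors", {
  sim <- generate_cohort(small_config(n = 80, seed = 14))
  co <- sim$cohort
  co$data$smri_005 <- 1.0
  fit <- fit_brainage(co, "sMRI", seed = 1)
  expect_identical(fit$dropped_features, "smri_005")
  expect_false("smri_005" %in% fit$feature_names)
  co2 <- co
  for (col in co2$schema$modality_blocks$dMRI) co2$data[[col]] <- 2.0
  expect_error(fit_brainage(co2, "dMRI", seed = 1), class = "model_error")
  expect_error(fit_brainage(co, "sMRI", cv_folds = 1), class = "config_error")
})
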
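#' Random train/test split of a cohort
#'
#' Disjoint random partition; the training set receives
#' `floor(train_fraction * n)` subjects and the test set the remainder (so
#' both are nonempty for `n >= 2` at the default fraction).
#'
#' @param cohort a `cohort`.
#' @param train_fraction fraction assigned to training (default 0.40).
#' @param seed integer seed; identical seeds give identical partitions.
#' @return list with `cohort` elements `train` and `test`.
#' @export
split_cohort <- function(cohort, train_fraction = 0.40, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("config_error", "train_fraction must lie in (0, 1)")
  }
  n <- n_subjects(cohort)
  if (n < 2) stopf("config_error", "need at least 2 subjects to split")
  n_train <- max(1L, floor(train_fraction * n))
  idx <- with_preserved_seed(seed, sample.int(n, n_train))
  list(train = subset_cohort(cohort, sort(idx)),
       test = subset_cohort(cohort, setdiff(seq_len(n), idx)))
}

#' Fit a per-modality sparse linear brain-age model
#'
#' Standardizes the modality's IDP block with training statistics (constant
#' features are dropped and recorded), selects the Lasso penalty from
#' `alpha_grid` by `cv_folds`-fold cross-validated mean absolute error (ties
#' broken toward the larger penalty, i.e. more regularization), refits on the
#' full training set at the selected penalty, and then fits the age-bias
#' terms: an ordinary least-squares regression of the raw training
#' predictions on chronological age, whose intercept (`bias_alpha`) and slope
#' (`bias_beta`) drive [apply_bias_correction()].
#'
#' @param train training `cohort`.
#' @param modality name of a modality block in the cohort schema.
#' @param alpha_grid candidate Lasso penalties; the default is the six-point
#'   grid 0.001, 0.01, 0.1, 1, 10, 100.
#' @param cv_folds number of cross-validation folds (>= 2).
#' @param seed integer seed controlling fold assignment.
#' @param correction_mode default correction mode stored on the model: one of
#'   `"residual"` (Eq.-style residual used directly as corrected BrainAGE,
#'   the default), `"rescale"` (`(raw - alpha)/beta` as corrected age), or
#'   `"none"`.
#' @return an object of class `brainage_model`.
#' @export
fit_brainage <- function(train, modality,
                         alpha_grid = c(0.001, 0.01, 0.1, 1, 10, 100),
                         cv_folds = 5L, seed = 1L,
                         correction_mode = c("residual", "rescale", "none")) {
  correction_mode <- match.arg(correction_mode)
  if (cv_folds < 2) stopf("config_error", "cv_folds must be >= 2")
  schema <- train$schema
  if (!modality %in% names(schema$modality_blocks)) {
    stopf("schema_error", "unknown modality '%s'", modality)
  }
  cols <- schema$modality_blocks[[modality]]
  x <- as.matrix(train$data[, cols, drop = FALSE])
  y <- train$data[[schema$age_column]]
  n <- nrow(x)
  if (n < cv_folds) stopf("config_error", "need at least cv_folds subjects")

  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  dropped <- cols[scale <= 0 | !is.finite(scale)]
  keep <- setdiff(cols, dropped)
  if (!length(keep)) stopf("model_error", "all features in block '%s' are constant",
                           modality)
  center <- center[keep]
  scale <- scale[keep]
  xs <- scale(x[, keep, drop = FALSE], center = center, scale = scale)

  lambda <- sort(as.numeric(alpha_grid), decreasing = TRUE)
  foldid <- with_preserved_seed(seed, sample(rep(seq_len(cv_folds), length.out = n)))
  if (length(lambda) > 1) {
    cv <- glmnet::cv.glmnet(xs, y, family = "gaussian", lambda = lambda,
                            type.measure = "mae", foldid = foldid,
                            standardize = FALSE)
    # cv$lambda is decreasing; ties broken toward the larger penalty
    cvm <- cv$cvm
    sel <- which(cvm <= min(cvm) + 1e-12)[1]
    penalty <- cv$lambda[sel]
    path <- cv$glmnet.fit
    cv_lambda <- cv$lambda
  } else {
    path <- glmnet::glmnet(xs, y, family = "gaussian", lambda = lambda,
                           standardize = FALSE)
    penalty <- lambda
    cvm <- NA_real_
    cv_lambda <- lambda
  }

  beta <- as.matrix(stats::coef(path, s = penalty))
  intercept <- beta[1, 1]
  coefs <- stats::setNames(beta[-1, 1], keep)

  raw <- drop(xs %*% coefs) + intercept
  bias <- stats::lm(raw ~ y)
  bias_alpha <- unname(stats::coef(bias)[1])
  bias_beta <- unname(stats::coef(bias)[2])

  structure(list(
    modality = modality, feature_names = keep, coefficients = coefs,
    intercept = intercept, penalty = penalty, alpha_grid = lambda,
    cv_mae = stats::setNames(cvm, cv_lambda),
    center = center, scale = scale, dropped_features = dropped,
    bias_alpha = bias_alpha, bias_beta = bias_beta,
    correction_mode = correction_mode,
    train_mae = mean(abs(raw - y)), n_train = n, seed = seed,
    glmnet_fit = path), class = "brainage_model")
}

#' Age-bias correction of raw predicted age
#'
#' With `alpha` and `beta` the intercept and slope of the training-set
#' regression of predicted on chronological age:
#' mode `"residual"` returns `raw - alpha - beta * age` (the regression
#' residual, used directly as corrected BrainAGE); mode `"rescale"` returns
#' `(raw - alpha) / beta`, a corrected predicted age on the original scale
#' (requires `beta != 0`); mode `"none"` returns `raw` unchanged.
#'
#' @param model a `brainage_model` with fitted bias terms.
#' @param predicted_raw raw predicted ages, years.
#' @param age chronological ages, years (aligned with `predicted_raw`).
#' @param mode overrides the model's stored correction mode.
#' @return numeric vector of corrected values.
#' @export
apply_bias_correction <- function(model, predicted_raw, age,
                                  mode = model$correction_mode) {
  if (length(predicted_raw) != length(age)) {
    stopf("alignment_error", "predicted and age vectors have different lengths")
  }
  switch(mode,
         residual = predicted_raw - model$bias_alpha - model$bias_beta * age,
         rescale = {
           if (abs(model$bias_beta) < 1e-8) {
             stopf("numeric_error", "bias slope too close to zero for rescale mode")
           }
           (predicted_raw - model$bias_alpha) / model$bias_beta
         },
         none = predicted_raw,
         stopf("config_error", "unknown correction mode '%s'", mode))
}

#' Brain-age gap (BrainAGE)
#'
#' BrainAGE is predicted age minus chronological age. Under the `"residual"`
#' correction mode the corrected value is already a deviation from the
#' age-expected prediction, so it is returned as the BrainAGE itself; under
#' `"rescale"` or `"none"` the gap `predicted - age` is formed.
#'
#' @param predicted corrected predicted values (mode `"residual"`) or
#'   (corrected) predicted ages in years (other modes).
#' @param age chronological ages, years.
#' @param mode correction mode the `predicted` values were produced under.
#' @return numeric vector of BrainAGE values, years.
#' @export
compute_brainage <- function(predicted, age, mode = c("residual", "rescale", "none")) {
  mode <- match.arg(mode)
  if (length(predicted) != length(age)) {
    stopf("alignment_error", "predicted and age vectors have different lengths")
  }
  if (mode == "residual") predicted else predicted - age
}

#' Mean absolute error of predicted age
#' @param predicted predicted ages, years.
#' @param age chronological ages, years.
#' @return mean absolute difference, years.
#' @export
evaluate_mae <- function(predicted, age) {
  if (length(predicted) != length(age)) {
    stopf("alignment_error", "predicted and age vectors have different lengths")
  }
  if (!length(predicted)) stopf("config_error", "empty input")
  mean(abs(predicted - age))
}

#' Predict brain age for new subjects
#'
#' @param object a `brainage_model`.
#' @param newdata a `cohort` containing the model's modality block.
#' @param mode correction mode (defaults to the model's).
#' @param ... unused.
#' @return data.frame with columns `subject_id`, `age`, `predicted_raw`,
#'   `corrected`, `brainage`.
#' @export
predict.brainage_model <- function(object, newdata,
                                   mode = object$correction_mode, ...) {
  schema <- newdata$schema
  x <- as.matrix(newdata$data[, object$feature_names, drop = FALSE])
  xs <- scale(x, center = object$center, scale = object$scale)
  raw <- drop(xs %*% object$coefficients) + object$intercept
  age <- newdata$data[[schema$age_column]]
  corrected <- apply_bias_correction(object, raw, age, mode = mode)
  brainage <- compute_brainage(corrected, age, mode = mode)
  data.frame(subject_id = subject_ids(newdata), age = age,
             predicted_raw = raw, corrected = corrected, brainage = brainage,
             stringsAsFactors = FALSE)
}

#' @export
coef.brainage_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
print.brainage_model <- function(x, ...) {
  cat(sprintf("brain-age model [%s]: %d features (%d nonzero), penalty = %g\n",
              x$modality, length(x$coefficients),
              sum(x$coefficients != 0), x$penalty))
  cat(sprintf("  bias correction: alpha = %.3f, beta = %.3f (mode %s); training MAE %.3f y\n",
              x$bias_alpha, x$bias_beta, x$correction_mode, x$train_mae))
  invisible(x)
}

#' @export
summary.brainage_model <- function(object, ...) {
  out <- list(modality = object$modality,
              penalty = object$penalty,
              cv_mae = object$cv_mae,
              n_nonzero = sum(object$coefficients != 0),
              n_features = length(object$coefficients),
              dropped = object$dropped_features,
              bias = c(alpha = object$bias_alpha, beta = object$bias_beta),
              train_mae = object$train_mae)
  class(out) <- "summary.brainage_model"
  out
}

#' @export
print.summary.brainage_model <- function(x, ...) {
  cat(sprintf("brain-age model [%s]\n", x$modality))
  cat("  CV MAE by penalty:\n")
  print(round(x$cv_mae, 4))
  cat(sprintf("  selected penalty %g; %d/%d nonzero coefficients; train MAE %.3f y\n",
              x$penalty, x$n_nonzero, x$n_features, x$train_mae))
  cat(sprintf("  bias terms: alpha = %.4f, beta = %.4f\n",
              x$bias["alpha"], x$bias["beta"]))
  invisible(x)
}

# JSON persistence of a fitted model (coefficients, penalty, bias terms,
# standardization); the glmnet path object is not serialized
write_brainage_model <- function(model, path) {
  keep <- c("modality", "feature_names", "coefficients", "intercept",
            "penalty", "alpha_grid", "cv_mae", "center", "scale",
            "dropped_features", "bias_alpha", "bias_beta",
            "correction_mode", "train_mae", "n_train", "seed")
  jsonlite::write_json(lapply(model[keep], unclass), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
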
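#' Synthetic cohort generator configuration
#'
#' Defines the statistical structure of a generated cohort: uniform ages over
#' `age_range`, a linear age effect per IDP, modality-block-correlated
#' Gaussian noise, a latent per-subject brain-age deviation shared across
#' modalities, and `n_subtypes` planted accelerated-aging (ABA) subtypes,
#' each expressed as a distinct (by default mutually orthogonal) multivariate
#' offset of length `subtype_effect_size` on the standardized feature scale,
#' plus a positive brain-age acceleration. Cognitive scores depend negatively
#' on subtype severity and the two time-valued scores are generated on a
#' strictly positive scale so the downstream log transform is exercised.
#'
#' All scales are in per-IDP standard-deviation (SD) units unless noted.
#'
#' @param n_subjects number of subjects.
#' @param age_range chronological age range in years.
#' @param block_sizes named integer vector of IDP counts per modality block.
#' @param n_networks resting-state network count; if `block_sizes` omits
#'   `rsfMRI`, its size is derived as `n_networks*(n_networks-1)/2`.
#' @param age_slope_scale SD of the per-IDP linear age effect, SD units/year.
#' @param noise_sd total per-IDP noise SD.
#' @param block_noise_cor share of noise variance from a per-block common
#'   factor (within-block correlation of the noise).
#' @param n_subtypes number of planted ABA subtypes.
#' @param subtype_effect_size Euclidean length of each subtype's offset
#'   vector, SD units.
#' @param subtype_fractions simplex vector of subtype mixing fractions
#'   (default equal).
#' @param aba_fraction fraction of subjects planted as ABA.
#' @param aba_acceleration mean extra apparent brain age of planted ABA
#'   subjects, years.
#' @param aba_acceleration_sd SD of the planted acceleration, years.
#' @param brainage_spread SD of the latent brain-age deviation shared across
#'   modalities for all subjects, years.
#' @param covariate_effects named vector: SD-unit effect scales for sex and
#'   (per year) education on IDPs.
#' @param cognitive_effect size of the subtype-severity deficit on cognitive
#'   scores (SD units of each score).
#' @param orthogonal_directions orthonormalize the subtype offset directions
#'   (set `FALSE` for correlated directions in robustness experiments).
#' @param confounded_covariates couple sex/education to subtype membership
#'   (off by default; used to exercise covariate residualization).
#' @param seed integer seed; identical configs produce bit-identical cohorts.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_subjects,
                             age_range = c(45, 83),
                             block_sizes = c(sMRI = 207L, dMRI = 144L, rsfMRI = 210L),
                             n_networks = 21L,
                             age_slope_scale = 0.02,
                             noise_sd = 0.1,
                             block_noise_cor = 0.2,
                             n_subtypes = 3L,
                             subtype_effect_size = 1.5,
                             subtype_fractions = NULL,
                             aba_fraction = 1 / 3,
                             aba_acceleration = 7,
                             aba_acceleration_sd = 0,
                             brainage_spread = 5,
                             covariate_effects = c(sex = 0.1, education = 0.02),
                             cognitive_effect = 1.0,
                             orthogonal_directions = TRUE,
                             confounded_covariates = FALSE,
                             seed = 1L) {
  if (!("rsfMRI" %in% names(block_sizes)) && !is.null(n_networks)) {
    block_sizes <- c(block_sizes, rsfMRI = as.integer(choose(n_networks, 2)))
  }
  n_subtypes <- as.integer(n_subtypes)
  if (is.null(subtype_fractions)) subtype_fractions <- rep(1 / n_subtypes, n_subtypes)
  if (length(subtype_fractions) != n_subtypes || any(subtype_fractions <= 0) ||
      abs(sum(subtype_fractions) - 1) > 1e-8) {
    stopf("config_error", "subtype_fractions must be %d positive values summing to 1",
          n_subtypes)
  }
  if (n_subjects < 2 * n_subtypes) {
    stopf("config_error", "n_subjects must be >= 2 * n_subtypes (= %d)", 2 * n_subtypes)
  }
  if (noise_sd <= 0) stopf("config_error", "noise_sd must be positive")
  if (aba_fraction <= 0 || aba_fraction >= 1) {
    stopf("config_error", "aba_fraction must lie in (0, 1)")
  }
  if (block_noise_cor < 0 || block_noise_cor >= 1) {
    stopf("config_error", "block_noise_cor must lie in [0, 1)")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), age_range = age_range,
    block_sizes = block_sizes, n_networks = n_networks,
    age_slope_scale = age_slope_scale, noise_sd = noise_sd,
    block_noise_cor = block_noise_cor, n_subtypes = n_subtypes,
    subtype_effect_size = subtype_effect_size,
    subtype_fractions = subtype_fractions, aba_fraction = aba_fraction,
    aba_acceleration = aba_acceleration,
    aba_acceleration_sd = aba_acceleration_sd,
    brainage_spread = brainage_spread,
    covariate_effects = covariate_effects,
    cognitive_effect = cognitive_effect,
    orthogonal_directions = orthogonal_directions,
    confounded_covariates = confounded_covariates,
    seed = as.integer(seed)), class = "generator_config")
}

#' Plant mutually orthogonal subtype offset directions
#'
#' Draws `n_subtypes` Gaussian vectors in `n_features` dimensions and
#' orthonormalizes them (QR), yielding unit-norm, pairwise-orthogonal rows.
#'
#' @param n_subtypes number of directions (rows).
#' @param n_features dimension.
#' @param seed integer seed; output is deterministic given the seed.
#' @param orthogonal if `FALSE`, rows are only unit-normalized.
#' @return a `n_subtypes x n_features` matrix with unit-norm rows.
#' @export
plant_subtypes <- function(n_subtypes, n_features, seed, orthogonal = TRUE) {
  if (n_subtypes > n_features) {
    stopf("dimension_error", "n_subtypes (%d) exceeds n_features (%d)",
          n_subtypes, n_features)
  }
  with_preserved_seed(seed, {
    m <- matrix(stats::rnorm(n_features * n_subtypes), n_features, n_subtypes)
    if (orthogonal) {
      q <- qr.Q(qr(m))[, seq_len(n_subtypes), drop = FALSE]
      out <- t(q)
    } else {
      out <- t(m) / sqrt(rowSums(t(m)^2))
    }
    rownames(out) <- sprintf("subtype_%d", seq_len(n_subtypes))
    out
  })
}

# internal: deterministic subtype counts matching the fractions within rounding
subtype_counts <- function(fractions, n) {
  cum <- round(cumsum(fractions) * n)
  diff(c(0L, cum))
}

subset_truth <- function(truth, ids) {
  keep <- intersect(names(truth$aba_flag), ids)
  truth$aba_flag <- truth$aba_flag[ids]
  truth$subtype_label <- truth$subtype_label[ids]
  truth$severity <- truth$severity[ids]
  truth$delta <- truth$delta[ids]
  truth
}

#' Generate a synthetic multimodal IDP cohort
#'
#' Each IDP, on its standardized scale, is
#' `slope_f * (age - mid_age + delta_i) + covariate effects + noise`, where
#' `delta_i` is a latent per-subject brain-age deviation (years) shared across
#' all modalities; planted ABA subjects draw `delta_i` from a positive
#' acceleration distribution and additionally receive
#' `subtype_effect_size * direction_k` for their subtype `k`. Standardized
#' values are mapped to the observed scale through a per-IDP center and scale.
#' Cognitive and lifestyle variables depend on age and on subtype severity.
#'
#' @param config a [generator_config()].
#' @param null internal switch used by [null_cohort()]: zero out every
#'   subtype-linked effect while keeping labels.
#' @return list with elements `cohort` (a [new_cohort()] carrying the truth)
#'   and `truth` (class `ground_truth`): per-subject `aba_flag`,
#'   `subtype_label` (NA for non-ABA), `severity`, `delta`, plus
#'   `offset_directions` (K x p, unit rows), `age_slopes` (observed scale),
#'   `idp_center`, `idp_scale`.
#' @export
generate_cohort <- function(config, null = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)
  schema <- schema_for_blocks(cfg$block_sizes, cfg$n_networks)
  schema$age_range <- cfg$age_range
  idps <- idp_columns(schema)
  p <- length(idps)
  n <- cfg$n_subjects
  K <- cfg$n_subtypes
  mid_age <- mean(cfg$age_range)

  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  sex <- stats::rbinom(n, 1, 0.5)
  edu <- as.integer(pmin(22, pmax(10, round(stats::rnorm(n, 16, 2.5)))))

  slopes <- cfg$age_slope_scale * stats::rnorm(p)
  sex_eff <- cfg$covariate_effects[["sex"]] * stats::rnorm(p)
  edu_eff <- cfg$covariate_effects[["education"]] * stats::rnorm(p)

  directions <- plant_subtypes(K, p, seed = derive_seed(cfg$seed, 101L),
                               orthogonal = cfg$orthogonal_directions)
  colnames(directions) <- idps

  n_aba <- round(cfg$aba_fraction * n)
  aba_idx <- sort(sample.int(n, n_aba))
  counts <- subtype_counts(cfg$subtype_fractions, n_aba)
  subtype <- rep(NA_integer_, n)
  subtype[aba_idx] <- sample(rep(seq_len(K), counts))

  if (cfg$confounded_covariates && !null) {
    # couple sex and education to subtype membership to stress residualization
    sex[aba_idx] <- stats::rbinom(n_aba, 1, 0.35 + 0.1 * subtype[aba_idx])
    edu[aba_idx] <- as.integer(pmin(22, pmax(10, edu[aba_idx] - subtype[aba_idx])))
  }

  delta <- stats::rnorm(n, 0, cfg$brainage_spread)
  if (!null) {
    delta[aba_idx] <- stats::rnorm(n_aba, cfg$aba_acceleration,
                                   cfg$aba_acceleration_sd)
  }
  severity <- numeric(n)
  if (!null) severity[aba_idx] <- subtype[aba_idx] / K

  # standardized-scale feature matrix
  z <- outer(age - mid_age + delta, slopes)
  z <- z + outer(sex, sex_eff) + outer(edu - 16, edu_eff)
  noise <- matrix(stats::rnorm(n * p), n, p) *
    (cfg$noise_sd * sqrt(1 - cfg$block_noise_cor))
  if (cfg$block_noise_cor > 0) {
    offset <- 0L
    for (m in names(schema$modality_blocks)) {
      nb <- length(schema$modality_blocks[[m]])
      u <- stats::rnorm(n)
      noise[, offset + seq_len(nb)] <- noise[, offset + seq_len(nb)] +
        u * (cfg$noise_sd * sqrt(cfg$block_noise_cor))
      offset <- offset + nb
    }
  }
  z <- z + noise
  effect <- if (null) 0 else cfg$subtype_effect_size
  if (effect != 0) {
    z[aba_idx, ] <- z[aba_idx, ] + effect * directions[subtype[aba_idx], , drop = FALSE]
  }

  idp_center <- stats::rnorm(p)
  idp_scale <- exp(stats::rnorm(p, 0, 0.25))
  x <- sweep(sweep(z, 2, idp_scale, "*"), 2, idp_center, "+")
  colnames(x) <- idps

  sev_mult <- if (null) 0 else cfg$cognitive_effect
  cog <- generate_cognitive(n, age, mid_age, severity, sev_mult)
  life <- generate_lifestyle(n, age, mid_age, sex, severity, sev_mult)

  ids <- sprintf("S%05d", seq_len(n))
  df <- data.frame(subject_id = ids, age = age, sex = sex,
                   education_years = edu, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x), cog, life)

  truth <- structure(list(
    aba_flag = stats::setNames(seq_len(n) %in% aba_idx, ids),
    subtype_label = stats::setNames(subtype, ids),
    severity = stats::setNames(severity, ids),
    delta = stats::setNames(delta, ids),
    offset_directions = directions,
    age_slopes = stats::setNames(slopes * idp_scale, idps),
    idp_center = stats::setNames(idp_center, idps),
    idp_scale = stats::setNames(idp_scale, idps)), class = "ground_truth")

  cohort <- new_cohort(df, schema, truth = truth)
  list(cohort = cohort, truth = truth)
}

# cognitive battery: seven score-valued tests plus two strictly positive
# time-valued tests (generated on a log10 scale, so downstream log transforms
# are well-defined); higher severity means worse performance
generate_cognitive <- function(n, age, mid_age, severity, sev_mult) {
  a <- age - mid_age
  s <- sev_mult * severity
  data.frame(
    pairs_matching = pmax(0, 3.6 + 0.02 * a + 0.4 * s + stats::rnorm(n, 0, 1.4)),
    numeric_memory = 6.8 - 0.02 * a - 0.5 * s + stats::rnorm(n, 0, 1.4),
    fluid_intelligence = 6.8 - 0.03 * a - 0.6 * s + stats::rnorm(n, 0, 2.0),
    paired_associate_learning = 7.2 - 0.03 * a - 0.6 * s + stats::rnorm(n, 0, 2.4),
    matrix_completion = 8.2 - 0.02 * a - 0.5 * s + stats::rnorm(n, 0, 2.0),
    reaction_time = 10^(2.764 + 0.002 * a + 0.02 * s + stats::rnorm(n, 0, 0.05)),
    symbol_digit = 19.6 - 0.15 * a - 1.2 * s + stats::rnorm(n, 0, 4.5),
    tower_rearranging = 10.0 - 0.04 * a - 0.5 * s + stats::rnorm(n, 0, 2.8),
    trail_making = 10^(2.711 + 0.003 * a + 0.03 * s + stats::rnorm(n, 0, 0.08)))
}

# lifestyle/health: four quantitative variables plus two integer-coded
# categorical ones (walking pace 1..3, diabetes 0/1)
generate_lifestyle <- function(n, age, mid_age, sex, severity, sev_mult) {
  a <- age - mid_age
  s <- sev_mult * severity
  pace_lin <- -1 + 1.2 * s + 0.03 * a + stats::rlogis(n)
  data.frame(
    systolic_bp = 135 + 0.35 * a + 6 * s + stats::rnorm(n, 0, 12),
    driving_time = exp(stats::rnorm(n, 0.3 * s, 0.5)),
    grip_strength = 32 + 8 * sex - 0.25 * a - 3 * s + stats::rnorm(n, 0, 7),
    physical_activity = pmax(0, 30 - 8 * s + stats::rnorm(n, 0, 10)),
    walking_pace = 4L - as.integer(cut(pace_lin, c(-Inf, 0, 2, Inf), labels = FALSE)),
    diabetes = stats::rbinom(n, 1, stats::plogis(-2.5 + 1.0 * s + 0.03 * a)))
}

#' Generate a global-null cohort
#'
#' Identical to [generate_cohort()] but with every subtype-linked effect
#' (IDP offsets, brain-age acceleration, cognitive/lifestyle severity
#' effects) forced to zero, so planted labels are uninformative and ABA/RBA
#' feature distributions coincide. Used for type-I-error checks.
#'
#' @param config a [generator_config()].
#' @return as [generate_cohort()].
#' @export
null_cohort <- function(config) {
  cfg <- config
  cfg$subtype_effect_size <- 0
  generate_cohort(cfg, null = TRUE)
}
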
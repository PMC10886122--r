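#' Z-scores relative to a reference group
#'
#' `(value - mean(reference)) / sd(reference)`; by construction the reference
#' group applied to itself has mean 0 and SD 1, so the reference baseline is
#' Z = 0.
#'
#' @param values numeric vector to score.
#' @param reference_values numeric reference sample (>= 2 values, SD > 0).
#' @return numeric vector of Z-scores.
#' @export
zscore_vs_reference <- function(values, reference_values) {
  if (length(reference_values) < 2) {
    stopf("degenerate_reference_error", "reference needs at least 2 values")
  }
  s <- stats::sd(reference_values)
  if (!is.finite(s) || s <= 0) {
    stopf("degenerate_reference_error", "reference SD is zero")
  }
  (values - mean(reference_values)) / s
}

#' Covariate adjustment by pooled least squares
#'
#' Residuals of the regression of `values` on the covariates (plus
#' intercept), fitted over all groups pooled.
#'
#' @param values numeric vector or matrix (one column per variable).
#' @param covariates numeric matrix or data.frame (age, sex, education).
#' @return residuals with the same shape as `values`.
#' @export
adjust_covariates_glm <- function(values, covariates) {
  z <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  v <- as.matrix(values)
  if (nrow(z) != nrow(v)) stopf("alignment_error", "covariates do not match values")
  if (anyNA(v) || anyNA(z)) stopf("validation_error", "missing values not allowed")
  qz <- qr(z)
  if (qz$rank < ncol(z)) stopf("rank_deficiency_error", "rank-deficient covariates")
  res <- qr.resid(qz, v)
  if (is.vector(values)) drop(res) else res
}

#' Per-IDP one-way ANOVA with Bonferroni control
#'
#' One-way ANOVA F and p per IDP across the groups, computed on
#' covariate-adjusted values when `covariates` is supplied. An IDP is flagged
#' significant when `p < q_threshold / m` with `m` the number of IDPs tested
#' (Bonferroni-adjusted p below the `q_threshold`, default 0.01). F statistics
#' come from the standard between/within decomposition of multi-response
#' least-squares fits, verified against `anova(lm(...))` column by column in
#' the package tests.
#'
#' @param data data.frame holding the IDP columns.
#' @param group factor of group membership (reference + subtypes).
#' @param idps character vector of IDP column names to test.
#' @param covariates optional matrix/data.frame for [adjust_covariates_glm()].
#' @param q_threshold family-wise threshold (default 0.01).
#' @return data.frame of class `idp_anova`: `idp`, `F`, `p`, `p_bonferroni`,
#'   `significant`; the per-test cutoff is in `attr(, "cutoff")`.
#' @export
anova_idps <- function(data, group, idps, covariates = NULL, q_threshold = 0.01) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stopf("config_error", "need at least 2 groups")
  if (any(table(group) < 2)) {
    stopf("config_error", "every group needs at least 2 subjects")
  }
  y <- as.matrix(data[, idps, drop = FALSE])
  if (length(group) != nrow(y)) stopf("alignment_error", "group does not match data")
  if (!is.null(covariates)) y <- adjust_covariates_glm(y, covariates)
  n <- nrow(y)
  g <- nlevels(group)
  x1 <- stats::model.matrix(~group)
  fit1 <- stats::lm.fit(x1, y)
  rss1 <- colSums(as.matrix(fit1$residuals)^2)
  rss0 <- colSums(sweep(y, 2, colMeans(y))^2)
  df1 <- g - 1L
  df2 <- n - g
  fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  m <- length(idps)
  cutoff <- q_threshold / m
  out <- data.frame(idp = idps, F = unname(fstat), p = unname(p),
                    p_bonferroni = pmin(1, unname(p) * m),
                    significant = unname(p) < cutoff,
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  attr(out, "m") <- m
  attr(out, "q_threshold") <- q_threshold
  class(out) <- c("idp_anova", "data.frame")
  out
}

#' Cognitive comparison: ANOVA with Dunnett-style contrasts
#'
#' Designated time-valued scores are log-transformed (values must be strictly
#' positive); each test is compared across groups with one-way ANOVA, and
#' many-to-one contrasts of every subtype against the reference plus all
#' pairwise subtype contrasts are tested jointly with single-step
#' multivariate-t adjustment (Dunnett-type, via \pkg{multcomp}), flagged at
#' `alpha`. Contrast p-values are computed under a pinned RNG state so the
#' report is deterministic.
#'
#' @param data data.frame holding the cognitive columns.
#' @param group factor of group membership; its first level (after releveling
#'   to `reference`) is the comparison baseline.
#' @param cognitive_columns character vector of score columns.
#' @param log_columns subset of `cognitive_columns` to log-transform.
#' @param alpha significance level for contrast flags (default 0.05).
#' @param reference reference group label (default the first factor level).
#' @return data.frame of class `cognitive_comparison`: one row per test with
#'   per-group means (on the analysis scale), the ANOVA p, and one
#'   `p_<contrast>` / `sig_<contrast>` column pair per contrast.
#' @export
compare_cognitive <- function(data, group, cognitive_columns,
                              log_columns = character(), alpha = 0.05,
                              reference = NULL) {
  group <- droplevels(as.factor(group))
  if (!is.null(reference)) group <- stats::relevel(group, ref = reference)
  lev <- levels(group)
  if (length(lev) < 2) stopf("config_error", "need at least 2 groups")
  k <- length(lev)
  # contrasts: each non-reference group vs reference, then all pairs among
  # the non-reference groups
  cm <- list()
  for (i in 2:k) {
    v <- numeric(k); v[i] <- 1; v[1] <- -1
    cm[[sprintf("%s - %s", lev[i], lev[1])]] <- v
  }
  if (k > 2) {
    for (i in 2:(k - 1)) for (j in (i + 1):k) {
      v <- numeric(k); v[j] <- 1; v[i] <- -1
      cm[[sprintf("%s - %s", lev[j], lev[i])]] <- v
    }
  }
  cmat <- do.call(rbind, cm)
  colnames(cmat) <- lev

  rows <- vector("list", length(cognitive_columns))
  for (ci in seq_along(cognitive_columns)) {
    col <- cognitive_columns[ci]
    y <- data[[col]]
    if (col %in% log_columns) {
      bad <- which(!is.na(y) & y <= 0)
      if (length(bad)) {
        stopf("transform_error",
              "non-positive value in log column '%s' at row %d", col, bad[1])
      }
      y <- log(y)
    }
    d <- data.frame(y = y, g = group)
    fit <- stats::aov(y ~ g, data = d)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    glht_fit <- with_preserved_seed(20240126L,
      multcomp::glht(fit, linfct = multcomp::mcp(g = cmat)))
    ps <- with_preserved_seed(20240126L,
      summary(glht_fit, test = multcomp::adjusted("single-step"))$test$pvalues)
    means <- tapply(y, group, mean)
    row <- c(list(test = col, log_transformed = col %in% log_columns),
             stats::setNames(as.list(means), paste0("mean_", lev)),
             list(anova_p = anova_p))
    for (q in seq_len(nrow(cmat))) {
      nm <- rownames(cmat)[q]
      row[[paste0("p_", nm)]] <- as.numeric(ps[q])
      row[[paste0("sig_", nm)]] <- as.numeric(ps[q]) < alpha
    }
    rows[[ci]] <- as.data.frame(row, check.names = FALSE,
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "reference") <- lev[1]
  class(out) <- c("cognitive_comparison", "data.frame")
  out
}

#' Chi-square comparison of qualitative variables across groups
#'
#' @param data data.frame holding the qualitative (integer-coded) columns.
#' @param group factor of group membership.
#' @param qualitative_columns character vector of variables to test.
#' @return data.frame of class `qualitative_comparison`: `variable`,
#'   `statistic`, `df`, `p`; the group-by-category contingency tables are in
#'   `attr(, "tables")`.
#' @export
compare_qualitative <- function(data, group, qualitative_columns) {
  group <- droplevels(as.factor(group))
  tables <- list()
  rows <- vector("list", length(qualitative_columns))
  for (ci in seq_along(qualitative_columns)) {
    col <- qualitative_columns[ci]
    v <- factor(data[[col]])
    if (nlevels(v) < 2) {
      stopf("config_error", "variable '%s' has a single observed category", col)
    }
    tab <- table(group = group, value = v)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tables[[col]] <- tab
    rows[[ci]] <- data.frame(variable = col,
                             statistic = unname(ct$statistic),
                             df = unname(ct$parameter),
                             p = unname(ct$p.value),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "tables") <- tables
  class(out) <- c("qualitative_comparison", "data.frame")
  out
}

#' Full subtype characterization report
#'
#' Builds the three report tables for a cohort with assigned groups
#' (reference group plus subtypes): (1) per-IDP Z-scores of each subtype
#' against the reference (mean and 95% CI half-width `1.96*sd/sqrt(n)` on the
#' Z scale) with covariate-adjusted one-way ANOVA under Bonferroni control;
#' (2) cognitive comparisons with Dunnett-style contrasts (time-valued scores
#' log-transformed); (3) chi-square tests of the qualitative lifestyle
#' variables. The reference group's Z is 0 by construction and is not
#' tabulated.
#'
#' @param cohort a `cohort`.
#' @param groups factor (aligned with cohort rows, NA = excluded) or named
#'   vector/factor keyed by subject ID.
#' @param reference label of the reference group (default `"RBA"`).
#' @param q_threshold Bonferroni family threshold for IDPs (default 0.01).
#' @param alpha significance level for cognitive contrasts (default 0.05).
#' @param adjust_covariates adjust IDPs for age, sex and education before
#'   ANOVA and Z-scoring (default `TRUE`).
#' @return object of class `subtype_report` with elements `idp`, `zscores`,
#'   `cognitive`, `qualitative`, `groups`, `settings`.
#' @export
characterize_subtypes <- function(cohort, groups, reference = "RBA",
                                  q_threshold = 0.01, alpha = 0.05,
                                  adjust_covariates = TRUE) {
  schema <- cohort$schema
  ids <- subject_ids(cohort)
  if (!is.null(names(groups))) {
    groups <- groups[ids]
  } else if (length(groups) != length(ids)) {
    stopf("alignment_error", "groups must align with cohort rows or be named by ID")
  }
  keep <- !is.na(groups)
  data <- cohort$data[keep, , drop = FALSE]
  g <- droplevels(factor(groups[keep]))
  if (!reference %in% levels(g)) {
    stopf("config_error", "reference group '%s' absent from labels", reference)
  }
  g <- stats::relevel(g, ref = reference)
  covs <- NULL
  if (adjust_covariates) {
    covs <- cbind(age = data[[schema$age_column]],
                  sex = data[[schema$sex_column]],
                  education = data[[schema$education_column]])
  }
  idps <- idp_columns(schema)
  anova_tab <- anova_idps(data, g, idps, covariates = covs,
                          q_threshold = q_threshold)

  y <- as.matrix(data[, idps, drop = FALSE])
  if (!is.null(covs)) y <- adjust_covariates_glm(y, covs)
  ref_rows <- g == reference
  z <- vapply(seq_along(idps),
              function(j) zscore_vs_reference(y[, j], y[ref_rows, j]),
              numeric(nrow(y)))
  colnames(z) <- idps
  ztab <- data.frame(idp = idps, stringsAsFactors = FALSE)
  for (lv in setdiff(levels(g), reference)) {
    rows <- g == lv
    zm <- colMeans(z[rows, , drop = FALSE])
    zs <- apply(z[rows, , drop = FALSE], 2, stats::sd)
    ztab[[paste0("z_", lv)]] <- unname(zm)
    ztab[[paste0("ci_", lv)]] <- unname(1.96 * zs / sqrt(sum(rows)))
  }

  cog <- compare_cognitive(data, g, schema$cognitive_columns,
                           log_columns = schema$log_transform_columns,
                           alpha = alpha, reference = reference)
  qual <- compare_qualitative(data, g, schema$qualitative_columns)

  structure(list(idp = anova_tab, zscores = ztab, cognitive = cog,
                 qualitative = qual, groups = g,
                 settings = list(reference = reference,
                                 q_threshold = q_threshold, alpha = alpha,
                                 adjust_covariates = adjust_covariates)),
            class = "subtype_report")
}

#' @export
print.subtype_report <- function(x, ...) {
  counts <- table(x$groups)
  cat("subtype characterization report\n")
  cat("  groups:", paste(sprintf("%s (%d)", names(counts), counts),
                         collapse = ", "), "\n")
  cat(sprintf("  IDPs flagged at Bonferroni q < %g: %d of %d (per-test cutoff %.3e)\n",
              x$settings$q_threshold, sum(x$idp$significant), nrow(x$idp),
              attr(x$idp, "cutoff")))
  sig_cols <- grep("^sig_", names(x$cognitive), value = TRUE)
  cat(sprintf("  cognitive tests with >= 1 significant contrast: %d of %d\n",
              sum(rowSums(as.matrix(x$cognitive[sig_cols])) > 0),
              nrow(x$cognitive)))
  cat(sprintf("  qualitative variables (chi-square p): %s\n",
              paste(sprintf("%s %.3g", x$qualitative$variable,
                            x$qualitative$p), collapse = ", ")))
  invisible(x)
}
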
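test_that("zscore_vs_reference standardizes against the reference moments", {
  ref <- c(8, 10, 12, 10)  # mean 10
  z <- zscore_vs_reference(14, ref)
  expect_equal(z, (14 - 10) / sd(ref))
  zz <- zscore_vs_reference(ref, ref)
  expect_lt(abs(mean(zz)), 1e-8)
  expect_equal(sd(zz), 1, tolerance = 1e-8)
  expect_error(zscore_vs_reference(1, rep(5, 4)),
               class = "degenerate_reference_error")
  expect_error(zscore_vs_reference(1, 3), class = "degenerate_reference_error")
})

test_that("covariate adjustment removes exact covariate signals and centers residuals", {
  set.seed(2)
  n <- 120
  covs <- cbind(age = runif(n, 45, 83), sex = rbinom(n, 1, 0.5),
                education = sample(10:20, n, TRUE))
  adj <- adjust_covariates_glm(3 * covs[, "age"], covs)
  expect_lt(max(abs(adj)), 1e-8)
  y <- rnorm(n)
  adj2 <- adjust_covariates_glm(y, covs)
  expect_lt(abs(mean(adj2)), 1e-10)
  expect_error(adjust_covariates_glm(y, cbind(covs, covs[, 1] * 2)),
               class = "rank_deficiency_error")
})

test_that("adjustment barely changes covariate-independent values", {
  set.seed(3)
  n <- 2000
  covs <- cbind(age = runif(n, 45, 83), sex = rbinom(n, 1, 0.5),
                education = sample(10:20, n, TRUE))
  y <- rnorm(n)
  expect_gt(cor(y, adjust_covariates_glm(y, covs)), 0.99)
})

test_that("anova_idps matches anova(lm()) per column and applies the Bonferroni cutoff", {
  set.seed(4)
  n <- 90
  g <- factor(rep(c("RBA", "S1", "S2"), each = 30))
  dat <- data.frame(i1 = rnorm(n), i2 = rnorm(n) + (g == "S2") * 2,
                    i3 = rnorm(n))
  res <- anova_idps(dat, g, c("i1", "i2", "i3"), q_threshold = 0.01)
  for (col in c("i1", "i2", "i3")) {
    ref <- anova(lm(dat[[col]] ~ g))
    expect_equal(res$F[res$idp == col], ref$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p[res$idp == col], ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_equal(attr(res, "cutoff"), 0.01 / 3)
  expect_identical(res$significant, res$p < 0.01 / 3)
  # the planted 2-SD offset is flagged, with 561 tests the cutoff is ~1.78e-5
  n2 <- 800
  g2 <- factor(rep(c("RBA", "S1", "S2", "S3"), each = 200))
  m <- 561
  dat2 <- as.data.frame(matrix(rnorm(n2 * m), n2, m))
  names(dat2) <- sprintf("idp_%03d", 1:m)
  dat2$idp_001 <- dat2$idp_001 + (g2 == "S2") * 2
  res2 <- anova_idps(dat2, g2, names(dat2), q_threshold = 0.01)
  expect_equal(attr(res2, "cutoff"), 0.01 / 561)
  expect_true(res2$significant[res2$idp == "idp_001"])
  expect_lt(mean(res2$significant), 0.01)
  # group with < 2 subjects errors
  expect_error(anova_idps(dat, factor(c("A", rep("B", n - 1))), "i1"),
               class = "config_error")
})

test_that("anova_idps with covariates matches the two-step lm oracle", {
  set.seed(5)
  n <- 150
  g <- factor(rep(c("RBA", "S1", "S2"), each = 50))
  covs <- cbind(age = runif(n, 45, 83), sex = rbinom(n, 1, 0.5),
                education = sample(10:20, n, TRUE))
  dat <- data.frame(i1 = rnorm(n) + 0.05 * covs[, "age"])
  res <- anova_idps(dat, g, "i1", covariates = covs)
  adj <- resid(lm(dat$i1 ~ covs))
  ref <- anova(lm(adj ~ g))
  expect_equal(res$F[1], ref$`F value`[1], tolerance = 1e-10)
})

test_that("compare_cognitive log-transforms only the designated columns and flags deficits", {
  set.seed(6)
  n <- 240
  g <- factor(rep(c("RBA", "S1", "S2"), each = 80))
  dat <- data.frame(
    fluid = rnorm(n, 7) - (g == "S2") * 1.5,
    rt = exp(rnorm(n, 6.3, 0.1) + (g == "S2") * 0.4),
    memory = rnorm(n, 6.8))
  res <- compare_cognitive(dat, g, c("fluid", "rt", "memory"),
                           log_columns = "rt", reference = "RBA")
  # means of the log column are on the log scale, others untouched
  expect_equal(res$mean_RBA[res$test == "rt"],
               mean(log(dat$rt[g == "RBA"])), tolerance = 1e-10)
  expect_equal(res$mean_RBA[res$test == "fluid"],
               mean(dat$fluid[g == "RBA"]), tolerance = 1e-10)
  expect_true(res$log_transformed[res$test == "rt"])
  expect_false(res$log_transformed[res$test == "fluid"])
  # planted deficits are flagged for the S2 contrasts
  expect_true(res[res$test == "fluid", "sig_S2 - RBA"])
  expect_true(res[res$test == "rt", "sig_S2 - RBA"])
  expect_true(res[res$test == "fluid", "sig_S2 - S1"])
  # a clean column has no flags
  sig_cols <- grep("^sig_", names(res), value = TRUE)
  expect_equal(sum(unlist(res[res$test == "memory", sig_cols])), 0)
  # non-positive values in a log column are a transform error naming the row
  dat$rt[5] <- 0
  expect_error(compare_cognitive(dat, g, "rt", log_columns = "rt"),
               "row 5", class = "transform_error")
})

test_that("compare_cognitive is deterministic", {
  set.seed(7)
  n <- 120
  g <- factor(rep(c("RBA", "S1", "S2"), each = 40))
  dat <- data.frame(a = rnorm(n), b = rnorm(n))
  r1 <- compare_cognitive(dat, g, c("a", "b"))
  r2 <- compare_cognitive(dat, g, c("a", "b"))
  expect_identical(r1, r2)
})

test_that("compare_qualitative matches the chi-square formula", {
  g <- factor(rep(c("A", "B"), each = 60))
  # perfectly homogeneous 2x2: statistic 0, p 1
  v_h <- rep(rep(c(0, 1), each = 30), 2)
  res_h <- compare_qualitative(data.frame(v = v_h), g, "v")
  expect_equal(res_h$statistic, 0)
  expect_equal(res_h$p, 1)
  # [[50,10],[10,50]] against the hand-computed sum((O-E)^2/E)
  g2 <- factor(rep(c("A", "B"), each = 60))
  v2 <- c(rep(0, 50), rep(1, 10), rep(0, 10), rep(1, 50))
  res2 <- compare_qualitative(data.frame(v = v2), g2, "v")
  o <- matrix(c(50, 10, 10, 50), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  expect_equal(res2$statistic, sum((o - e)^2 / e), tolerance = 1e-12)
  tab <- attr(res2, "tables")$v
  expect_equal(sum(tab), 120)
  expect_error(compare_qualitative(data.frame(v = rep(1, 10)),
                                   factor(rep(c("A", "B"), 5)), "v"),
               class = "config_error")
})

test_that("characterize_subtypes assembles a coherent report on a synthetic cohort", {
  cfg <- small_config(n = 900, seed = 31, aba_fraction = 0.4)
  sim <- generate_cohort(cfg)
  co <- sim$cohort
  lab <- sim$truth$subtype_label
  groups <- ifelse(is.na(lab), "RBA", sprintf("SubGroup%d", lab))
  names(groups) <- names(lab)
  rep <- characterize_subtypes(co, groups, reference = "RBA")
  expect_s3_class(rep, "subtype_report")
  expect_equal(nrow(rep$idp), length(idp_columns(co$schema)))
  expect_equal(nrow(rep$cognitive), 9)
  expect_equal(nrow(rep$qualitative), 2)
  # planted subtype offsets produce flagged IDPs
  expect_gt(sum(rep$idp$significant), 0)
  # Z columns exist for each subtype and CIs are positive
  expect_true(all(c("z_SubGroup1", "ci_SubGroup1") %in% names(rep$zscores)))
  expect_true(all(rep$zscores$ci_SubGroup1 > 0))
  expect_error(characterize_subtypes(co, groups, reference = "nope"),
               class = "config_error")
})
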
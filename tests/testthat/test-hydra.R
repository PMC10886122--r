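test_that("residualization zeroes covariate-driven features and centers the reference", {
  set.seed(1)
  n <- 80
  covs <- cbind(age = runif(n, 45, 83), sex = rbinom(n, 1, 0.5),
                education = sample(10:20, n, TRUE))
  feats <- cbind(f1 = 2 * covs[, "age"],
                 f2 = rnorm(n),
                 f3 = covs[, "sex"] - 0.1 * covs[, "education"] + rnorm(n))
  ref <- rep(c(TRUE, FALSE), n / 2)
  res <- residualize_covariates(feats, covs, ref)
  expect_lt(max(abs(res$features[, "f1"])), 1e-6)
  expect_lt(max(abs(colMeans(res$features[ref, ]))), 1e-8)
  expect_equal(unname(apply(res$features[ref, c("f2", "f3")], 2, sd)),
               rep(1, 2), tolerance = 1e-8)
  # zero-variance feature dropped with a warning
  feats2 <- cbind(feats, f4 = 1)
  expect_warning(res2 <- residualize_covariates(feats2, covs, ref),
                 "zero-variance")
  expect_equal(ncol(res2$features), 3)
  # collinear covariates rejected
  expect_error(residualize_covariates(feats, cbind(covs, covs[, 1]), ref),
               class = "rank_deficiency_error")
})

test_that("residualization is a no-op (up to noise) when covariate effects are zero", {
  cfg <- small_config(n = 600, seed = 3,
                      covariate_effects = c(sex = 0, education = 0))
  sim <- generate_cohort(cfg)
  co <- sim$cohort
  x <- as.matrix(co$data[, idp_columns(co$schema)])
  covs <- cbind(sex = co$data$sex, education = co$data$education_years)
  res <- residualize_covariates(x, covs, rep(TRUE, nrow(x)))
  # residualized features stay essentially perfectly correlated with originals
  cors <- vapply(seq_len(ncol(x)),
                 function(j) cor(x[, j], res$features[, j]), numeric(1))
  expect_gt(min(cors), 0.99)
})

test_that("DPP initialization separates antipodal clouds and is locally det-optimal", {
  toy <- separable_toy(n_per = 10, seed = 2)
  xt <- toy$x[toy$is_target, ]
  xc <- toy$x[!toy$is_target, ]
  init <- dpp_initialize(xt, xc, K = 2, n_candidates = 10, seed = 1)
  expect_equal(adjusted_rand_index(init$assignments, toy$truth), 1.0)
  # K = 1: everything in one cluster
  init1 <- dpp_initialize(xt, xc, K = 1, n_candidates = 5, seed = 1)
  expect_true(all(init1$assignments == 1L))
  # local optimality: no single swap of a selected direction increases the
  # Gram determinant
  set.seed(9)
  xt2 <- matrix(rnorm(40 * 8), 40, 8)
  xc2 <- matrix(rnorm(30 * 8), 30, 8)
  init2 <- dpp_initialize(xt2, xc2, K = 3, n_candidates = 40, seed = 4)
  centroid <- colMeans(xc2)
  dirs <- sweep(xt2, 2, centroid)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  sel_dirs <- init2$directions
  gram_det <- function(d) det((1 + tcrossprod(d)) / 2)
  base <- gram_det(sel_dirs)
  for (i in 1:3) for (j in seq_len(nrow(dirs))) {
    trial <- sel_dirs
    trial[i, ] <- dirs[j, ]
    expect_lte(gram_det(trial), base + 1e-9)
  }
  expect_error(dpp_initialize(xt2, xc2, K = 5, n_candidates = 3),
               class = "init_error")
})

test_that("the one-face polytope equals a directly fitted weighted classifier", {
  toy <- separable_toy(n_per = 8, seed = 3)
  fp <- fit_polytope(toy$x, toy$is_target, K = 1, C = 1, svm_gtol = 1e-8)
  direct <- svm_squared_hinge(toy$x, ifelse(toy$is_target, 1, -1),
                              weights = rep(1, nrow(toy$x)), C = 1)
  dec_fp <- drop(toy$x %*% fp$hyperplane_weights[1, ]) + fp$hyperplane_offsets[1]
  expect_lt(max(abs(dec_fp - decision_values(direct, toy$x))), 1e-6)
})

test_that("assignment step picks the face with maximal decision value, ties to lowest index", {
  model <- structure(list(K = 2L,
                          hyperplane_weights = rbind(c(1, 0), c(0, 1)),
                          hyperplane_offsets = c(0, 0)),
                     class = "polytope_model")
  expect_equal(assign_clusters(model, rbind(c(2, 1))), 1L)
  expect_equal(assign_clusters(model, rbind(c(1, 2))), 2L)
  expect_equal(assign_clusters(model, rbind(c(1, 1))), 1L)  # tie -> face 1
  expect_error(assign_clusters(model, matrix(1, 1, 3)), class = "dimension_error")
})

test_that("labels are invariant under a joint rotation of features and hyperplanes", {
  toy <- separable_toy(n_per = 8, seed = 4)
  fp <- fit_polytope(toy$x, toy$is_target, K = 2, seed = 1)
  theta <- 0.7
  q <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  rotated <- fp
  rotated$hyperplane_weights <- fp$hyperplane_weights %*% q
  xt <- toy$x[toy$is_target, ]
  expect_identical(assign_clusters(rotated, xt %*% q),
                   assign_clusters(fp, xt))
})

test_that("the polytope objective trace is non-increasing and assignments are a fixed point", {
  for (seed in 1:4) {
    toy <- separable_toy(n_per = 7, n_controls = 16, seed = seed)
    fp <- fit_polytope(toy$x, toy$is_target, K = 2, seed = seed)
    expect_false(fp$reseeded)
    expect_true(all(diff(fp$objective_trace) <= 1e-8))
    expect_true(fp$converged)
    xt <- toy$x[toy$is_target, ]
    expect_identical(assign_clusters(fp, xt), fp$assignments)
  }
})

test_that("controls end up on the negative side of every face on separable toys", {
  toy <- separable_toy(n_per = 8, n_controls = 20, sep = 8, seed = 6)
  fp <- fit_polytope(toy$x, toy$is_target, K = 2, seed = 2)
  xc <- toy$x[!toy$is_target, ]
  dec <- xc %*% t(fp$hyperplane_weights) +
    matrix(fp$hyperplane_offsets, nrow(xc), 2, byrow = TRUE)
  expect_true(all(dec < 0))
})

test_that("adjusted Rand index matches identity, permutation and oracle cases", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1.0)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1.0)
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, b), ari_pair_counting(a, b))
  # random partitions against both oracles
  set.seed(12)
  for (r in 1:10) {
    pa <- sample(1:3, 25, TRUE)
    pb <- sample(1:4, 25, TRUE)
    expect_equal(adjusted_rand_index(pa, pb), ari_pair_counting(pa, pb),
                 tolerance = 1e-12)
    if (requireNamespace("mclust", quietly = TRUE)) {
      expect_equal(adjusted_rand_index(pa, pb),
                   mclust::adjustedRandIndex(pa, pb), tolerance = 1e-12)
    }
  }
  expect_error(adjusted_rand_index(1:3, 1:4), class = "alignment_error")
})

test_that("consensus fusion is invariant to label permutations and robust to noise", {
  set.seed(8)
  truth <- rep(1:3, each = 20)
  # single run comes back unchanged up to renaming
  single <- consensus_fuse(list(truth), K = 3)
  expect_equal(adjusted_rand_index(single, truth), 1.0)
  # identical runs under label permutations fuse to the same partition
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  runs <- lapply(perms, function(p) p[truth])
  fused <- consensus_fuse(runs, K = 3)
  expect_equal(adjusted_rand_index(fused, truth), 1.0)
  # 20 noisy runs: fused labels at least as good as the best single run - 0.05
  noisy <- lapply(1:20, function(r) {
    lab <- truth
    flip <- sample(60, 9)
    lab[flip] <- sample(1:3, 9, TRUE)
    sample(1:3)[lab]
  })
  fused2 <- consensus_fuse(noisy, K = 3)
  best_single <- max(vapply(noisy, adjusted_rand_index, numeric(1), truth))
  expect_gte(adjusted_rand_index(fused2, truth), best_single - 0.05)
  expect_error(consensus_fuse(list(1:3, 1:4), K = 2), class = "alignment_error")
})

test_that("hydra recovers planted clusters on a small separable problem", {
  toy <- separable_toy(n_per = 15, n_controls = 30, sep = 5, seed = 10)
  h <- hydra(toy$x, toy$is_target, K = 2, n_init = 3, n_candidates = 10,
             seed = 3)
  expect_equal(adjusted_rand_index(h$assignments, toy$truth), 1.0)
  expect_identical(predict(h, toy$x[toy$is_target, ]), h$assignments)
})

test_that("cluster_stability rejects K < 2 and returns one entry per K", {
  set.seed(20)
  xc <- matrix(rnorm(60 * 4), 60, 4)
  centers <- rbind(c(5, 0, 0, 0), c(0, 5, 0, 0), c(0, 0, 5, 0))
  xt <- centers[rep(1:3, each = 15), ] + matrix(rnorm(45 * 4, 0, 0.4), 45, 4)
  x <- rbind(xc, xt)
  is_target <- c(rep(FALSE, 60), rep(TRUE, 45))
  expect_error(cluster_stability(x, is_target, k_range = 1:3),
               class = "config_error")
  curve <- cluster_stability(x, is_target, k_range = 2:4, n_folds = 3,
                             n_init = 2, n_candidates = 10, seed = 5)
  expect_length(curve$mean_ari, 3)
  expect_true(all(curve$mean_ari >= -1 & curve$mean_ari <= 1))
  expect_true(curve$selected_k %in% 2:4)
  # a strongly separated 3-cluster layout is maximally stable at the true K
  # (on a toy this clean, merging two clusters at K = 2 can be equally
  # reproducible, so K = 3 must attain the maximum but may tie)
  expect_gte(curve$mean_ari[curve$k_values == 3], max(curve$mean_ari) - 1e-9)
  expect_gt(curve$mean_ari[curve$k_values == 3], 0.95)
})

test_that("polytope inputs are validated", {
  toy <- separable_toy(seed = 11)
  expect_error(fit_polytope(toy$x, toy$is_target[-1], K = 2),
               class = "alignment_error")
  expect_error(fit_polytope(toy$x, rep(TRUE, nrow(toy$x)), K = 2),
               class = "config_error")
  expect_error(fit_polytope(toy$x, toy$is_target, K = 2,
                            init = rep(5L, sum(toy$is_target))),
               class = "init_error")
})
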
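#' Residualize features on nuisance covariates against a reference group
#'
#' For each feature, ordinary least squares of the feature on the covariates
#' (plus intercept) is fitted on reference-group rows only; residuals are
#' formed for all rows with those coefficients and standardized by the
#' reference-group residual SD. Reference-group residuals therefore have mean
#' 0 and SD 1 per feature. Zero-variance features are dropped with a warning.
#'
#' @param features numeric matrix (subjects x features).
#' @param covariates numeric matrix or data.frame of nuisance covariates
#'   (age, sex, education), aligned with `features` rows.
#' @param reference_mask logical vector marking the reference (control) rows
#'   used to fit the regressions.
#' @return object of class `residualized_features`: `features` (residualized,
#'   standardized), `coefficients`, `scale`, `dropped`, `reference_mask`.
#' @export
residualize_covariates <- function(features, covariates, reference_mask) {
  x <- as.matrix(features)
  z <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (nrow(z) != nrow(x)) stopf("alignment_error", "covariates do not match features")
  reference_mask <- as.logical(reference_mask)
  if (!any(reference_mask)) stopf("config_error", "reference group is empty")
  if (anyNA(x) || anyNA(z)) stopf("validation_error", "missing values not allowed")
  zr <- z[reference_mask, , drop = FALSE]
  qz <- qr(zr)
  if (qz$rank < ncol(zr)) stopf("rank_deficiency_error", "collinear covariates")
  # features without variance in the reference group carry no signal: drop
  in_sd <- apply(x[reference_mask, , drop = FALSE], 2, stats::sd)
  drop_idx <- which(in_sd <= sqrt(.Machine$double.eps))
  if (length(drop_idx)) {
    warning(sprintf("dropping %d zero-variance feature(s)", length(drop_idx)))
    x <- x[, -drop_idx, drop = FALSE]
  }
  beta <- qr.coef(qz, x[reference_mask, , drop = FALSE])
  resid <- x - z %*% beta
  ref_sd <- apply(resid[reference_mask, , drop = FALSE], 2, stats::sd)
  # features perfectly explained by the covariates stay as (exact) zeros
  ref_sd[ref_sd <= sqrt(.Machine$double.eps)] <- 1
  resid <- sweep(resid, 2, ref_sd, "/")
  structure(list(features = resid, coefficients = beta, scale = ref_sd,
                 dropped = drop_idx, reference_mask = reference_mask),
            class = "residualized_features")
}

# accept either a raw matrix or a residualized_features object
feature_matrix <- function(features) {
  if (inherits(features, "residualized_features")) features$features
  else as.matrix(features)
}

#' Diverse initialization via a greedy k-DPP over aging directions
#'
#' Candidate directions are unit-normalized differences between randomly
#' chosen target subjects and the control centroid. A size-`K` subset is
#' selected to maximize the determinant of the similarity kernel
#' `(1 + cosine)/2` over the candidates (greedy max-determinant selection
#' followed by single-swap ascent, a deterministic approximation to k-DPP
#' sampling). The affine map of the linear-kernel Gram matrix makes
#' antipodal directions maximally diverse instead of collinear. Each target
#' is then assigned to the selected direction of largest cosine similarity.
#'
#' @param targets matrix of target-group rows.
#' @param controls matrix of control-group rows.
#' @param K number of initial clusters.
#' @param n_candidates number of candidate directions to draw.
#' @param seed integer seed (candidate draw).
#' @return list: `assignments` (length `nrow(targets)`, values 1..K),
#'   `directions` (K x p), `candidates` (row indices), `log_det`.
#' @export
dpp_initialize <- function(targets, controls, K, n_candidates = 50L, seed = 1L) {
  targets <- as.matrix(targets)
  controls <- as.matrix(controls)
  if (K < 1) stopf("config_error", "K must be >= 1")
  if (n_candidates < K) stopf("init_error", "n_candidates must be >= K")
  if (!nrow(targets)) stopf("init_error", "no target subjects")
  centroid <- colMeans(controls)
  nt <- nrow(targets)
  cand <- with_preserved_seed(seed, sample.int(nt, min(n_candidates, nt)))
  dirs <- sweep(targets[cand, , drop = FALSE], 2, centroid)
  nrm <- sqrt(rowSums(dirs^2))
  ok <- nrm > sqrt(.Machine$double.eps)
  cand <- cand[ok]
  dirs <- dirs[ok, , drop = FALSE] / nrm[ok]
  if (nrow(dirs) < K) stopf("init_error", "fewer than K distinct candidate directions")
  # similarity kernel (1 + cosine)/2 over the unit directions: 1 for aligned
  # candidates, 0 for antipodal ones, so opposite aging directions count as
  # maximally diverse (a raw Gram determinant would treat them as collinear)
  gram <- (1 + tcrossprod(dirs)) / 2

  subset_det <- function(s) det(gram[s, s, drop = FALSE])
  selected <- integer(0)
  for (step in seq_len(K)) {
    rest <- setdiff(seq_len(nrow(dirs)), selected)
    gains <- vapply(rest, function(j) subset_det(c(selected, j)), numeric(1))
    selected <- c(selected, rest[which.max(gains)])
  }
  # single-swap ascent to local optimality of the Gram determinant
  repeat {
    improved <- FALSE
    cur <- subset_det(selected)
    for (i in seq_along(selected)) {
      rest <- setdiff(seq_len(nrow(dirs)), selected)
      for (j in rest) {
        trial <- selected
        trial[i] <- j
        v <- subset_det(trial)
        if (v > cur + 1e-12) {
          selected <- trial
          cur <- v
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  chosen <- dirs[selected, , drop = FALSE]
  tdir <- sweep(targets, 2, centroid)
  tn <- sqrt(rowSums(tdir^2))
  tn[tn == 0] <- 1
  sim <- (tdir / tn) %*% t(chosen)
  assignments <- max.col(sim, ties.method = "first")
  list(assignments = assignments, directions = chosen,
       candidates = cand[selected], log_det = log(max(subset_det(selected), 0)))
}

#' Fit a convex polytope of max-margin classifiers (one HYDRA run)
#'
#' Alternating optimization: (estimation) for each face `j` a weighted
#' squared-hinge linear classifier is fitted on all controls (label -1,
#' weight 1/K each, so total control influence is constant in K) plus the
#' targets currently assigned to face `j` (label +1, weight 1), warm-started
#' from the previous hyperplane; (assignment) each target moves to the face
#' with maximal decision value. Iterations stop when assignments no longer
#' change or `max_iter` is reached. The recorded objective is the sum over
#' faces of `0.5*||w_j||^2 + C * weighted squared hinge loss` and is
#' non-increasing across iterations (warm starts guarantee the estimation
#' step never increases it; an empty face triggers a reseed with the worst
#' target, flagged on the result).
#'
#' @param features matrix or [residualize_covariates()] output.
#' @param is_target logical vector: `TRUE` for target rows, `FALSE` controls.
#' @param K number of polytope faces (subtypes).
#' @param C margin/loss trade-off.
#' @param init initial face assignment of targets (1..K); defaults to
#'   [dpp_initialize()].
#' @param max_iter maximum alternations.
#' @param seed integer seed (used by the default initialization).
#' @param n_candidates candidate count for the default initialization.
#' @param svm_maxit,svm_gtol optimizer controls for face classifiers.
#' @return object of class `polytope_model`: `K`, `hyperplane_weights`
#'   (K x p), `hyperplane_offsets`, `assignments`, `objective_trace`,
#'   `converged`, `reseeded`, `C`, `seed`.
#' @export
fit_polytope <- function(features, is_target, K, C = 0.01, init = NULL,
                         max_iter = 50L, seed = 1L, n_candidates = 50L,
                         svm_maxit = 100L, svm_gtol = 1e-6) {
  x <- feature_matrix(features)
  is_target <- as.logical(is_target)
  if (length(is_target) != nrow(x)) {
    stopf("alignment_error", "is_target does not match feature rows")
  }
  xt <- x[is_target, , drop = FALSE]
  xc <- x[!is_target, , drop = FALSE]
  nt <- nrow(xt)
  nc <- nrow(xc)
  if (!nt || !nc) stopf("config_error", "both groups must be nonempty")
  if (K < 1) stopf("config_error", "K must be >= 1")
  if (nt < K) stopf("config_error", "fewer targets than faces")
  if (is.null(init)) {
    init <- dpp_initialize(xt, xc, K, n_candidates = n_candidates,
                           seed = seed)$assignments
  }
  assign <- as.integer(init)
  if (length(assign) != nt || any(assign < 1L | assign > K)) {
    stopf("init_error", "init must assign every target to a face in 1..K")
  }
  # guarantee no empty faces at the start
  for (j in seq_len(K)) {
    if (!any(assign == j)) {
      src <- which(tabulate(assign, K)[assign] > 1L)[1]
      if (is.na(src)) stopf("init_error", "cannot populate face %d", j)
      assign[src] <- j
    }
  }

  p <- ncol(x)
  W <- matrix(0, K, p)
  b <- numeric(K)
  trace <- numeric(0)
  converged <- FALSE
  reseeded <- FALSE
  y_c <- rep(-1, nc)
  w_c <- rep(1 / K, nc)

  for (it in seq_len(max_iter)) {
    obj <- 0
    for (j in seq_len(K)) {
      rows <- which(assign == j)
      xf <- rbind(xc, xt[rows, , drop = FALSE])
      yf <- c(y_c, rep(1, length(rows)))
      sf <- c(w_c, rep(1, length(rows)))
      warm <- if (it == 1L) NULL else c(W[j, ], b[j])
      fit <- svm_squared_hinge(xf, yf, sf, C = C, init = warm,
                               maxit = svm_maxit, gtol = svm_gtol)
      W[j, ] <- fit$w
      b[j] <- fit$b
      obj <- obj + fit$objective
    }
    trace <- c(trace, obj)
    dec <- xt %*% t(W) + matrix(b, nt, K, byrow = TRUE)
    new_assign <- max.col(dec, ties.method = "first")
    # reseed empty faces with the worst-explained target
    reseeded_now <- FALSE
    repeat {
      counts <- tabulate(new_assign, K)
      empty <- which(counts == 0L)
      if (!length(empty)) break
      movable <- which(counts[new_assign] > 1L)
      worst <- movable[which.min(apply(dec[movable, , drop = FALSE], 1, max))]
      new_assign[worst] <- empty[1]
      reseeded <- TRUE
      reseeded_now <- TRUE
    }
    # convergence requires a pure argmax fixed point (no forced reseed), so
    # converged models satisfy assignments == assign_clusters(model, targets)
    if (identical(new_assign, assign)) {
      if (!reseeded_now) converged <- TRUE
      break
    }
    assign <- new_assign
  }
  dimnames(W) <- list(sprintf("face_%d", seq_len(K)), colnames(x))
  structure(list(K = K, hyperplane_weights = W, hyperplane_offsets = b,
                 assignments = assign, objective_trace = trace,
                 converged = converged, reseeded = reseeded, C = C,
                 seed = seed, n_iter = length(trace)),
            class = "polytope_model")
}

#' Assign subjects to polytope faces
#'
#' Each subject goes to the face with the largest decision value
#' `w_j . x + b_j`; ties break to the lowest face index.
#'
#' @param model a `polytope_model` (or `hydra` fit).
#' @param features matrix with the model's feature dimension.
#' @return integer label vector in 1..K.
#' @export
assign_clusters <- function(model, features) {
  if (inherits(model, "hydra")) model <- model$model
  x <- feature_matrix(features)
  W <- model$hyperplane_weights
  if (ncol(x) != ncol(W)) {
    stopf("dimension_error", "feature dimension %d does not match model (%d)",
          ncol(x), ncol(W))
  }
  dec <- x %*% t(W) + matrix(model$hyperplane_offsets, nrow(x), model$K, byrow = TRUE)
  max.col(dec, ties.method = "first")
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-model chance-corrected agreement computed from the contingency
#' table: 1 for identical partitions (up to label renaming), expected 0 for
#' independent ones.
#'
#' @param labels_a,labels_b label vectors of equal length (>= 2).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stopf("alignment_error", "label vectors have different lengths")
  }
  n <- length(labels_a)
  if (n < 2) stopf("config_error", "need at least 2 elements")
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  expected <- sum_i * sum_j / total
  maximum <- (sum_i + sum_j) / 2
  if (abs(maximum - expected) < .Machine$double.eps) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' Fuse multiple cluster assignments by co-assignment consensus
#'
#' Builds the co-assignment matrix (fraction of runs in which two subjects
#' share a cluster) and cuts an average-linkage hierarchical clustering of
#' `1 - co-assignment` into `K` groups. Deterministic given its inputs.
#'
#' @param assignment_list list of equal-length label vectors.
#' @param K number of fused clusters.
#' @param seed unused; kept for interface stability.
#' @return integer label vector in 1..K.
#' @export
consensus_fuse <- function(assignment_list, K, seed = NULL) {
  if (!length(assignment_list)) stopf("config_error", "no assignments to fuse")
  n <- length(assignment_list[[1]])
  if (any(vapply(assignment_list, length, integer(1)) != n)) {
    stopf("alignment_error", "assignment vectors have different lengths")
  }
  co <- matrix(0, n, n)
  for (a in assignment_list) co <- co + outer(a, a, "==")
  co <- co / length(assignment_list)
  hc <- stats::hclust(stats::as.dist(1 - co), method = "average")
  unname(stats::cutree(hc, k = K))
}

#' Fit HYDRA with multi-initialization consensus
#'
#' Runs [fit_polytope()] from `n_init` diverse (k-DPP) initializations, fuses
#' the resulting assignments with [consensus_fuse()], and refits the polytope
#' once from the fused assignment. Because the alternating optimization is
#' non-convex, the returned model is the candidate with the lowest polytope
#' objective among the fused refit and the individual runs (ties prefer the
#' fused refit); it provides the final subtype labels and the hyperplanes
#' used by [predict.hydra()].
#'
#' @inheritParams fit_polytope
#' @param n_init number of fused initializations.
#' @return object of class `hydra`: `model` (selected `polytope_model`),
#'   `assignments`, `fused_init`, `objective`, `selected` (`"fused"` or the
#'   run index), `runs` (per-run assignments and final objectives), `K`,
#'   `seed`.
#' @export
hydra <- function(features, is_target, K, C = 0.01, n_init = 10L,
                  n_candidates = 50L, max_iter = 50L, seed = 1L,
                  svm_maxit = 100L, svm_gtol = 1e-6) {
  x <- feature_matrix(features)
  runs <- vector("list", n_init)
  for (r in seq_len(n_init)) {
    runs[[r]] <- fit_polytope(x, is_target, K, C = C,
                              max_iter = max_iter,
                              seed = derive_seed(seed, r),
                              n_candidates = n_candidates,
                              svm_maxit = svm_maxit, svm_gtol = svm_gtol)
  }
  fused <- consensus_fuse(lapply(runs, `[[`, "assignments"), K)
  refit <- fit_polytope(x, is_target, K, C = C, init = fused,
                        max_iter = max_iter, seed = seed,
                        svm_maxit = svm_maxit, svm_gtol = svm_gtol)
  objs <- vapply(runs, function(r) utils::tail(r$objective_trace, 1), numeric(1))
  refit_obj <- utils::tail(refit$objective_trace, 1)
  if (any(objs < refit_obj - 1e-12)) {
    best <- which.min(objs)
    final <- runs[[best]]
    selected <- best
  } else {
    final <- refit
    selected <- "fused"
  }
  structure(list(model = final, assignments = final$assignments,
                 fused_init = fused,
                 objective = utils::tail(final$objective_trace, 1),
                 selected = selected,
                 runs = lapply(runs, function(r) {
                   list(assignments = r$assignments,
                        objective = utils::tail(r$objective_trace, 1),
                        converged = r$converged)
                 }),
                 K = K, C = C, n_init = n_init, seed = seed),
            class = "hydra")
}

#' @export
predict.hydra <- function(object, features, ...) {
  assign_clusters(object$model, features)
}

#' @export
print.hydra <- function(x, ...) {
  sizes <- tabulate(x$assignments, x$K)
  cat(sprintf("HYDRA fit: K = %d faces, %d targets (cluster sizes %s), %d fused runs\n",
              x$K, length(x$assignments), paste(sizes, collapse = "/"),
              x$n_init))
  cat(sprintf("  final objective %.4f, converged: %s\n",
              utils::tail(x$model$objective_trace, 1), x$model$converged))
  invisible(x)
}

#' @export
print.polytope_model <- function(x, ...) {
  cat(sprintf("polytope model: K = %d, %d targets, %d iterations, converged: %s\n",
              x$K, length(x$assignments), x$n_iter, x$converged))
  invisible(x)
}

#' Cross-validated cluster-stability curve over K
#'
#' For each `K` in `k_range` the targets are split into `n_folds` folds; a
#' fused HYDRA model is fitted on each fold's training portion (all controls
#' plus the other folds' targets) and its training-target assignments are
#' recorded. Stability at `K` is the mean pairwise adjusted Rand index
#' between fold solutions on their shared targets. The selected `K`
#' maximizes mean ARI, with ties broken toward the smaller `K`.
#'
#' @inheritParams hydra
#' @param k_range integer vector of candidate cluster counts (all >= 2; the
#'   default follows the two-to-five sweep).
#' @param n_folds number of cross-validation folds.
#' @return object of class `stability_curve`: `k_values`, `mean_ari`,
#'   `pair_ari`, `fold_assignments`, `selected_k`.
#' @export
cluster_stability <- function(features, is_target, k_range = 2:5,
                              n_folds = 5L, n_init = 10L, C = 0.01,
                              n_candidates = 50L, max_iter = 50L, seed = 1L,
                              svm_maxit = 100L, svm_gtol = 1e-6) {
  if (any(k_range < 2)) {
    stopf("config_error", "stability is undefined for K < 2 (ARI needs >= 2 clusters)")
  }
  x <- feature_matrix(features)
  is_target <- as.logical(is_target)
  t_idx <- which(is_target)
  nt <- length(t_idx)
  if (nt < n_folds) stopf("config_error", "fewer targets than folds")
  fold <- with_preserved_seed(derive_seed(seed, 1L),
                              sample(rep(seq_len(n_folds), length.out = nt)))
  k_range <- sort(unique(as.integer(k_range)))
  mean_ari <- numeric(length(k_range))
  pair_ari <- vector("list", length(k_range))
  fold_assignments <- vector("list", length(k_range))
  names(fold_assignments) <- names(pair_ari) <- paste0("K", k_range)

  for (ki in seq_along(k_range)) {
    K <- k_range[ki]
    labels <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      train_t <- t_idx[fold != f]
      rows <- c(which(!is_target), train_t)
      fit <- hydra(x[rows, , drop = FALSE],
                   is_target = rows %in% train_t, K = K, C = C,
                   n_init = n_init, n_candidates = n_candidates,
                   max_iter = max_iter,
                   seed = derive_seed(seed, 100L * K + f),
                   svm_maxit = svm_maxit, svm_gtol = svm_gtol)
      labels[[f]] <- stats::setNames(fit$assignments, train_t)
    }
    pairs <- utils::combn(n_folds, 2)
    ari <- numeric(ncol(pairs))
    for (q in seq_len(ncol(pairs))) {
      f <- pairs[1, q]; g <- pairs[2, q]
      shared <- as.character(t_idx[fold != f & fold != g])
      ari[q] <- adjusted_rand_index(labels[[f]][shared], labels[[g]][shared])
    }
    mean_ari[ki] <- mean(ari)
    pair_ari[[ki]] <- ari
    fold_assignments[[ki]] <- labels
  }
  selected_k <- k_range[which.max(mean_ari)]
  structure(list(k_values = k_range, mean_ari = mean_ari,
                 pair_ari = pair_ari, fold_assignments = fold_assignments,
                 selected_k = selected_k, n_folds = n_folds,
                 n_init = n_init, seed = seed),
            class = "stability_curve")
}

#' @export
print.stability_curve <- function(x, ...) {
  cat("cluster-stability curve (mean pairwise ARI across CV folds)\n")
  print(stats::setNames(round(x$mean_ari, 4), paste0("K=", x$k_values)))
  cat(sprintf("selected K = %d\n", x$selected_k))
  invisible(x)
}

#' @export
plot.stability_curve <- function(x, ...) {
  graphics::plot(x$k_values, x$mean_ari, type = "b", pch = 19,
                 xlab = "number of subtypes K",
                 ylab = "mean pairwise ARI across folds",
                 main = "Cluster stability", ...)
  graphics::abline(v = x$selected_k, lty = 2, col = "grey40")
  invisible(x)
}
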
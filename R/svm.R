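#' Weighted squared-hinge linear max-margin classifier
#'
#' Minimizes the smooth convex objective
#' \deqn{\tfrac12 \lVert w \rVert^2 + C \sum_i s_i \max(0,\; 1 - y_i (w^\top x_i + b))^2}
#' over the hyperplane `(w, b)`, where `s_i` are per-sample weights. This is
#' the base learner of the polytope clusterer: each face is one such
#' classifier separating the reference group (label -1) from the targets
#' currently assigned to that face (label +1). The bias `b` is not penalized.
#' Warm starts via `init` make alternating optimization monotone.
#'
#' The default solver is a damped Newton method with conjugate-gradient inner
#' steps on the active (positive-margin) rows — the standard approach for
#' squared-hinge linear classification. `method = "lbfgs"` solves the same
#' objective with `stats::optim`; the two agree to optimization tolerance and
#' are cross-checked in the package tests.
#'
#' @param x numeric matrix, one row per sample.
#' @param y labels in \{-1, +1\}.
#' @param weights nonnegative per-sample weights.
#' @param C margin/loss trade-off (> 0).
#' @param init optional warm start, `c(w, b)`.
#' @param maxit maximum outer iterations.
#' @param gtol stop when the gradient max-norm falls below `gtol` (newton).
#' @param factr L-BFGS-B convergence tolerance factor (lbfgs).
#' @param method `"newton"` (default) or `"lbfgs"`.
#' @return list of class `linear_classifier`: `w`, `b`, `objective`,
#'   `converged`, `counts` (matvec-equivalent work).
#' @export
svm_squared_hinge <- function(x, y, weights = rep(1, nrow(x)), C = 1,
                              init = NULL, maxit = 100L, gtol = 1e-6,
                              factr = 1e7, method = c("newton", "lbfgs")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  if (length(y) != n) stopf("alignment_error", "y length does not match x rows")
  if (!all(y %in% c(-1, 1))) stopf("config_error", "labels must be -1 or +1")
  if (length(weights) != n || any(weights < 0)) {
    stopf("config_error", "weights must be nonnegative and match x rows")
  }
  if (C <= 0) stopf("config_error", "C must be positive")
  par0 <- if (is.null(init)) numeric(d + 1L) else as.numeric(init)
  if (length(par0) != d + 1L) stopf("dimension_error", "init must have length ncol(x)+1")
  cw <- C * weights

  out <- if (method == "newton") {
    newton_squared_hinge(x, y, cw, par0, maxit = maxit, gtol = gtol)
  } else {
    lbfgs_squared_hinge(x, y, cw, par0, maxit = max(maxit, 500L), factr = factr)
  }
  # a warm start must never come back worse
  if (!is.null(init)) {
    obj0 <- squared_hinge_objective(x, y, cw, par0)
    if (out$objective > obj0) {
      out$par <- par0
      out$objective <- obj0
    }
  }
  structure(list(w = out$par[seq_len(d)], b = out$par[d + 1L],
                 objective = out$objective, converged = out$converged,
                 counts = out$counts), class = "linear_classifier")
}

squared_hinge_objective <- function(x, y, cw, par) {
  d <- ncol(x)
  w <- par[seq_len(d)]
  m <- 1 - y * (drop(x %*% w) + par[d + 1L])
  m[m < 0] <- 0
  0.5 * sum(w * w) + sum(cw * m * m)
}

# damped Newton with CG inner solves; the Gauss-Newton Hessian is evaluated
# on the rows with positive margin only, which makes iterations cheap once
# the fit is nearly separable
newton_squared_hinge <- function(x, y, cw, par, maxit = 100L, gtol = 1e-6,
                                 cg_maxit = 30L) {
  n <- nrow(x)
  d <- ncol(x)
  w <- par[seq_len(d)]
  b <- par[d + 1L]
  f <- drop(x %*% w) + b
  nmat <- 1L
  obj <- function(w, b, f) {
    m <- 1 - y * f
    m[m < 0] <- 0
    0.5 * sum(w * w) + sum(cw * m * m)
  }
  cur <- obj(w, b, f)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    m <- 1 - y * f
    act <- which(m > 0)
    ma <- m[act]
    coefa <- -2 * cw[act] * y[act] * ma
    g <- c(w + drop(crossprod(x[act, , drop = FALSE], coefa)), sum(coefa))
    if (max(abs(g)) <= gtol) {
      converged <- TRUE
      break
    }
    xa <- x[act, , drop = FALSE]
    cwa <- 2 * cw[act]
    hv <- function(v) {
      fv <- drop(xa %*% v[seq_len(d)]) + v[d + 1L]
      c(v[seq_len(d)] + drop(crossprod(xa, cwa * fv)), sum(cwa * fv))
    }
    # conjugate gradient for H dir = -g
    dir <- numeric(d + 1L)
    r <- -g
    p <- r
    rs <- sum(r * r)
    rs0 <- rs
    for (cg in seq_len(cg_maxit)) {
      hp <- hv(p)
      alpha <- rs / sum(p * hp)
      dir <- dir + alpha * p
      r <- r - alpha * hp
      rs_new <- sum(r * r)
      if (rs_new <= 1e-8 * rs0) break
      p <- r + (rs_new / rs) * p
      rs <- rs_new
    }
    nmat <- nmat + 1L
    f_dir <- drop(x %*% dir[seq_len(d)]) + dir[d + 1L]
    gd <- sum(g * dir)
    # backtracking line search on the exact objective
    step <- 1
    ok <- FALSE
    for (ls in seq_len(40L)) {
      w_new <- w + step * dir[seq_len(d)]
      b_new <- b + step * dir[d + 1L]
      f_new <- f + step * f_dir
      val <- obj(w_new, b_new, f_new)
      if (val <= cur + 1e-4 * step * gd) {
        ok <- TRUE
        break
      }
      step <- step / 2
    }
    if (!ok || cur - val <= 1e-14 * (abs(cur) + 1e-12)) {
      converged <- max(abs(g)) <= 100 * gtol
      break
    }
    w <- w_new
    b <- b_new
    f <- f_new
    cur <- val
  }
  list(par = c(w, b), objective = cur, converged = converged,
       counts = c(newton = it, matvec = nmat))
}

lbfgs_squared_hinge <- function(x, y, cw, par0, maxit = 500L, factr = 1e7) {
  d <- ncol(x)
  cache <- new.env(parent = emptyenv())
  margins <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$m)
    w <- par[seq_len(d)]
    m <- 1 - y * (drop(x %*% w) + par[d + 1L])
    m[m < 0] <- 0
    cache$par <- par
    cache$m <- m
    m
  }
  fn <- function(par) {
    m <- margins(par)
    w <- par[seq_len(d)]
    0.5 * sum(w * w) + sum(cw * m * m)
  }
  gr <- function(par) {
    m <- margins(par)
    w <- par[seq_len(d)]
    coef <- -2 * cw * y * m
    c(w + drop(crossprod(x, coef)), sum(coef))
  }
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = factr))
  list(par = opt$par, objective = opt$value,
       converged = opt$convergence == 0L, counts = opt$counts)
}

#' Decision values of a linear classifier
#' @param fit a `linear_classifier`.
#' @param x numeric matrix of samples.
#' @return numeric vector `x w + b`.
#' @export
decision_values <- function(fit, x) {
  drop(as.matrix(x) %*% fit$w) + fit$b
}
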
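# Univariate-response partial least squares (PLS1) by NIPALS, with
# cross-validated RMSE model selection and VIP scores. The class membership
# is regressed as a 0/1-coded response with an ordinary least-squares inner
# relation, the standard chemometric treatment of binary classification
# through PLS regression.

#' Fit a PLS1 model (NIPALS)
#'
#' X and y are mean-centred internally; no scaling is applied. Components
#' stop early if the residual covariance vanishes (rank exhausted).
#'
#' @param X numeric matrix (rows = samples).
#' @param y numeric response vector (0/1 class coding for classification).
#' @param ncomp maximum number of latent components.
#' @return object of class `pls1_fit` with weights `W`, loadings `P`,
#'   y-loadings `q`, score sums of squares `tt`, per-component coefficient
#'   matrix `B` (column a = coefficients using components 1..a), centres,
#'   and `ncomp` actually extracted.
#' @export
pls1_fit <- function(X, y, ncomp = 10) {
  X <- as.matrix(X); y <- as.numeric(y)
  xmean <- colMeans(X); ymean <- mean(y)
  E <- sweep(X, 2, xmean); f <- y - ymean
  n <- ncol(E)
  ncomp <- min(ncomp, n, nrow(X) - 1L)
  W <- P <- matrix(0, n, ncomp)
  q <- tt <- numeric(ncomp)
  a <- 0L
  for (h in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- E %*% w
    tth <- sum(t_^2)
    if (tth < 1e-12) break
    p <- crossprod(E, t_) / tth
    qh <- sum(f * t_) / tth
    E <- E - t_ %*% t(p)
    f <- f - t_ * qh
    a <- h
    W[, h] <- w; P[, h] <- p; q[h] <- qh; tt[h] <- tth
  }
  if (a == 0L) stop_specsel("X carries no variance; PLS undefined", "specsel_param_error")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]; tt <- tt[seq_len(a)]
  # B_a = W (P'W)^-1 q over leading a components; P'W is upper triangular
  B <- matrix(0, n, a)
  PW <- crossprod(P, W)
  for (h in seq_len(a)) {
    bh <- W[, seq_len(h), drop = FALSE] %*%
      solve(PW[seq_len(h), seq_len(h), drop = FALSE], q[seq_len(h)])
    B[, h] <- bh
  }
  structure(list(W = W, P = P, q = q, tt = tt, B = B,
                 xmean = xmean, ymean = ymean, ncomp = a),
            class = "pls1_fit")
}

#' Predict from a PLS1 fit
#'
#' @param object a `pls1_fit`.
#' @param newdata matrix of predictors.
#' @param ncomp number of components to use (default: all extracted). May be
#'   a vector, in which case a matrix with one column per requested count is
#'   returned.
#' @param ... unused.
#' @return numeric vector (or matrix) of predicted responses.
#' @export
predict.pls1_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  Xc <- sweep(as.matrix(newdata), 2, object$xmean)
  out <- sapply(ncomp, function(a) object$ymean + Xc %*% object$B[, a])
  if (length(ncomp) == 1) as.numeric(out) else out
}

# Kernel PLS1 on the Gram matrix A = Xc'Xc and covariance c = Xc'yc:
# algebraically identical to NIPALS on X (A and c are deflated in step), but
# each component costs O(n^2) regardless of sample count, and column
# subsets reuse a precomputed A. Returns per-component coefficient matrix.
kernel_pls1_B <- function(A, c0, ncomp) {
  n <- length(c0)
  ncomp <- min(ncomp, n)
  B <- matrix(0, n, ncomp)
  R <- matrix(0, n, ncomp)  # rotations: T = Xc R
  P <- matrix(0, n, ncomp)
  b <- numeric(n)
  cc <- c0
  a <- 0L
  for (h in seq_len(ncomp)) {
    nw <- sqrt(sum(cc^2))
    if (nw < 1e-12) break
    w <- cc / nw
    Aw <- A %*% w
    tth <- sum(w * Aw)
    if (tth < 1e-12) break
    p <- as.numeric(Aw) / tth
    q <- sum(cc * w) / tth
    r <- w
    if (h > 1) {
      prev <- seq_len(h - 1)
      r <- w - R[, prev, drop = FALSE] %*% crossprod(P[, prev, drop = FALSE], w)
    }
    A <- A - tth * tcrossprod(p)
    cc <- cc - q * tth * p
    b <- b + as.numeric(r) * q
    a <- h
    R[, h] <- r; P[, h] <- p
    B[, h] <- b
  }
  if (a == 0L) return(NULL)
  B[, seq_len(a), drop = FALSE]
}

#' Build a reusable RMSECV evaluator over column subsets
#'
#' Precomputes, per CV fold, the centred Gram matrix, covariance vector and
#' centred test rows, then returns a closure that scores any column subset:
#' PLS1 is refitted on the subset via the kernel form and the RMSE curve
#' over 1..max_components returned with its minimum. Used heavily by the
#' interval-elimination loop, where thousands of subsets share one fold
#' assignment.
#'
#' @param X predictor matrix.
#' @param y01 0/1-coded response.
#' @param cv_shuffle integer fold id per row.
#' @param max_components component budget.
#' @return function(cols) -> list(best_rmse, best_ncomp, rmse).
#' @export
make_rmsecv_evaluator <- function(X, y01, cv_shuffle, max_components = 30) {
  X <- as.matrix(X); y01 <- as.numeric(y01)
  folds <- sort(unique(cv_shuffle))
  pre <- lapply(folds, function(f) {
    te <- which(cv_shuffle == f)
    Xtr <- X[-te, , drop = FALSE]
    xm <- colMeans(Xtr); ym <- mean(y01[-te])
    Xc <- sweep(Xtr, 2, xm)
    list(A = crossprod(Xc), c = as.numeric(crossprod(Xc, y01[-te] - ym)),
         Xte = sweep(X[te, , drop = FALSE], 2, xm), yte = y01[te],
         ym = ym, te = te)
  })
  n_all <- length(y01)
  function(cols) {
    press <- matrix(NA_real_, n_all, max_components)
    amax <- 0L
    for (p in pre) {
      B <- kernel_pls1_B(p$A[cols, cols, drop = FALSE], p$c[cols], max_components)
      if (is.null(B)) { press[p$te, ] <- (p$ym - p$yte)^2; amax <- max(amax, 1L); next }
      a <- ncol(B)
      amax <- max(amax, a)
      pred <- p$ym + p$Xte[, cols, drop = FALSE] %*% B
      press[p$te, seq_len(a)] <- (pred - p$yte)^2
      if (a < max_components) press[p$te, (a + 1):max_components] <- press[p$te, a]
    }
    rmse <- sqrt(colMeans(press[, seq_len(max(amax, 1L)), drop = FALSE]))
    best <- which.min(rmse)
    list(best_rmse = rmse[best], best_ncomp = best, rmse = rmse)
  }
}

#' Cross-validated RMSE of a PLS1 regression
#'
#' RMSECV is computed for each component count 1..`max_components` under a
#' fixed fold assignment (the "CV shuffle"); the minimum and its component
#' count are returned.
#'
#' @param X predictor matrix.
#' @param y01 response vector (0/1 class coding).
#' @param max_components maximum latent components to scan (default 30).
#' @param cv_shuffle integer fold id per row (from [make_cv_shuffle()]), or
#'   NULL for a default 5-fold assignment with seed 1.
#' @return list with `best_rmse`, `best_ncomp`, and the full `rmse` curve.
#' @export
rmsecv <- function(X, y01, max_components = 30, cv_shuffle = NULL) {
  X <- as.matrix(X); y01 <- as.numeric(y01)
  if (all(apply(X, 2, stats::sd) < 1e-12))
    stop_specsel("X has zero variance everywhere", "specsel_param_error")
  ids <- cv_shuffle %||% make_cv_shuffle(length(y01), folds = 5, seed = 1)
  ev <- make_rmsecv_evaluator(X, y01, ids, max_components)
  ev(seq_len(ncol(X)))
}

#' Fixed CV fold assignment ("shuffle")
#'
#' @param n number of rows.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids, length n.
#' @export
make_cv_shuffle <- function(n, folds = 5, seed = 1) {
  with_seed(seed, sample(rep_len(seq_len(folds), n)))
}

#' Variable importance in projection (VIP)
#'
#' Standard VIP: `VIP_j = sqrt(p * sum_a(SSY_a * w_ja^2) / sum_a SSY_a)`
#' where `SSY_a = q_a^2 * tt_a` is the y-variance explained by component a
#' and the weight vectors are unit length, so `mean(VIP^2) = 1`.
#'
#' @param fit a `pls1_fit`.
#' @return numeric vector of VIP scores, one per predictor.
#' @export
pls_vip <- function(fit) {
  ssy <- fit$q^2 * fit$tt
  p <- nrow(fit$W)
  w2 <- sweep(fit$W^2, 2, colSums(fit$W^2), "/")  # guard non-unit weights
  as.numeric(sqrt(p * (w2 %*% ssy) / sum(ssy)))
}
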
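#' Univariate partial least squares (PLS1) by NIPALS
#'
#' Core latent-variable engine used by the PLSR calibration model and by
#' CARS band ranking. Predictors and response are mean-centered; for a
#' single response the NIPALS weight of each component is the (normalised)
#' covariance direction `X'y`, followed by score computation and rank-one
#' deflation of `X`. With as many components as the rank of the centered
#' predictor matrix, predictions coincide with ordinary least squares.
#'
#' @param X Numeric n x p matrix.
#' @param y Numeric response of length n.
#' @param ncomp Number of latent components (capped at `min(n - 1, p)`).
#' @return A list of class `pls1_fit`: regression `coef` (length p),
#'   `intercept`, `ncomp` actually extracted, and the centering means.
#' @keywords internal
#' @export
pls1_fit <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X rows and y length differ", call. = FALSE)
  if (n < 2L) stop("at least two samples required", call. = FALSE)
  ncomp <- as.integer(min(ncomp, n - 1L, p))
  if (ncomp < 1L) stop("ncomp must be >= 1", call. = FALSE)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  a <- 0L
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break            # no covariance left to model
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pl <- drop(crossprod(Xc, t)) / tt
    qh <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pl)
    yc <- yc - qh * t
    a <- h
    W[, h] <- w; P[, h] <- pl; q[h] <- qh
  }
  if (a == 0L) {
    coef <- numeric(p)
  } else {
    W <- W[, seq_len(a), drop = FALSE]
    P <- P[, seq_len(a), drop = FALSE]
    q <- q[seq_len(a)]
    # B = W (P'W)^-1 q
    coef <- drop(W %*% solve(crossprod(P, W), q))
  }
  structure(list(coef = coef, intercept = ym - sum(xm * coef),
                 ncomp = a, x_means = xm, y_mean = ym),
            class = "pls1_fit")
}

#' @export
predict.pls1_fit <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coef) + object$intercept
}

#' Cross-validated RMSE of a PLS1 model
#'
#' k-fold cross-validation RMSE (RMSECV) for a given component count, used
#' both for automatic component selection and for scoring CARS runs.
#'
#' @param X,y Calibration data.
#' @param ncomp Component count to evaluate.
#' @param folds Number of CV folds.
#' @param seed Seed controlling the fold assignment.
#' @return RMSECV (scalar).
#' @keywords internal
#' @export
pls1_cv_rmse <- function(X, y, ncomp, folds = 10L, seed = 1L) {
  X <- as.matrix(X); n <- nrow(X)
  folds <- as.integer(min(folds, n))
  if (folds < 2L) stop("at least 2 CV folds required", call. = FALSE)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  press <- 0
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    fit <- pls1_fit(X[!hold, , drop = FALSE], y[!hold],
                    ncomp = min(ncomp, sum(!hold) - 1L, ncol(X)))
    press <- press + sum((y[hold] - predict(fit, X[hold, , drop = FALSE]))^2)
  }
  sqrt(press / n)
}

# Pick the PLS component count minimising k-fold RMSECV over 1..max_comp.
select_ncomp_cv <- function(X, y, max_comp, folds = 10L, seed = 1L) {
  max_comp <- min(max_comp, nrow(X) - 2L, ncol(X))
  rmse <- vapply(seq_len(max_comp), function(a) {
    pls1_cv_rmse(X, y, a, folds = folds, seed = seed)
  }, numeric(1))
  list(ncomp = which.min(rmse), rmsecv = rmse)
}
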
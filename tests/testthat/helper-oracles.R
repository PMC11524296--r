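# Shared fixtures and independent oracles used across the test files.

# Small, fast synthetic configuration: 64-band grid, 6 seedlings per group.
small_config <- function(seed = 1L, scene_dim = c(8L, 8L), ...) {
  synthetic_config(n_per_group = 6L, seed = seed, grid = default_grid(64L),
                   scene_dim = scene_dim, ...)
}

# Planted-signal design: the informative columns carry dominant variance so
# a variance-driven selector (SPA chains depend on X geometry alone) can
# find them; y is then a noiseless linear function of exactly those bands.
planted_design <- function(n, p, planted, coefs, seed, scale = 5) {
  X <- random_bands(n, p, seed = seed)
  X[, planted] <- X[, planted] * scale
  list(X = X, y = drop(X[, planted] %*% coefs))
}

# Brute-force successive-projections oracle: at each step build the explicit
# orthogonal-complement projector of the selected columns and pick the
# unselected column of largest residual norm.
spa_oracle_chain <- function(X, start, k) {
  X <- as.matrix(X)
  sel <- as.integer(start)
  for (step in seq_len(k - 1L)) {
    S <- X[, sel, drop = FALSE]
    P <- diag(nrow(X)) - S %*% solve(crossprod(S), t(S))
    resid <- P %*% X
    norms <- colSums(resid^2)
    norms[sel] <- -Inf
    sel <- c(sel, which.max(norms))
  }
  sel
}

# Streaming (single-pass) computation of R^2 and RMSE, independent of the
# vectorised package implementation.
streaming_metrics <- function(y, yhat) {
  n <- 0L; s_err <- 0; s_y <- 0; s_y2 <- 0
  for (i in seq_along(y)) {
    n <- n + 1L
    s_err <- s_err + (y[i] - yhat[i])^2
    s_y <- s_y + y[i]
    s_y2 <- s_y2 + y[i]^2
  }
  ss_tot <- s_y2 - s_y^2 / n
  list(r2 = 1 - s_err / ss_tot, rmse = sqrt(s_err / n))
}

# Random spectra-like matrix with named bands.
random_bands <- function(n, p, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("b%d", seq_len(p))
  X
}
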
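#' Successive projections: build one variable chain
#'
#' The successive projections algorithm (SPA) grows a chain of band indices
#' with minimal collinearity: starting from one column of the calibration
#' matrix, each step projects every unselected column onto the orthogonal
#' complement of the span of the selected ones and appends the column with
#' the largest residual norm. Implemented by repeated rank-one deflation,
#' which is algebraically a pivoted Gram-Schmidt ordering.
#'
#' @param X Calibration matrix (samples x bands).
#' @param start_band Index of the first band of the chain.
#' @param k Desired chain length.
#' @param tol Relative residual-norm tolerance below which a column is
#'   treated as linearly dependent on the chain.
#' @return Integer vector of band indices in selection order; shorter than
#'   `k` (with a warning) if the matrix runs out of rank first.
#' @export
spa_project_chain <- function(X, start_band, k, tol = 1e-10) {
  X <- as.matrix(X)
  p <- ncol(X)
  k <- as.integer(k)
  if (k < 1L || k > min(nrow(X), p)) {
    stop("chain length k must be in [1, min(n_samples, n_bands)]",
         call. = FALSE)
  }
  if (start_band < 1L || start_band > p) stop("start_band out of range",
                                              call. = FALSE)
  ref_norm2 <- max(colSums(X^2))
  Xr <- X
  sel <- integer(0)
  cur <- as.integer(start_band)
  for (step in seq_len(k)) {
    u <- Xr[, cur]
    nu2 <- sum(u^2)
    if (nu2 <= tol * ref_norm2) {
      warning("SPA chain truncated: remaining columns are linearly ",
              "dependent on the selection", call. = FALSE)
      break
    }
    sel <- c(sel, cur)
    if (step == k) break
    Xr <- Xr - u %*% (crossprod(u, Xr) / nu2)   # deflate span of u
    norms2 <- colSums(Xr^2)
    norms2[sel] <- -Inf
    cur <- which.max(norms2)
    if (norms2[cur] <= tol * ref_norm2) {
      warning("SPA chain truncated: remaining columns are linearly ",
              "dependent on the selection", call. = FALSE)
      break
    }
  }
  sel
}

#' SPA characteristic-wavelength selection
#'
#' For every candidate subset size `k` in `[k_min, k_max]` and every
#' candidate starting band, [spa_project_chain()] proposes a band chain; a
#' multiple linear regression on those bands is fitted to the training
#' portion and scored by RMSE on a seeded holdout portion (or on the
#' training data itself when `validation = "none"`, which makes the search
#' fully deterministic). The subset with the lowest validation RMSE wins;
#' ties go to the smaller subset, then the lower starting band index.
#'
#' @param X Calibration spectra matrix (samples x bands).
#' @param y Trait values (length = rows of X).
#' @param k_min,k_max Subset-size search range (defaults 1 and 30).
#' @param starts Candidate starting bands (default: all bands).
#' @param validation `"holdout"` (default) or `"none"`.
#' @param holdout_frac Fraction of rows held out for validation.
#' @param seed Seed for the holdout split.
#' @return A `selection_result`: `method`, `selected_indices` (in chain
#'   order), `selected_wavelengths_nm` (when `grid` is given),
#'   `rmse_trajectory` (best RMSE at each subset size), `chosen_point`
#'   (index into the trajectory), `k`, `start_band`.
#' @param grid Optional [wavelength_grid()] used to report wavelengths.
#' @export
spa_select <- function(X, y, k_min = 1L, k_max = 30L, starts = NULL,
                       validation = c("holdout", "none"),
                       holdout_frac = 0.2, seed = 1L, grid = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X rows and y length differ", call. = FALSE)
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min < 1L || k_min > k_max) stop("need 1 <= k_min <= k_max",
                                        call. = FALSE)
  if (k_max > p) stop("k_max exceeds the number of bands", call. = FALSE)
  validation <- match.arg(validation)
  if (is.null(starts)) starts <- seq_len(p)
  set.seed(seed)
  if (validation == "holdout") {
    n_val <- max(1L, round(holdout_frac * n))
    val_rows <- sort(sample.int(n, n_val))
    train_rows <- setdiff(seq_len(n), val_rows)
  } else {
    train_rows <- seq_len(n)
    val_rows <- seq_len(n)
  }
  if (k_max >= length(train_rows)) {
    stop("k_max must be smaller than the number of training samples ",
         "(multiple linear regression would be underdetermined)",
         call. = FALSE)
  }
  Xtr <- X[train_rows, , drop = FALSE]; ytr <- y[train_rows]
  Xva <- X[val_rows, , drop = FALSE]; yva <- y[val_rows]
  # center columns on training data so chains ignore the common offset
  Xc <- sweep(Xtr, 2, colMeans(Xtr))

  n_k <- k_max - k_min + 1L
  best_rmse_k <- rep(Inf, n_k)
  best_chain_k <- vector("list", n_k)
  best_start_k <- rep(NA_integer_, n_k)
  for (s in starts) {
    chain <- suppressWarnings(spa_project_chain(Xc, s, k_max))
    if (length(chain) < k_min) next
    for (ki in seq_len(n_k)) {
      k <- k_min + ki - 1L
      if (length(chain) < k) break
      bands <- chain[seq_len(k)]
      fit <- stats::lm.fit(cbind(1, Xtr[, bands, drop = FALSE]), ytr)
      pred <- drop(cbind(1, Xva[, bands, drop = FALSE]) %*% fit$coefficients)
      r <- sqrt(mean((yva - pred)^2))
      if (r < best_rmse_k[ki] - 1e-15 ||
          (abs(r - best_rmse_k[ki]) <= 1e-15 &&
           s < (best_start_k[ki] %||% Inf))) {
        best_rmse_k[ki] <- r
        best_chain_k[[ki]] <- bands
        best_start_k[ki] <- s
      }
    }
  }
  if (all(!is.finite(best_rmse_k))) {
    stop("SPA found no evaluable subset (rank deficiency)", call. = FALSE)
  }
  # global winner: lowest RMSE; ties -> smallest k (earliest index wins)
  chosen <- which.min(best_rmse_k)
  sel <- best_chain_k[[chosen]]
  structure(list(
    method = "spa",
    selected_indices = sel,
    selected_wavelengths_nm = if (is.null(grid)) NULL
                              else unclass(grid)[sel],
    rmse_trajectory = best_rmse_k,
    trajectory_sizes = seq(k_min, k_max),
    chosen_point = chosen,
    k = length(sel),
    start_band = best_start_k[chosen],
    validation = validation
  ), class = "selection_result")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d bands selected\n",
              toupper(x$method), length(x$selected_indices)))
  cat("  indices:", paste(utils::head(sort(x$selected_indices), 12),
                          collapse = " "),
      if (length(x$selected_indices) > 12) "..." else "", "\n")
  invisible(x)
}
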
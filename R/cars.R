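#' Exponentially decreasing retention schedule of CARS
#'
#' The fraction of the `p` original bands retained at sampling run `i` of
#' `N` follows `r_i = a * exp(-k * i)` with the boundary conditions that
#' all `p` bands survive run 1 and exactly 2 survive run `N`, giving
#' `a = (p/2)^(1/(N-1))` and `k = log(p/2)/(N-1)`.
#'
#' @param i Run index (1..N), vectorised.
#' @param p Number of bands on the full grid (>= 2).
#' @param n_runs Total number of Monte-Carlo sampling runs N.
#' @return Retention ratio(s) in (0, 1].
#' @export
cars_edf_ratio <- function(i, p, n_runs) {
  if (p < 2L) stop("EDF needs at least 2 bands", call. = FALSE)
  if (n_runs < 2L) stop("EDF needs at least 2 runs", call. = FALSE)
  if (any(i < 1L | i > n_runs)) stop("run index out of [1, N]", call. = FALSE)
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  a * exp(-k * i)
}

#' @rdname cars_edf_ratio
#' @details `cars_edf_count` converts the ratio to a band count,
#'   `ceiling(r_i * p)` clamped to \[2, p\]; a tiny backoff inside the
#'   ceiling keeps floating-point noise at the exact boundary runs
#'   (`r_1 p = p`, `r_N p = 2`) from inflating the count by one.
#' @export
cars_edf_count <- function(i, p, n_runs) {
  r <- cars_edf_ratio(i, p, n_runs)
  pmin(as.integer(p), pmax(2L, as.integer(ceiling(r * p - 1e-9))))
}

#' CARS characteristic-wavelength selection
#'
#' Competitive adaptive reweighted sampling: over `n_runs` Monte-Carlo
#' sampling runs, (1) a random `mc_fraction` of the calibration samples is
#' drawn and a PLS model fitted on the currently retained bands; (2) the
#' exponentially decreasing function ([cars_edf_ratio()]) enforces how many
#' bands survive the run; (3) adaptive reweighted sampling performs the
#' competition, drawing that many bands without replacement with
#' probability proportional to the absolute PLS regression coefficients
#' ('survival of the fittest'); (4) the surviving band set is scored by
#' k-fold cross-validated RMSE on the full calibration set. The run with
#' the lowest RMSECV provides the selected wavelengths.
#'
#' The PLS component count is chosen once per call by k-fold RMSECV on the
#' full calibration data (capped at `max_pls_components`) and reused in
#' every run.
#'
#' @param X Calibration spectra matrix (samples x bands).
#' @param y Trait values.
#' @param n_runs Number of Monte-Carlo runs N (default 50).
#' @param cv_folds Folds of the scoring cross-validation (default 10).
#' @param mc_fraction Fraction of calibration samples drawn per run
#'   (default 0.8).
#' @param max_pls_components Upper bound on PLS components (default 10).
#' @param seed Integer seed; fixed seed gives identical selections.
#' @param grid Optional [wavelength_grid()] used to report wavelengths.
#' @return A `selection_result` with `selected_indices` (sorted),
#'   `rmse_trajectory` (RMSECV per run), `chosen_point` (winning run),
#'   `retained_counts` (bands surviving each run) and `ncomp`.
#' @export
cars_select <- function(X, y, n_runs = 50L, cv_folds = 10L,
                        mc_fraction = 0.8, max_pls_components = 10L,
                        seed = 1L, grid = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X rows and y length differ", call. = FALSE)
  if (n_runs < 2L) stop("n_runs must be >= 2", call. = FALSE)
  if (cv_folds < 2L || cv_folds > n) stop("cv_folds must be in [2, n]",
                                          call. = FALSE)
  if (mc_fraction <= 0 || mc_fraction >= 1) {
    stop("mc_fraction must be in (0, 1)", call. = FALSE)
  }
  if (p < 2L) stop("at least 2 bands required", call. = FALSE)

  set.seed(seed)
  ncomp <- select_ncomp_cv(X, y, max_pls_components,
                           folds = cv_folds, seed = seed)$ncomp
  n_mc <- max(2L, round(mc_fraction * n))
  retained <- seq_len(p)
  retained_counts <- integer(n_runs)
  rmsecv <- rep(NA_real_, n_runs)
  run_sets <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    rows <- sample.int(n, n_mc)
    fit <- tryCatch(
      pls1_fit(X[rows, retained, drop = FALSE], y[rows],
               ncomp = min(ncomp, length(retained), n_mc - 1L)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("CARS run %d skipped: PLS fit failed", i),
              call. = FALSE)
      retained_counts[i] <- length(retained)
      run_sets[[i]] <- retained
      next
    }
    w <- abs(fit$coef)
    keep_n <- min(length(retained), cars_edf_count(i, p, n_runs))
    # ARS: weighted competition without replacement at the EDF-enforced size
    retained <- sort(sample(retained, keep_n, prob = w + 1e-12))
    retained_counts[i] <- length(retained)
    run_sets[[i]] <- retained
    rmsecv[i] <- tryCatch(
      pls1_cv_rmse(X[, retained, drop = FALSE], y,
                   ncomp = min(ncomp, length(retained)),
                   folds = cv_folds, seed = seed + i),
      error = function(e) {
        warning(sprintf("CARS run %d not scored: %s", i, conditionMessage(e)),
                call. = FALSE)
        NA_real_
      })
  }
  if (all(is.na(rmsecv))) stop("no CARS run could be scored", call. = FALSE)
  chosen <- which.min(rmsecv)   # ties: earliest run = fewest bands later? no:
  # retained counts are non-increasing, so the earliest minimal run has the
  # most bands; prefer the smallest subset among exact ties instead
  ties <- which(!is.na(rmsecv) & rmsecv == min(rmsecv, na.rm = TRUE))
  if (length(ties) > 1L) chosen <- ties[which.min(retained_counts[ties])]
  sel <- run_sets[[chosen]]
  structure(list(
    method = "cars",
    selected_indices = sel,
    selected_wavelengths_nm = if (is.null(grid)) NULL else unclass(grid)[sel],
    rmse_trajectory = rmsecv,
    chosen_point = chosen,
    retained_counts = retained_counts,
    ncomp = ncomp,
    n_runs = n_runs
  ), class = "selection_result")
}
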
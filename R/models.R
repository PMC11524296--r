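#' Calibration models: PLSR, epsilon-SVR and single-hidden-layer ANN
#'
#' The three model families share one fit/predict contract: they are fitted
#' on a calibration matrix whose columns are named bands, remember those
#' band names, and refuse to predict on inputs whose band set differs
#' (columns may be permuted -- alignment is by band identity). Every
#' data-dependent statistic used at predict time (input/target scaling,
#' hyperparameters) is learned from the calibration data only.
#'
#' @param X Calibration matrix (samples x bands). Column names identify
#'   bands; unnamed columns are named positionally.
#' @param y Trait values (length = rows of X).
#' @param components `"auto"` (choose by `cv_folds`-fold RMSECV) or an
#'   integer component count.
#' @param max_components Cap for automatic component selection.
#' @param cv_folds Folds for internal cross-validation.
#' @param seed Seed for internal CV fold assignment.
#' @return An object of class `firspec_model` supporting [predict()].
#' @name calibration_models
NULL

model_bands <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("b%d", seq_len(ncol(X)))
  X
}

new_firspec_model <- function(family, fit, bands, extra = list()) {
  structure(c(list(family = family, fit = fit, bands = bands), extra),
            class = "firspec_model")
}

#' @rdname calibration_models
#' @export
fit_plsr <- function(X, y, components = "auto", max_components = 20L,
                     cv_folds = 10L, seed = 1L) {
  X <- model_bands(X)
  if (identical(components, "auto")) {
    sel <- select_ncomp_cv(X, y, max_components, folds = cv_folds,
                           seed = seed)
    ncomp <- sel$ncomp
    cv <- sel$rmsecv
  } else {
    ncomp <- as.integer(components)
    if (ncomp > min(nrow(X) - 1L, ncol(X))) {
      stop("requested components exceed the rank of the data", call. = FALSE)
    }
    cv <- NULL
  }
  fit <- pls1_fit(X, y, ncomp)
  new_firspec_model("plsr", fit, colnames(X),
                    extra = list(ncomp = fit$ncomp, rmsecv = cv, seed = seed))
}

#' @rdname calibration_models
#' @param kernel SVR kernel: `"radial"` (default) or `"linear"`.
#' @param cost,gamma,epsilon Hyperparameter grids searched by
#'   `cv_folds`-fold cross-validation (defaults: log-spaced C 0.1..1000,
#'   gamma 0.001..1, epsilon 0.01/0.1).
#' @export
fit_svr <- function(X, y, kernel = c("radial", "linear"),
                    cost = 10^(-1:3), gamma = 10^(-3:0),
                    epsilon = c(0.01, 0.1), cv_folds = 5L, seed = 1L) {
  kernel <- match.arg(kernel)
  X <- model_bands(X)
  n <- nrow(X)
  if (length(cost) == 0L || length(epsilon) == 0L ||
      (kernel == "radial" && length(gamma) == 0L)) {
    stop("empty hyperparameter grid", call. = FALSE)
  }
  if (kernel == "linear") gamma <- NA_real_
  grid <- expand.grid(cost = cost, gamma = gamma, epsilon = epsilon)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(min(cv_folds, n)), length.out = n))
  cv_rmse <- vapply(seq_len(nrow(grid)), function(g) {
    press <- 0
    for (f in unique(fold_id)) {
      hold <- fold_id == f
      m <- do.call(e1071::svm, c(
        list(x = X[!hold, , drop = FALSE], y = y[!hold], type = "eps-regression",
             kernel = kernel, cost = grid$cost[g], epsilon = grid$epsilon[g]),
        if (kernel == "radial") list(gamma = grid$gamma[g])))
      press <- press + sum((y[hold] -
                              predict(m, X[hold, , drop = FALSE]))^2)
    }
    sqrt(press / n)
  }, numeric(1))
  best <- grid[which.min(cv_rmse), ]
  fit <- do.call(e1071::svm, c(
    list(x = X, y = y, type = "eps-regression", kernel = kernel,
         cost = best$cost, epsilon = best$epsilon),
    if (kernel == "radial") list(gamma = best$gamma)))
  new_firspec_model("svr", fit, colnames(X),
                    extra = list(best = best, cv_rmse = min(cv_rmse),
                                 kernel = kernel, seed = seed))
}

#' @rdname calibration_models
#' @param hidden_units Hidden-layer size (default 10).
#' @param activation `"logistic"` (sigmoid hidden layer, the default) or
#'   `"identity"` (no hidden layer: the model class collapses to linear
#'   regression, trained by the same optimiser).
#' @param decay Weight-decay regularisation strength.
#' @param maxit Maximum training iterations (BFGS).
#' @export
fit_ann <- function(X, y, hidden_units = 10L,
                    activation = c("logistic", "identity"),
                    decay = 1e-4, maxit = 2000L, seed = 1L) {
  activation <- match.arg(activation)
  if (hidden_units < 1L) stop("hidden_units must be >= 1", call. = FALSE)
  X <- model_bands(X)
  # standardize inputs and target with calibration statistics only
  xc <- colMeans(X)
  xs <- apply(X, 2, stats::sd); xs[xs == 0] <- 1
  yc <- mean(y); ys <- stats::sd(y); if (is.na(ys) || ys == 0) ys <- 1
  Xs <- sweep(sweep(X, 2, xc), 2, xs, "/")
  ysc <- (y - yc) / ys
  set.seed(seed)
  fit <- if (activation == "identity") {
    nnet::nnet(Xs, ysc, size = 0, skip = TRUE, linout = TRUE,
               decay = decay, maxit = maxit, trace = FALSE)
  } else {
    nnet::nnet(Xs, ysc, size = hidden_units, linout = TRUE,
               decay = decay, maxit = maxit, trace = FALSE)
  }
  if (!all(is.finite(fit$wts))) {
    stop("ANN training diverged: non-finite weights", call. = FALSE)
  }
  new_firspec_model("ann", fit, colnames(X),
                    extra = list(x_center = xc, x_scale = xs,
                                 y_center = yc, y_scale = ys,
                                 activation = activation,
                                 hidden_units = hidden_units, seed = seed))
}

align_bands <- function(object, newdata) {
  X <- as.matrix(newdata)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(object$bands)) {
      stop("unnamed prediction input has ", ncol(X),
           " columns but the model was trained on ",
           length(object$bands), " bands", call. = FALSE)
    }
    colnames(X) <- object$bands
  }
  missing <- setdiff(object$bands, colnames(X))
  extra <- setdiff(colnames(X), object$bands)
  if (length(missing) || length(extra)) {
    stop("band mismatch between model and prediction input",
         if (length(missing)) paste0("; missing: ",
                                     paste(utils::head(missing, 5),
                                           collapse = ", ")),
         if (length(extra)) paste0("; unknown: ",
                                   paste(utils::head(extra, 5),
                                         collapse = ", ")),
         call. = FALSE)
  }
  X[, object$bands, drop = FALSE]
}

#' Predict from a fitted calibration model
#'
#' @param object A `firspec_model`.
#' @param newdata Matrix whose named columns carry the model's training
#'   bands (any order; extra or missing bands raise an error).
#' @param ... Unused.
#' @return Numeric predictions, one per row.
#' @export
predict.firspec_model <- function(object, newdata, ...) {
  X <- align_bands(object, newdata)
  switch(object$family,
    plsr = predict(object$fit, X),
    svr = as.numeric(predict(object$fit, X)),
    ann = {
      Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
      as.numeric(predict(object$fit, Xs)) * object$y_scale + object$y_center
    },
    stop("unknown model family", call. = FALSE))
}

#' @export
print.firspec_model <- function(x, ...) {
  cat(sprintf("<firspec_model> %s on %d bands\n", toupper(x$family),
              length(x$bands)))
  invisible(x)
}
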
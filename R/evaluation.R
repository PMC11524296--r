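#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, the fraction of
#' trait variance explained on the evaluated set.
#'
#' @param y_true Measured values (length >= 2, not constant).
#' @param y_pred Predicted values of equal length.
#' @return Scalar R-squared (<= 1; negative when worse than the mean).
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (length(y_true) < 2L) stop("need at least two observations", call. = FALSE)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    stop("R-squared undefined: measured values are constant", call. = FALSE)
  }
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Root mean square error
#'
#' `RMSE = sqrt(sum((y - yhat)^2) / n)`.
#'
#' @param y_true,y_pred Equal-length numeric vectors (non-empty).
#' @return Scalar RMSE in the units of the trait.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  sqrt(mean((y_true - y_pred)^2))
}

#' Stratified calibration/prediction split
#'
#' Splits the samples into a calibration (training) and a prediction
#' (test) set, stratified by drought group so every group is represented
#' in both sets in near-equal proportion. Group counts are allocated by
#' largest remainder so the global fraction is hit exactly: the default
#' 0.7 on 180 samples (five groups of 36) yields 126 calibration and 54
#' prediction samples.
#'
#' @param set A [spectra_set()] whose metadata carries a `group` column.
#' @param calibration_fraction Fraction assigned to calibration.
#' @param seed Seed controlling the within-group draw.
#' @return A list of class `split_plan`: `calibration_ids`,
#'   `prediction_ids`, `fraction`, `seed`.
#' @export
split_calibration_prediction <- function(set, calibration_fraction = 0.7,
                                         seed = 42L) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.null(set$meta) || !"group" %in% names(set$meta)) {
    stop("spectra set has no group labels to stratify on", call. = FALSE)
  }
  if (calibration_fraction <= 0 || calibration_fraction > 1) {
    stop("calibration_fraction must be in (0, 1]", call. = FALSE)
  }
  groups <- split(set$ids, set$meta$group)
  if (any(lengths(groups) < 2L)) {
    stop("every group needs at least 2 samples to stratify", call. = FALSE)
  }
  n <- length(set$ids)
  target_total <- round(calibration_fraction * n)
  exact <- lengths(groups) * calibration_fraction
  base <- floor(exact)
  short <- target_total - sum(base)
  # largest-remainder allocation; ties broken by group order
  order_rem <- order(exact - base, decreasing = TRUE)
  take <- base
  if (short > 0) take[order_rem[seq_len(short)]] <- base[order_rem[seq_len(short)]] + 1
  set.seed(seed)
  calib <- unlist(lapply(seq_along(groups), function(g) {
    ids <- groups[[g]]
    sample(ids, min(take[g], length(ids)))
  }), use.names = FALSE)
  structure(list(calibration_ids = sort(calib),
                 prediction_ids = sort(setdiff(set$ids, calib)),
                 fraction = calibration_fraction, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d calibration / %d prediction (fraction %.2f)\n",
              length(x$calibration_ids), length(x$prediction_ids),
              x$fraction))
  invisible(x)
}

run_selector <- function(method, X, y, grid, spa_args, cars_args, seed) {
  switch(method,
    full = structure(list(method = "full",
                          selected_indices = seq_len(ncol(X)),
                          selected_wavelengths_nm = unclass(grid),
                          rmse_trajectory = NULL, chosen_point = NULL),
                     class = "selection_result"),
    spa = do.call(spa_select, c(list(X = X, y = y, grid = grid, seed = seed),
                                spa_args)),
    cars = do.call(cars_select, c(list(X = X, y = y, grid = grid, seed = seed),
                                  cars_args)),
    stop("unknown selector: ", method, call. = FALSE))
}

run_model <- function(family, X, y, seed) {
  switch(family,
    plsr = fit_plsr(X, y, seed = seed),
    svr = fit_svr(X, y, seed = seed),
    ann = fit_ann(X, y, seed = seed),
    stop("unknown model family: ", family, call. = FALSE))
}

#' Run the preprocessing x selection x model evaluation grid
#'
#' Orchestrates the full comparison: the samples are split once into
#' calibration and prediction sets (stratified by drought group); for each
#' requested combination of preprocessing, wavelength selector, model
#' family and trait, all fitting -- preprocessing statistics, selected
#' bands, hyperparameters -- is confined to the calibration split, and the
#' frozen pipeline is then applied to the prediction split. One report row
#' per combination records R-squared and RMSE on both sets; failed cells
#' are reported with their reason and do not abort the run.
#'
#' @param set A [spectra_set()] with `group` labels and trait metadata.
#' @param targets Traits to model: subset of `"lcc"`, `"lwc"`.
#' @param preprocess_methods Subset of `"none"`, `"sg"`, `"snv"`, `"msc"`.
#' @param selectors Subset of `"full"`, `"spa"`, `"cars"`.
#' @param models Subset of `"plsr"`, `"svr"`, `"ann"`.
#' @param calibration_fraction,split_seed Split parameters (default 0.7,
#'   reproducing a 126/54 split on 180 samples).
#' @param sg_window,sg_polyorder,sg_deriv Savitzky-Golay settings.
#' @param spa_args,cars_args Named argument lists passed to [spa_select()]
#'   and [cars_select()].
#' @param seed Seed for selection and model internals.
#' @return A list of class `evaluation_report`: `report` (data.frame with
#'   columns index, preprocessing, selector, n_bands, model, r2_c, rmse_c,
#'   r2_p, rmse_p, status, note), `split` (the [split_calibration_prediction()]
#'   plan), and `selections` (the selection results, keyed by
#'   target/preprocessing/selector).
#' @export
run_pipeline <- function(set,
                         targets = c("lcc", "lwc"),
                         preprocess_methods = "sg",
                         selectors = c("full", "spa", "cars"),
                         models = "plsr",
                         calibration_fraction = 0.7,
                         split_seed = 42L,
                         sg_window = 11L, sg_polyorder = 2L, sg_deriv = 0L,
                         spa_args = list(), cars_args = list(),
                         seed = 1L) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.null(set$meta) || !all(targets %in% names(set$meta))) {
    stop("spectra set metadata lacks the requested trait columns",
         call. = FALSE)
  }
  plan <- split_calibration_prediction(set, calibration_fraction, split_seed)
  if (length(plan$prediction_ids) == 0L) {
    stop("empty prediction set: cannot evaluate", call. = FALSE)
  }
  cal <- subset_spectra(set, samples = plan$calibration_ids)
  prd <- subset_spectra(set, samples = plan$prediction_ids)

  rows <- list(); selections <- list()
  for (prep in preprocess_methods) {
    cal_p <- apply_preprocess(cal, prep, sg_window, sg_polyorder, sg_deriv)
    prd_p <- apply_preprocess(prd, prep, sg_window, sg_polyorder, sg_deriv,
                              state = cal_p)
    for (target in targets) {
      y_c <- cal_p$meta[[target]]
      y_p <- prd_p$meta[[target]]
      for (selm in selectors) {
        sel_key <- paste(target, prep, selm, sep = ".")
        sel <- tryCatch(
          run_selector(selm, cal_p$matrix, y_c, cal_p$grid,
                       spa_args, cars_args, seed),
          error = function(e) e)
        if (inherits(sel, "error")) {
          for (fam in models) {
            rows[[length(rows) + 1L]] <- data.frame(
              index = toupper(target), preprocessing = prep, selector = selm,
              n_bands = NA_integer_, model = fam,
              r2_c = NA_real_, rmse_c = NA_real_,
              r2_p = NA_real_, rmse_p = NA_real_,
              status = "failed", note = conditionMessage(sel),
              stringsAsFactors = FALSE)
          }
          next
        }
        selections[[sel_key]] <- sel
        bands <- sel$selected_indices
        Xc <- cal_p$matrix[, bands, drop = FALSE]
        Xp <- prd_p$matrix[, bands, drop = FALSE]
        for (fam in models) {
          row <- tryCatch({
            model <- run_model(fam, Xc, y_c, seed)
            pc <- predict(model, Xc)
            pp <- predict(model, Xp)
            data.frame(
              index = toupper(target), preprocessing = prep, selector = selm,
              n_bands = length(bands), model = fam,
              r2_c = r_squared(y_c, pc), rmse_c = rmse(y_c, pc),
              r2_p = r_squared(y_p, pp), rmse_p = rmse(y_p, pp),
              status = "ok", note = "", stringsAsFactors = FALSE)
          }, error = function(e) data.frame(
            index = toupper(target), preprocessing = prep, selector = selm,
            n_bands = length(bands), model = fam,
            r2_c = NA_real_, rmse_c = NA_real_,
            r2_p = NA_real_, rmse_p = NA_real_,
            status = "failed", note = conditionMessage(e),
            stringsAsFactors = FALSE))
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  structure(list(report = do.call(rbind, rows), split = plan,
                 selections = selections,
                 seeds = list(split = split_seed, pipeline = seed)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat(sprintf("<evaluation_report> %d rows (%d calibration / %d prediction samples)\n",
              nrow(x$report), length(x$split$calibration_ids),
              length(x$split$prediction_ids)))
  df <- x$report
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df[, setdiff(names(df), "note")], row.names = FALSE)
  invisible(x)
}
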
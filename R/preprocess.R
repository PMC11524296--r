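#' Savitzky-Golay smoothing / differentiation of spectra
#'
#' Applies a Savitzky-Golay filter (local least-squares polynomial
#' convolution) to each spectrum independently. Edges are handled by the
#' filter's polynomial fit on truncated windows, so polynomials of degree
#' up to `polyorder` pass through unchanged everywhere, including the band
#' ends. Defaults (window 11, order 2, no derivative) are common NIR
#' smoothing practice; a derivative filter is available via `deriv`.
#'
#' @param set A [spectra_set()].
#' @param window Odd window length >= 3 (bands).
#' @param polyorder Polynomial order, `0 <= polyorder < window`.
#' @param deriv Derivative order, `0 <= deriv <= polyorder`.
#' @return A [spectra_set()] on the same grid.
#' @export
sg_smooth <- function(set, window = 11L, polyorder = 2L, deriv = 0L) {
  stopifnot(inherits(set, "spectra_set"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  if (deriv > polyorder) stop("deriv must be <= polyorder", call. = FALSE)
  if (window > n_bands(set$grid)) {
    stop("window exceeds the number of bands", call. = FALSE)
  }
  out <- t(apply(set$matrix, 1, signal::sgolayfilt,
                 p = polyorder, n = window, m = deriv))
  spectra_set(out, set$grid, ids = set$ids, meta = set$meta)
}

#' Standard normal variate (SNV) transform
#'
#' Centers every spectrum by its own mean and scales by its own standard
#' deviation (population convention, divisor `n`), removing per-sample
#' additive and multiplicative scatter. Affinely related spectra
#' (`a*x + b`, `a > 0`) map to identical output.
#'
#' @param set A [spectra_set()].
#' @return A [spectra_set()] of standardized spectra.
#' @export
snv <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  mu <- rowMeans(set$matrix)
  sd_pop <- sqrt(rowMeans((set$matrix - mu)^2))
  if (any(sd_pop == 0)) {
    stop(sprintf("zero-variance spectrum (sample %s): SNV undefined",
                 set$ids[which(sd_pop == 0)[1]]), call. = FALSE)
  }
  spectra_set((set$matrix - mu) / sd_pop, set$grid,
              ids = set$ids, meta = set$meta)
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum by ordinary least
#' squares, `x ~ a * r + b`, and returns the corrected spectrum
#' `(x - b) / a`. The reference defaults to the mean spectrum of the set
#' being transformed; when correcting a prediction set, pass the reference
#' frozen from the calibration set (returned in the result) so no
#' information leaks across the split.
#'
#' @param set A [spectra_set()].
#' @param reference Reference spectrum (length = bands). `NULL` uses the
#'   mean spectrum of `set`.
#' @return A [spectra_set()] with attributes `reference` (the spectrum
#'   used, for reuse on new data) and `coef` (per-sample fitted gain `a`
#'   and offset `b`).
#' @export
msc <- function(set, reference = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.null(reference)) reference <- colMeans(set$matrix)
  if (length(reference) != n_bands(set$grid)) {
    stop("reference length must equal the band count", call. = FALSE)
  }
  r <- as.numeric(reference)
  rc <- r - mean(r)
  ss <- sum(rc^2)
  if (ss == 0) stop("constant MSC reference is degenerate", call. = FALSE)
  out <- set$matrix
  coefs <- matrix(NA_real_, nrow(out), 2,
                  dimnames = list(set$ids, c("gain", "offset")))
  for (i in seq_len(nrow(out))) {
    x <- out[i, ]
    a <- sum((x - mean(x)) * rc) / ss
    b <- mean(x) - a * mean(r)
    if (abs(a) < 1e-12) {
      stop(sprintf("degenerate MSC fit (gain ~ 0) for sample %s",
                   set$ids[i]), call. = FALSE)
    }
    out[i, ] <- (x - b) / a
    coefs[i, ] <- c(a, b)
  }
  res <- spectra_set(out, set$grid, ids = set$ids, meta = set$meta)
  attr(res, "reference") <- r
  attr(res, "coef") <- coefs
  res
}

#' Apply a named preprocessing method
#'
#' Dispatcher used by the evaluation pipeline: `"none"`, `"sg"`, `"snv"` or
#' `"msc"`. For MSC the reference is fitted on `set` unless `state` (the
#' result of a previous call on the calibration set) supplies a frozen one.
#'
#' @param set A [spectra_set()].
#' @param method One of `"none"`, `"sg"`, `"snv"`, `"msc"`.
#' @param sg_window,sg_polyorder,sg_deriv Savitzky-Golay settings.
#' @param state Result of applying the same method to the calibration set;
#'   carries the frozen MSC reference.
#' @return A transformed [spectra_set()] (with the MSC reference attached
#'   when `method = "msc"`).
#' @export
apply_preprocess <- function(set, method = c("none", "sg", "snv", "msc"),
                             sg_window = 11L, sg_polyorder = 2L,
                             sg_deriv = 0L, state = NULL) {
  method <- match.arg(method)
  switch(method,
         none = set,
         sg = sg_smooth(set, sg_window, sg_polyorder, sg_deriv),
         snv = snv(set),
         msc = msc(set, reference = if (is.null(state)) NULL
                                    else attr(state, "reference")))
}
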
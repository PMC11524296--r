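#' Reflectance calibration against white and dark references
#'
#' Converts raw intensities to reflectance with the standard flat-field
#' normalisation `R = (I - D) / (W - D)`, where `I` is the raw cube, `W`
#' the white reference and `D` the dark reference. References may be full
#' images or single scan lines (broadcast across lines). The result is
#' invariant to rescaling `I`, `W`, `D` by a common positive factor.
#'
#' @param raw A raw-intensity [hypercube()].
#' @param refs A [reference_frames()] object.
#' @return A [hypercube()] flagged as reflectance.
#' @export
calibrate_reflectance <- function(raw, refs) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "reference_frames"))
  if (raw$reflectance) stop("cube is already reflectance", call. = FALSE)
  d <- dim(raw$data)
  rd <- dim(refs$white)
  white <- refs$white; dark <- refs$dark
  if (rd[1] == 1L && d[1] > 1L) {
    # scan-line references: replicate across lines
    if (!all(rd[2:3] == d[2:3])) {
      stop("scan-line references do not match cube samples/bands", call. = FALSE)
    }
    white <- array(rep(refs$white[1, , ], each = d[1]), dim = d)
    dark <- array(rep(refs$dark[1, , ], each = d[1]), dim = d)
  } else if (!identical(rd, d)) {
    stop("reference frames do not match cube dimensions", call. = FALSE)
  }
  denom <- white - dark
  if (any(denom == 0)) {
    bad <- which(denom == 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "degenerate calibration: white = dark at line %d, sample %d, band %d",
      bad[1], bad[2], bad[3]), call. = FALSE)
  }
  hypercube((raw$data - dark) / denom, raw$grid, reflectance = TRUE,
            interleave = raw$interleave)
}

#' Canopy mask by brightness thresholding
#'
#' Builds the region-of-interest mask: a pixel is included when its
#' brightness statistic is at or above the threshold (boundary inclusive).
#' The statistic is the mean reflectance across all bands by default, or a
#' single band's reflectance.
#'
#' @param cube A reflectance [hypercube()].
#' @param threshold Minimum brightness for inclusion (default 0.45).
#' @param statistic `"mean"` (mean over bands) or `"band"`.
#' @param band Band index used when `statistic = "band"`.
#' @return A logical lines x samples matrix of class `canopy_mask` with
#'   attributes `threshold`, `statistic` and `empty` (TRUE when no pixel
#'   passed).
#' @export
make_mask <- function(cube, threshold = 0.45,
                      statistic = c("mean", "band"), band = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  if (!cube$reflectance) {
    stop("mask thresholding expects a calibrated reflectance cube",
         call. = FALSE)
  }
  statistic <- match.arg(statistic)
  stat <- if (statistic == "mean") {
    rowMeans(matrix(cube$data, prod(dim(cube$data)[1:2]), dim(cube$data)[3]))
  } else {
    if (is.null(band)) stop("band index required for statistic = 'band'",
                            call. = FALSE)
    as.vector(cube$data[, , band])
  }
  m <- matrix(stat >= threshold, dim(cube$data)[1], dim(cube$data)[2])
  structure(m, class = c("canopy_mask", "matrix"),
            threshold = threshold, statistic = statistic,
            empty = !any(m))
}

#' Mean spectrum over the masked region of interest
#'
#' @param cube A reflectance [hypercube()].
#' @param mask A logical matrix (e.g. from [make_mask()]) matching the
#'   cube's spatial dimensions.
#' @return A list of class `roi_spectrum`: `grid`, `values` (per-band mean
#'   reflectance over masked pixels) and `n_pixels`.
#' @export
extract_roi_mean <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (!all(dim(mask)[1:2] == d[1:2])) {
    stop("mask does not match cube spatial dimensions", call. = FALSE)
  }
  keep <- as.vector(mask)
  if (!any(keep)) stop("empty ROI: no masked pixels to average", call. = FALSE)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  structure(list(grid = cube$grid,
                 values = colMeans(flat[keep, , drop = FALSE]),
                 n_pixels = sum(keep)),
            class = "roi_spectrum")
}

#' @export
print.roi_spectrum <- function(x, ...) {
  cat(sprintf("<roi_spectrum> %d bands, mean of %d pixels\n",
              length(x$values), x$n_pixels))
  invisible(x)
}
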
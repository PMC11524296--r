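#' Wavelength grid of band centers
#'
#' A `wavelength_grid` is the ordered vector of band-center wavelengths (nm)
#' shared by cubes, spectra matrices, and selection indices. The default grid
#' reproduces the instrument layout used throughout the package: 512 bands
#' uniformly spanning 870--1720 nm inclusive.
#'
#' @param wavelengths_nm Strictly increasing numeric vector of band centers
#'   in nanometres.
#' @return An object of class `wavelength_grid`: a numeric vector with a
#'   `n_bands` attribute.
#' @examples
#' g <- default_grid()
#' n_bands(g)
#' range(g)
#' @export
wavelength_grid <- function(wavelengths_nm) {
  w <- as.numeric(wavelengths_nm)
  if (length(w) < 2L) {
    stop("a wavelength grid needs at least two bands", call. = FALSE)
  }
  if (anyNA(w) || any(!is.finite(w))) {
    stop("wavelengths must be finite", call. = FALSE)
  }
  if (any(diff(w) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  structure(w, class = "wavelength_grid")
}

#' @rdname wavelength_grid
#' @param n_bands Number of bands for the default uniform grid.
#' @param from,to Range of the grid in nm (inclusive at both ends).
#' @export
default_grid <- function(n_bands = 512L, from = 870, to = 1720) {
  wavelength_grid(seq(from, to, length.out = n_bands))
}

#' @rdname wavelength_grid
#' @param grid A `wavelength_grid`.
#' @export
n_bands <- function(grid) length(unclass(grid))

#' Map wavelengths to nearest band indices on a grid
#'
#' @param grid A `wavelength_grid`.
#' @param wavelengths_nm Wavelengths to locate.
#' @return Integer band indices of the nearest grid band centers.
#' @export
nearest_band <- function(grid, wavelengths_nm) {
  w <- unclass(grid)
  vapply(wavelengths_nm, function(x) which.min(abs(w - x)), integer(1))
}

#' @export
print.wavelength_grid <- function(x, ...) {
  w <- unclass(x)
  cat(sprintf("<wavelength_grid> %d bands, %.1f-%.1f nm (step ~%.2f nm)\n",
              length(w), w[1], w[length(w)], mean(diff(w))))
  invisible(x)
}
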
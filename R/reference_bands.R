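#' Published characteristic-wavelength sets for Chinese fir needles
#'
#' Reference lists of the characteristic wavelengths reported for needle
#' LCC and LWC prediction in drought-stressed Chinese fir seedlings on the
#' 512-band 870--1720 nm instrument grid: 10 (SPA) and 53 (CARS) bands for
#' LCC, 13 (SPA) and 29 (CARS) bands for LWC. Shipped as a plain-text CSV
#' in `inst/extdata`; useful as a realistic input for retention statistics
#' and as a sanity reference for selections on synthetic data.
#'
#' @param method Optional filter: `"spa"` or `"cars"`.
#' @param trait Optional filter: `"lcc"` or `"lwc"`.
#' @return A data.frame with columns `method`, `trait`, `wavelength_nm`.
#' @export
reference_wavelengths <- function(method = NULL, trait = NULL) {
  path <- system.file("extdata", "chinese_fir_reference_wavelengths.csv",
                      package = "firspec", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(method)) df <- df[df$method == match.arg(method, c("spa", "cars")), ]
  if (!is.null(trait)) df <- df[df$trait == match.arg(trait, c("lcc", "lwc")), ]
  rownames(df) <- NULL
  df
}

#' Band retention percentage of a wavelength selection
#'
#' Maps selected wavelengths onto a grid's nearest band centers and
#' reports what percentage of the grid's bands they occupy -- the usual
#' summary of how aggressively a selector compressed the spectrum.
#'
#' @param wavelengths_nm Selected wavelengths (nm).
#' @param grid The [wavelength_grid()] they were selected from.
#' @return Percentage of grid bands retained (0--100).
#' @examples
#' sel <- reference_wavelengths("cars", "lcc")
#' band_retention_pct(sel$wavelength_nm) # ~10.35
#' @export
band_retention_pct <- function(wavelengths_nm, grid = default_grid()) {
  w <- unclass(grid)
  if (any(wavelengths_nm < w[1] - 1 | wavelengths_nm > w[length(w)] + 1)) {
    stop("selected wavelengths fall outside the grid", call. = FALSE)
  }
  idx <- unique(nearest_band(grid, wavelengths_nm))
  100 * length(idx) / n_bands(grid)
}
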
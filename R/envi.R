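#' Hyperspectral cube container
#'
#' A `hypercube` holds a rows x cols x bands array of intensities (raw
#' counts) or reflectance, together with the [wavelength_grid()] of its band
#' centers.
#'
#' @param data 3-D numeric array, dimensions (lines, samples, bands).
#' @param grid A [wavelength_grid()]; band count must match `dim(data)[3]`.
#' @param reflectance Logical flag: has this cube been calibrated?
#' @param interleave Storage interleave tag used when writing ("bsq"/"bil").
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, grid, reflectance = FALSE, interleave = "bsq") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("cube data must be 3-D", call. = FALSE)
  if (dim(data)[3] != n_bands(grid)) {
    stop(sprintf("cube has %d bands but grid has %d", dim(data)[3],
                 n_bands(grid)), call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("cube values must be finite", call. = FALSE)
  }
  interleave <- match.arg(tolower(interleave), c("bsq", "bil"))
  structure(list(data = data, grid = grid, reflectance = isTRUE(reflectance),
                 interleave = interleave), class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d lines x %d samples x %d bands [%s]\n",
              d[1], d[2], d[3],
              if (x$reflectance) "reflectance" else "raw intensity"))
  invisible(x)
}

#' White and dark reference frames
#'
#' Reference images used for reflectance calibration: the white frame is
#' acquired from a white reference panel (near full scale) and the dark
#' frame with the lens capped (sensor offset). Frames may be full images
#' with the same dimensions as the cube, or single scan lines
#' (1 x samples x bands) that are broadcast across all lines, as is common
#' for push-broom instruments.
#'
#' @param white,dark 3-D arrays, either cube-shaped or 1 x samples x bands.
#' @return An object of class `reference_frames`.
#' @export
reference_frames <- function(white, dark) {
  white <- as.array(white); dark <- as.array(dark)
  if (!identical(dim(white), dim(dark))) {
    stop("white and dark frames must have identical dimensions", call. = FALSE)
  }
  if (length(dim(white)) != 3L) stop("reference frames must be 3-D", call. = FALSE)
  structure(list(white = white, dark = dark), class = "reference_frames")
}

# --- ENVI format -----------------------------------------------------------
# Text header (samples/lines/bands/data type/interleave/wavelength list)
# plus a raw binary file. Data types 4 (float32) and 5 (float64); BSQ and
# BIL interleaves.

envi_data_path <- function(header_path) {
  stem <- sub("\\.hdr$", "", header_path)
  for (cand in c(stem, paste0(stem, ".raw"), paste0(stem, ".dat"),
                 paste0(stem, ".img"))) {
    if (file.exists(cand) && cand != header_path) return(cand)
  }
  stop("ENVI data file not found for header ", header_path, call. = FALSE)
}

parse_envi_header <- function(header_path) {
  txt <- readLines(header_path, warn = FALSE)
  joined <- paste(txt, collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(joined,
                    regexec(sprintf("(?im)^\\s*%s\\s*=\\s*([^\\n{]+)", key),
                            joined, perl = TRUE))[[1]]
    if (length(m) < 2) NA_character_ else trimws(m[2])
  }
  h <- list(
    samples = as.integer(get_scalar("samples")),
    lines = as.integer(get_scalar("lines")),
    bands = as.integer(get_scalar("bands")),
    data_type = as.integer(get_scalar("data type")),
    interleave = tolower(get_scalar("interleave")),
    byte_order = as.integer(get_scalar("byte order"))
  )
  if (anyNA(c(h$samples, h$lines, h$bands))) {
    stop("ENVI header parse error: samples/lines/bands missing", call. = FALSE)
  }
  if (is.na(h$data_type) || !h$data_type %in% c(4L, 5L)) {
    stop("ENVI header parse error: unsupported or missing data type ",
         "(supported: 4 = float32, 5 = float64)", call. = FALSE)
  }
  if (is.na(h$interleave) || !h$interleave %in% c("bsq", "bil")) {
    stop("ENVI header parse error: unknown interleave (supported: bsq, bil)",
         call. = FALSE)
  }
  wl_m <- regmatches(joined,
                     regexec("(?is)wavelength\\s*=\\s*\\{([^}]*)\\}",
                             joined, perl = TRUE))[[1]]
  if (length(wl_m) < 2) {
    stop("ENVI header parse error: wavelength list missing", call. = FALSE)
  }
  wl <- as.numeric(strsplit(wl_m[2], "[,\\s]+")[[1]] |> (\(x) x[nzchar(x)])())
  if (length(wl) != h$bands) {
    stop(sprintf(
      "ENVI header parse error: %d wavelengths listed but bands = %d",
      length(wl), h$bands), call. = FALSE)
  }
  h$wavelengths <- wl
  h
}

#' Read and write ENVI hyperspectral cubes
#'
#' `read_envi` parses an ENVI text header plus its companion raw binary
#' file into a [hypercube()]; `write_envi` does the reverse. BSQ and BIL
#' interleaves and float32/float64 (ENVI data types 4 and 5) are supported;
#' the round trip is lossless for float64. Wavelengths are parsed from the
#' header's `wavelength = { ... }` list into the cube's grid.
#'
#' @param header_path Path to the `.hdr` text header. The binary data file
#'   is looked up next to it (same stem, or stem + `.raw`/`.dat`/`.img`).
#' @return `read_envi` returns a [hypercube()]; `write_envi` returns the
#'   header path invisibly.
#' @export
read_envi <- function(header_path) {
  h <- parse_envi_header(header_path)
  data_path <- envi_data_path(header_path)
  size <- if (h$data_type == 4L) 4L else 8L
  n <- h$samples * h$lines * h$bands
  expected_bytes <- as.numeric(n) * size
  actual_bytes <- file.info(data_path)$size
  if (!isTRUE(actual_bytes == expected_bytes)) {
    stop(sprintf(
      "ENVI size mismatch: header implies %.0f bytes but %s has %.0f",
      expected_bytes, basename(data_path), actual_bytes), call. = FALSE)
  }
  con <- file(data_path, "rb"); on.exit(close(con))
  endian <- if (isTRUE(h$byte_order == 1L)) "big" else "little"
  v <- readBin(con, "double", n = n, size = size, endian = endian)
  # in-memory layout: (lines, samples, bands)
  cube <- if (h$interleave == "bsq") {
    aperm(array(v, dim = c(h$samples, h$lines, h$bands)), c(2, 1, 3))
  } else { # bil: samples fastest, then bands, then lines
    aperm(array(v, dim = c(h$samples, h$bands, h$lines)), c(3, 1, 2))
  }
  hypercube(cube, wavelength_grid(h$wavelengths), interleave = h$interleave)
}

#' @rdname read_envi
#' @param cube A [hypercube()].
#' @param data_type ENVI data type code: 4 (float32) or 5 (float64).
#' @export
write_envi <- function(cube, header_path, data_type = 5L) {
  stopifnot(inherits(cube, "hypercube"))
  if (!data_type %in% c(4L, 5L)) {
    stop("supported data types: 4 (float32), 5 (float64)", call. = FALSE)
  }
  d <- dim(cube$data)
  v <- if (cube$interleave == "bsq") {
    as.vector(aperm(cube$data, c(2, 1, 3)))
  } else {
    as.vector(aperm(cube$data, c(2, 3, 1)))
  }
  data_path <- paste0(sub("\\.hdr$", "", header_path), ".raw")
  con <- file(data_path, "wb")
  writeBin(v, con, size = if (data_type == 4L) 4L else 8L, endian = "little")
  close(con)
  wl <- paste(format(unclass(cube$grid), trim = TRUE, digits = 10),
              collapse = ", ")
  writeLines(c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", cube$interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = { %s }", wl)
  ), header_path)
  invisible(header_path)
}
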
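#' Spectra set: samples x bands reflectance with sample metadata
#'
#' The central container of the pipeline: a numeric matrix of reflectance
#' (rows = samples, columns = bands of a shared [wavelength_grid()]) plus a
#' metadata table carrying sample IDs, drought-group labels and, when known,
#' the ground-truth traits (LCC in mg/g, LWC as a fraction).
#'
#' @param matrix Numeric samples x bands matrix; column count must equal the
#'   grid's band count.
#' @param grid A [wavelength_grid()].
#' @param ids Character vector of unique sample identifiers (one per row).
#' @param meta Optional data.frame with one row per sample; columns `group`,
#'   `lcc`, `lwc` are recognised downstream.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(matrix, grid, ids = NULL, meta = NULL) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (ncol(m) != n_bands(grid)) {
    stop(sprintf("matrix has %d columns but grid has %d bands",
                 ncol(m), n_bands(grid)), call. = FALSE)
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop("reflectance values must be finite", call. = FALSE)
  }
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(m)))
  ids <- as.character(ids)
  if (length(ids) != nrow(m)) stop("one id per row required", call. = FALSE)
  if (anyDuplicated(ids)) stop("sample ids must be unique", call. = FALSE)
  rownames(m) <- ids
  colnames(m) <- band_names(grid)
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (nrow(meta) != nrow(m)) stop("meta must have one row per sample", call. = FALSE)
    meta$sample_id <- ids
  }
  structure(list(matrix = m, grid = grid, ids = ids, meta = meta),
            class = "spectra_set")
}

band_names <- function(grid) sprintf("nm%.4f", unclass(grid))

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d bands (%.1f-%.1f nm)\n",
              nrow(x$matrix), n_bands(x$grid),
              unclass(x$grid)[1], max(unclass(x$grid))))
  if (!is.null(x$meta) && "group" %in% names(x$meta)) {
    cat("  groups:", paste(names(table(x$meta$group)), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$matrix)

#' Subset a spectra set by sample and/or band
#'
#' @param x A `spectra_set`.
#' @param samples Row selector (ids, logical, or integer indices).
#' @param bands Band selector (integer indices into the grid).
#' @return A `spectra_set` restricted to the selection; selecting bands
#'   subsets the grid accordingly.
#' @export
subset_spectra <- function(x, samples = NULL, bands = NULL) {
  stopifnot(inherits(x, "spectra_set"))
  ri <- seq_len(nrow(x$matrix))
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, x$ids) else ri[samples]
    if (anyNA(ri)) stop("unknown sample id in selection", call. = FALSE)
  }
  ci <- if (is.null(bands)) seq_len(n_bands(x$grid)) else as.integer(bands)
  g <- if (is.null(bands)) x$grid else wavelength_grid(unclass(x$grid)[ci])
  spectra_set(x$matrix[ri, ci, drop = FALSE], g, ids = x$ids[ri],
              meta = if (is.null(x$meta)) NULL else x$meta[ri, , drop = FALSE])
}

#' Write / read a spectra set as CSV
#'
#' The schema is one row per sample: `sample_id`, `group`, `lcc`, `lwc`,
#' then one reflectance column per band named by its wavelength
#' (e.g. `nm870.0000`). Missing traits are written as empty fields.
#'
#' @param x A `spectra_set`.
#' @param path File path.
#' @return `read_spectra_csv` returns a `spectra_set`; the writer returns
#'   `path` invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  meta <- x$meta
  df <- data.frame(
    sample_id = x$ids,
    group = if (!is.null(meta) && "group" %in% names(meta)) meta$group else NA,
    lcc = if (!is.null(meta) && "lcc" %in% names(meta)) meta$lcc else NA,
    lwc = if (!is.null(meta) && "lwc" %in% names(meta)) meta$lwc else NA,
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(x$matrix))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  band_cols <- grep("^nm[0-9]", names(df))
  if (length(band_cols) < 2L) stop("no band columns (nm*) found", call. = FALSE)
  wl <- as.numeric(sub("^nm", "", names(df)[band_cols]))
  m <- as.matrix(df[, band_cols, drop = FALSE])
  meta <- df[, setdiff(names(df)[-band_cols], "sample_id"), drop = FALSE]
  spectra_set(m, wavelength_grid(wl), ids = df$sample_id, meta = meta)
}
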
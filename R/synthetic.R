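#' Configuration of the synthetic drought-gradient generator
#'
#' Builds the parameter set for [simulate_traits()], [simulate_spectra()] and
#' [simulate_cube()]. The defaults emulate the study design the pipeline is
#' meant for: 180 Chinese fir seedlings in five drought groups (D0, D14, D28,
#' D42, D56) of 36 seedlings each, with group-mean chlorophyll content (LCC)
#' declining from 2.4 to 0.1 mg/g and water content (LWC) from 68% to 9% as
#' drought progresses, measured on a 512-band 870--1720 nm reflectance grid.
#'
#' Spectra are built as a smooth quadratic continuum minus Gaussian
#' absorption features: water bands near 970 and 1450 nm (O-H overtones)
#' whose depths grow linearly with LWC, and chlorophyll-linked bands near
#' 1100 and 1190 nm (N-H / C-H overtones) whose depths grow linearly with
#' LCC. Each spectrum is then distorted by per-sample multiplicative gain
#' and additive offset (scatter, the signal MSC/SNV are designed to remove)
#' and additive Gaussian noise.
#'
#' @param n_per_group Seedlings per drought group (5 groups; total 5x).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param grid A [wavelength_grid()] (default 512 bands, 870--1720 nm).
#' @param lcc_means,lwc_means Group means for D0..D56 (mg/g; fraction).
#' @param trait_cv Within-group coefficient of variation (sd = cv * mean).
#' @param noise_sd Additive spectral noise sd (reflectance units).
#' @param scatter_gain_sd,scatter_offset_sd Sd of the per-sample
#'   multiplicative gain (around 1) and additive offset (around 0).
#' @param feature_centers_nm Absorption feature centers (nm).
#' @param feature_widths_nm Gaussian sd of each feature (nm).
#' @param feature_traits Trait driving each feature depth ("lwc" or "lcc").
#' @param feature_gains Depth per unit trait for each feature
#'   (reflectance per fraction for LWC features, per mg/g for LCC features).
#' @param baseline_coefs Continuum coefficients `c(b0, b1, b2)` of
#'   `b0 + b1*u + b2*u^2` with `u` the wavelength rescaled to \[-1, 1\].
#' @param scene_dim Spatial dimensions (rows, cols) of simulated cubes.
#' @param cube_noise_sd Pixelwise reflectance noise inside simulated cubes.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = 36L,
                             seed = 1L,
                             grid = default_grid(),
                             lcc_means = c(2.4, 1.8, 1.2, 0.6, 0.1),
                             lwc_means = c(0.68, 0.55, 0.40, 0.25, 0.09),
                             trait_cv = 0.10,
                             noise_sd = 0.005,
                             scatter_gain_sd = 0.05,
                             scatter_offset_sd = 0.02,
                             feature_centers_nm = c(970, 1100, 1190, 1450),
                             feature_widths_nm = c(30, 20, 40, 45),
                             feature_traits = c("lwc", "lcc", "lcc", "lwc"),
                             feature_gains = c(0.15, 0.05, 0.04, 0.50),
                             baseline_coefs = c(0.85, -0.05, -0.08),
                             scene_dim = c(24L, 24L),
                             cube_noise_sd = 0.01) {
  if (n_per_group < 1L) stop("n_per_group must be positive", call. = FALSE)
  stopifnot(inherits(grid, "wavelength_grid"))
  if (length(lcc_means) != 5L || length(lwc_means) != 5L) {
    stop("five group means required (D0, D14, D28, D42, D56)", call. = FALSE)
  }
  if (any(c(trait_cv, noise_sd, scatter_gain_sd, scatter_offset_sd,
            cube_noise_sd) < 0)) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  nf <- length(feature_centers_nm)
  if (length(feature_widths_nm) != nf || length(feature_traits) != nf ||
      length(feature_gains) != nf) {
    stop("feature vectors must have equal length", call. = FALSE)
  }
  if (!all(feature_traits %in% c("lcc", "lwc"))) {
    stop("feature_traits must be 'lcc' or 'lwc'", call. = FALSE)
  }
  w <- unclass(grid)
  if (any(feature_centers_nm < w[1] | feature_centers_nm > w[length(w)])) {
    stop("feature centers must lie within the wavelength grid", call. = FALSE)
  }
  structure(list(
    n_per_group = as.integer(n_per_group), seed = as.integer(seed),
    grid = grid, lcc_means = lcc_means, lwc_means = lwc_means,
    trait_cv = trait_cv, noise_sd = noise_sd,
    scatter_gain_sd = scatter_gain_sd, scatter_offset_sd = scatter_offset_sd,
    feature_centers_nm = feature_centers_nm,
    feature_widths_nm = feature_widths_nm,
    feature_traits = feature_traits, feature_gains = feature_gains,
    baseline_coefs = baseline_coefs,
    scene_dim = as.integer(scene_dim), cube_noise_sd = cube_noise_sd
  ), class = "synthetic_config")
}

drought_groups <- c("D0", "D14", "D28", "D42", "D56")

#' Simulate ground-truth traits for a drought gradient
#'
#' Draws per-seedling LCC (mg/g) and LWC (fraction) around the configured
#' group means with sd = `trait_cv` times the mean, truncated at the
#' physical bounds (LCC >= 0, LWC in \[0, 1\]) by resampling.
#'
#' @param config A [synthetic_config()].
#' @return A data.frame with columns `sample_id`, `group`, `lcc`, `lwc`;
#'   one row per seedling, groups ordered D0..D56.
#' @export
simulate_traits <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_per_group
  draw_trunc <- function(mean, sd, lower, upper) {
    x <- stats::rnorm(n, mean, sd)
    for (it in 1:100) {
      bad <- x < lower | x > upper
      if (!any(bad)) break
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    pmin(pmax(x, lower), upper)
  }
  rows <- lapply(seq_along(drought_groups), function(g) {
    data.frame(
      group = drought_groups[g],
      lcc = draw_trunc(config$lcc_means[g], config$trait_cv * config$lcc_means[g],
                       0, Inf),
      lwc = draw_trunc(config$lwc_means[g], config$trait_cv * config$lwc_means[g],
                       0, 1),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(sample_id = sprintf("S%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Noise-free generative map: continuum minus trait-scaled Gaussian features.
clean_spectrum <- function(lcc, lwc, config) {
  w <- unclass(config$grid)
  u <- 2 * (w - w[1]) / (w[length(w)] - w[1]) - 1
  b <- config$baseline_coefs
  base <- b[1] + b[2] * u + b[3] * u^2
  trait <- c(lcc = lcc, lwc = lwc)
  for (f in seq_along(config$feature_centers_nm)) {
    depth <- config$feature_gains[f] * trait[[config$feature_traits[f]]]
    base <- base - depth *
      exp(-(w - config$feature_centers_nm[f])^2 /
            (2 * config$feature_widths_nm[f]^2))
  }
  base
}

#' Simulate reflectance spectra from trait truth
#'
#' Applies the generative map described in [synthetic_config()]: clean
#' spectrum from the traits, then per-sample affine scatter
#' (gain ~ N(1, scatter_gain_sd), offset ~ N(0, scatter_offset_sd)),
#' then additive Gaussian noise, clipped to (0, 1.2\].
#'
#' @param truth Data.frame as returned by [simulate_traits()].
#' @param config A [synthetic_config()].
#' @return A [spectra_set()] with the truth attached as metadata.
#' @export
simulate_spectra <- function(truth, config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!all(c("lcc", "lwc") %in% names(truth))) {
    stop("truth must have lcc and lwc columns", call. = FALSE)
  }
  if (any(truth$lcc < 0) || any(truth$lwc < 0) || any(truth$lwc > 1)) {
    stop("traits out of physical bounds", call. = FALSE)
  }
  set.seed(config$seed + 1000L)
  n <- nrow(truth)
  p <- n_bands(config$grid)
  gains <- stats::rnorm(n, 1, config$scatter_gain_sd)
  offsets <- stats::rnorm(n, 0, config$scatter_offset_sd)
  m <- matrix(0, n, p)
  for (i in seq_len(n)) {
    s <- clean_spectrum(truth$lcc[i], truth$lwc[i], config)
    s <- gains[i] * s + offsets[i]
    if (config$noise_sd > 0) s <- s + stats::rnorm(p, 0, config$noise_sd)
    m[i, ] <- pmin(pmax(s, 1e-6), 1.2)
  }
  ids <- if ("sample_id" %in% names(truth)) truth$sample_id else NULL
  spectra_set(m, config$grid, ids = ids,
              meta = truth[, setdiff(names(truth), "sample_id"), drop = FALSE])
}

#' Simulate a raw hyperspectral cube with reference frames
#'
#' Builds a small push-broom-style scene for one seedling: a central disk of
#' "canopy" pixels carrying the sample's reflectance spectrum (with
#' pixelwise noise) over a dark background, plus matching full-scale white
#' and near-zero dark reference frames, and the ground-truth canopy mask.
#' Canopy reflectance is bright (continuum ~0.85) and background is held at
#' reflectance 0.08, so a 0.45 brightness threshold separates them exactly.
#'
#' @param truth_row One row of a [simulate_traits()] table (or any list with
#'   `lcc` and `lwc`).
#' @param config A [synthetic_config()].
#' @param canopy Optional logical matrix (scene_dim) to use as the canopy
#'   mask; default is a centred disk. An all-`FALSE` matrix gives a
#'   background-only scene.
#' @return A list with elements `cube` (raw intensity [hypercube()]),
#'   `refs` ([reference_frames()]), `mask` (true canopy mask) and
#'   `spectrum` (the injected clean reflectance spectrum).
#' @export
simulate_cube <- function(truth_row, config = synthetic_config(),
                          canopy = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  dims <- config$scene_dim
  if (length(dims) != 2L || any(dims < 2L)) {
    stop("scene must be at least 2x2", call. = FALSE)
  }
  set.seed(config$seed + 2000L)
  nr <- dims[1]; nc <- dims[2]; p <- n_bands(config$grid)
  if (is.null(canopy)) {
    rc <- expand.grid(r = seq_len(nr), c = seq_len(nc))
    d2 <- (rc$r - (nr + 1) / 2)^2 + (rc$c - (nc + 1) / 2)^2
    canopy <- matrix(d2 <= (min(nr, nc) / 3)^2, nr, nc)
  }
  stopifnot(is.logical(canopy), all(dim(canopy) == dims))
  spec <- clean_spectrum(truth_row$lcc, truth_row$lwc, config)
  full_scale <- 4095; dark_level <- 60
  refl <- array(0.08, dim = c(nr, nc, p))
  idx <- which(canopy)
  for (k in idx) {
    r <- (k - 1) %% nr + 1; cc <- (k - 1) %/% nr + 1
    px <- spec
    if (config$cube_noise_sd > 0) {
      px <- px + stats::rnorm(p, 0, config$cube_noise_sd)
    }
    refl[r, cc, ] <- pmin(pmax(px, 1e-6), 1.2)
  }
  raw <- dark_level + refl * (full_scale - dark_level)
  cube <- hypercube(raw, config$grid, reflectance = FALSE)
  refs <- reference_frames(
    white = array(full_scale, dim = c(nr, nc, p)),
    dark = array(dark_level, dim = c(nr, nc, p))
  )
  list(cube = cube, refs = refs, mask = canopy, spectrum = spec)
}
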
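#' Needle chlorophyll content from ethanol-extract absorbance
#'
#' Computes chlorophyll a, b and total concentrations from microplate
#' absorbance at 665 and 649 nm (95% ethanol extraction), then scales to
#' leaf chlorophyll content per gram of fresh needles:
#' \deqn{Ca = 13.95 D_{665} - 6.88 D_{649}}
#' \deqn{Cb = 24.96 D_{649} - 7.32 D_{665}}
#' \deqn{C_T = Ca + Cb}
#' \deqn{LCC = C_T \cdot V_T \cdot B_T / W}
#' Concentrations are mg/L and the extract volume is given in mL, so the
#' volume is converted to litres inside the formula (divide by 1000) to
#' make LCC come out in mg per g of fresh weight.
#'
#' Readings that yield a negative total concentration are reported with
#' `flag = "negative_ct"` rather than clamped, so bad wells surface in QC.
#' Absorbance at 470 nm (carotenoid channel) is accepted in lab sheets but
#' not consumed by any formula here.
#'
#' @param d665,d649 Absorbance readings (dimensionless, >= 0).
#' @param vt_ml Extract volume in mL.
#' @param bt Dilution ratio (>= 1).
#' @param fresh_weight_g Fresh needle weight in g (> 0).
#' @return A data.frame with columns `ca`, `cb`, `ct` (mg/L), `lcc` (mg/g)
#'   and `flag` (`"ok"` or `"negative_ct"`).
#' @examples
#' chlorophyll_content(1, 1, vt_ml = 10, bt = 1, fresh_weight_g = 0.3)
#' @export
chlorophyll_content <- function(d665, d649, vt_ml, bt = 1,
                                fresh_weight_g) {
  if (any(fresh_weight_g <= 0)) stop("fresh weight must be > 0", call. = FALSE)
  if (any(vt_ml <= 0)) stop("extract volume must be > 0", call. = FALSE)
  if (any(bt < 1)) stop("dilution ratio must be >= 1", call. = FALSE)
  if (any(!is.finite(c(d665, d649)))) stop("absorbance must be finite",
                                           call. = FALSE)
  ca <- 13.95 * d665 - 6.88 * d649
  cb <- 24.96 * d649 - 7.32 * d665
  ct <- ca + cb
  lcc <- ct * (vt_ml / 1000) * bt / fresh_weight_g
  data.frame(ca = ca, cb = cb, ct = ct, lcc = lcc,
             flag = ifelse(ct < 0, "negative_ct", "ok"),
             stringsAsFactors = FALSE)
}

#' Needle leaf water content from fresh and dry weights
#'
#' `LWC = (M1 - M2) / M1`, the water mass fraction of fresh needles,
#' returned as a fraction in \[0, 1\]; report layers multiply by 100 when a
#' percent display is wanted.
#'
#' @param m1_fresh_g Fresh needle weight in g (> 0).
#' @param m2_dry_g Oven-dry needle weight in g (0 <= m2 <= m1).
#' @return Numeric LWC fraction(s).
#' @examples
#' leaf_water_content(2.0, 0.64) # 0.68
#' @export
leaf_water_content <- function(m1_fresh_g, m2_dry_g) {
  if (any(m1_fresh_g <= 0)) stop("fresh weight must be > 0", call. = FALSE)
  if (any(m2_dry_g < 0)) stop("dry weight must be >= 0", call. = FALSE)
  if (any(m2_dry_g > m1_fresh_g)) {
    stop("dry weight cannot exceed fresh weight", call. = FALSE)
  }
  (m1_fresh_g - m2_dry_g) / m1_fresh_g
}

#' Compute a trait table from a lab sheet CSV
#'
#' Reads a wet-lab sheet with columns `sample_id`, `d665`, `d649`, `d470`,
#' `vt_ml`, `bt`, `fresh_weight_g`, `m1_g`, `m2_g` and returns the derived
#' trait table (sample_id, lcc, lwc, flag).
#'
#' @param path CSV path.
#' @return A data.frame with one row per sample.
#' @export
read_lab_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "d665", "d649", "vt_ml", "bt", "fresh_weight_g",
            "m1_g", "m2_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("lab sheet missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  chl <- chlorophyll_content(df$d665, df$d649, df$vt_ml, df$bt,
                             df$fresh_weight_g)
  data.frame(sample_id = df$sample_id, lcc = chl$lcc,
             lwc = leaf_water_content(df$m1_g, df$m2_g),
             flag = chl$flag, stringsAsFactors = FALSE)
}
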
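#' Relative electron density table
#'
#' Relative electron densities (water = 1) used to convert geometric tissue
#' segment lengths into water-equivalent lengths. The defaults are the values
#' commonly adopted for thoracic dosimetry: lung 0.3, soft tissue 1.0,
#' bone 1.2.
#'
#' @param lung Relative electron density of lung parenchyma.
#' @param tissue Relative electron density of soft tissue.
#' @param bone Relative electron density of (trabecular) bone.
#' @return An object of class `electron_density_table`: a named numeric
#'   vector with elements `lung`, `tissue`, `bone`.
#' @examples
#' electron_density_table()
#' @export
electron_density_table <- function(lung = 0.3, tissue = 1.0, bone = 1.2) {
  rho <- c(lung = lung, tissue = tissue, bone = bone)
  if (!all(is.finite(rho)) || any(rho <= 0)) {
    stop("electron densities must be finite and > 0")
  }
  structure(rho, class = "electron_density_table")
}

#' Tissue segment runs along a measurement chord
#'
#' A small record of consecutive same-tissue segments crossed by an AP or LAT
#' measurement line, as used for the electron-density-corrected dimension.
#'
#' @param tissue_class Character vector with values in
#'   `c("lung", "tissue", "bone")`.
#' @param length_cm Segment lengths in cm, same length as `tissue_class`.
#' @return A `data.frame` of class `segment_runs` with columns
#'   `tissue_class` and `length_cm`.
#' @export
segment_runs <- function(tissue_class = character(), length_cm = numeric()) {
  tissue_class <- as.character(tissue_class)
  length_cm <- as.numeric(length_cm)
  if (length(tissue_class) != length(length_cm)) {
    stop("tissue_class and length_cm must have equal length")
  }
  bad <- setdiff(unique(tissue_class), c("lung", "tissue", "bone"))
  if (length(bad) > 0) {
    stop("unknown tissue class: ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(length_cm)) || any(length_cm < 0)) {
    stop("segment lengths must be finite and >= 0")
  }
  structure(
    data.frame(tissue_class = tissue_class, length_cm = length_cm,
               stringsAsFactors = FALSE),
    class = c("segment_runs", "data.frame")
  )
}

#' Water-equivalent diameter from ROI statistics
#'
#' TG220 water-equivalent diameter of a region of interest:
#' \deqn{D_w = 2 \sqrt{\left(\frac{\overline{CT}}{1000} + 1\right)
#'   \frac{A_{ROI}}{\pi}}}
#' where the mean CT number is in Hounsfield units and the area in cm^2.
#'
#' @param mean_ct Mean CT number over the ROI (HU); must be >= -1000.
#' @param area_cm2 ROI area in cm^2; must be >= 0.
#' @return Water-equivalent diameter in cm.
#' @examples
#' water_equivalent_diameter(0, 100 * pi)    # a water disc of radius 10 cm
#' water_equivalent_diameter(-500, 8 * pi)
#' @export
water_equivalent_diameter <- function(mean_ct, area_cm2) {
  if (!all(is.finite(mean_ct)) || !all(is.finite(area_cm2))) {
    stop("mean_ct and area_cm2 must be finite")
  }
  if (any(mean_ct < -1000)) {
    stop("mean_ct below -1000 HU would make the attenuation bracket negative")
  }
  if (any(area_cm2 < 0)) stop("area_cm2 must be >= 0")
  2 * sqrt((mean_ct / 1000 + 1) * area_cm2 / pi)
}

#' Electron-density-corrected dimension
#'
#' Water-equivalent length of a body dimension: the sum over the tissue
#' segments crossed by the measurement line of segment length times relative
#' electron density, \eqn{\sum_j \rho_e(j) \, l(j)}.
#'
#' @param runs A [segment_runs()] table (or data.frame with columns
#'   `tissue_class`, `length_cm`). An empty table yields 0.
#' @param densities An [electron_density_table()].
#' @return Corrected dimension in cm.
#' @examples
#' corrected_dimension(segment_runs(c("lung", "tissue", "bone"), c(10, 5, 2)))
#' @export
corrected_dimension <- function(runs, densities = electron_density_table()) {
  if (is.null(runs) || nrow(runs) == 0) return(0)
  runs <- segment_runs(runs$tissue_class, runs$length_cm)
  sum(unclass(densities)[runs$tissue_class] * runs$length_cm)
}

#' Corrected effective diameter
#'
#' Geometric mean of the electron-density-corrected AP and LAT dimensions,
#' \eqn{D_{eff}^{corr} = \sqrt{AP^{corr} \times LAT^{corr}}}.
#'
#' @param ap_corr Corrected anterior-posterior dimension (cm), >= 0.
#' @param lat_corr Corrected lateral dimension (cm), >= 0.
#' @return Corrected effective diameter in cm.
#' @export
corrected_effective_diameter <- function(ap_corr, lat_corr) {
  if (any(!is.finite(ap_corr)) || any(!is.finite(lat_corr)) ||
      any(ap_corr < 0) || any(lat_corr < 0)) {
    stop("ap_corr and lat_corr must be finite and >= 0")
  }
  sqrt(ap_corr * lat_corr)
}

#' Size-dependent conversion factor
#'
#' Exponential conversion factor for the 32-cm PMMA body phantom at 120 kVp,
#' \eqn{f = 3.704369 \, e^{-0.03671937 D}}, applied identically to the
#' corrected effective diameter and the water-equivalent diameter. `f` is
#' strictly decreasing in the diameter and exceeds 1 for diameters below
#' about 35.7 cm.
#'
#' @param diameter Patient size in cm (either diameter flavour), >= 0.
#' @return Dimensionless conversion factor.
#' @examples
#' conversion_factor(c(15.9, 20.9, 25.9))
#' @export
conversion_factor <- function(diameter) {
  if (any(!is.finite(diameter)) || any(diameter < 0)) {
    stop("diameter must be finite and >= 0")
  }
  3.704369 * exp(-0.03671937 * diameter)
}

#' Size-specific dose estimate
#'
#' \eqn{SSDE = f \times CTDI_{vol}} in mGy.
#'
#' @param f Size-dependent conversion factor, > 0.
#' @param ctdi_vol Volumetric CT dose index in mGy, >= 0.
#' @return SSDE in mGy.
#' @export
ssde <- function(f, ctdi_vol) {
  if (any(!is.finite(f)) || any(f <= 0)) stop("f must be finite and > 0")
  if (any(!is.finite(ctdi_vol)) || any(ctdi_vol < 0)) {
    stop("ctdi_vol must be finite and >= 0")
  }
  f * ctdi_vol
}

#' Assemble a per-slice dose result
#'
#' Bundles both diameter flavours with their conversion factors and SSDEs.
#' The SSDE slots satisfy `ssde_x == f_x * ctdi_vol` by construction; when
#' `ctdi_vol` is `NA` the SSDE slots are `NA` and only the diameters are
#' reported.
#'
#' @param d_w Water-equivalent diameter (cm).
#' @param d_eff_corr Corrected effective diameter (cm).
#' @param ctdi_vol CTDIvol (mGy), or `NA` when the scanner did not report it.
#' @param id Optional slice identifier.
#' @return A list of class `dose_result` with elements `id`, `d_w`,
#'   `d_eff_corr`, `f_dw`, `f_deff`, `ctdi_vol`, `ssde_dw`, `ssde_deff`.
#' @export
dose_result <- function(d_w, d_eff_corr, ctdi_vol = NA_real_, id = NA_character_) {
  if (d_w < 0 || d_eff_corr < 0) stop("diameters must be >= 0")
  f_dw <- conversion_factor(d_w)
  f_deff <- conversion_factor(d_eff_corr)
  has_dose <- is.finite(ctdi_vol)
  if (has_dose && ctdi_vol < 0) stop("ctdi_vol must be >= 0")
  structure(list(
    id = as.character(id),
    d_w = d_w, d_eff_corr = d_eff_corr,
    f_dw = f_dw, f_deff = f_deff,
    ctdi_vol = if (has_dose) ctdi_vol else NA_real_,
    ssde_dw = if (has_dose) ssde(f_dw, ctdi_vol) else NA_real_,
    ssde_deff = if (has_dose) ssde(f_deff, ctdi_vol) else NA_real_
  ), class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat("SSDE result", if (!is.na(x$id)) paste0("[", x$id, "]"), "\n")
  cat(sprintf("  D_w         : %.1f cm (f = %.2f)\n", x$d_w, x$f_dw))
  cat(sprintf("  D_eff^corr  : %.1f cm (f = %.2f)\n", x$d_eff_corr, x$f_deff))
  if (is.finite(x$ctdi_vol)) {
    cat(sprintf("  CTDIvol     : %.1f mGy\n", x$ctdi_vol))
    cat(sprintf("  SSDE (D_w)  : %.1f mGy\n", x$ssde_dw))
    cat(sprintf("  SSDE (D_eff): %.1f mGy\n", x$ssde_deff))
  } else {
    cat("  CTDIvol     : not available (SSDE not computed)\n")
  }
  invisible(x)
}
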
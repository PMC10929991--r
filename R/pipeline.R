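#' Compute the SSDE for one slice
#'
#' The full per-slice chain: segment the slice into four tissue classes,
#' extract the body mask and measurement axes, compute the water-equivalent
#' diameter from the body-ROI statistics and the corrected effective
#' diameter from the electron-density-weighted AP/LAT chords, then apply
#' the size-dependent conversion factor to CTDIvol for both diameters.
#'
#' @param slice A [ct_slice()].
#' @param segmenter `"threshold"` (default, deterministic) or `"unet"`
#'   (requires `model`).
#' @param model A trained `unet_model` when `segmenter = "unet"`.
#' @param densities An [electron_density_table()].
#' @param ctdi_vol Optional CTDIvol override in mGy (takes precedence over
#'   the slice's value).
#' @param thresholds Named list overriding the threshold segmenter's
#'   defaults (`body_thr`, `lung_thr`, `bone_thr`).
#' @return A list of class `ssde_result` with `dose` (a [dose_result()]),
#'   `class_map`, `measurement` (the [measure_corrected_dimensions()]
#'   output) and `roi` (the [roi_stats()]).
#' @export
compute_ssde <- function(slice, segmenter = c("threshold", "unet"),
                         model = NULL,
                         densities = electron_density_table(),
                         ctdi_vol = NULL, thresholds = list()) {
  segmenter <- match.arg(segmenter)
  if (segmenter == "unet") {
    if (is.null(model)) stop("segmenter = \"unet\" requires a model")
    class_map <- predict_classmap(model, slice)
  } else {
    class_map <- do.call(threshold_segment, c(list(slice), thresholds))
  }
  meas <- measure_corrected_dimensions(class_map, densities)
  roi <- roi_stats(slice$hu_pixels, meas$geometry$body_mask,
                   slice$pixel_spacing)
  d_w <- water_equivalent_diameter(roi$mean_ct, roi$area)
  d_eff <- corrected_effective_diameter(meas$ap_corr, meas$lat_corr)
  dose_ctdi <- if (!is.null(ctdi_vol)) ctdi_vol else slice$ctdi_vol
  structure(list(
    dose = dose_result(d_w, d_eff, dose_ctdi, slice$id),
    class_map = class_map,
    measurement = meas,
    roi = roi
  ), class = "ssde_result")
}

#' Compute SSDEs for a batch of slices
#'
#' Applies [compute_ssde()] to each slice; per-slice failures are reported
#' as warnings and skipped, and the number skipped is attached to the
#' result.
#'
#' @param slices List of [ct_slice()] objects.
#' @inheritParams compute_ssde
#' @return A list of `ssde_result`s with attribute `n_failed`.
#' @export
compute_ssde_batch <- function(slices, segmenter = "threshold", model = NULL,
                               densities = electron_density_table(),
                               ctdi_vol = NULL, thresholds = list()) {
  out <- list()
  n_failed <- 0L
  for (s in slices) {
    res <- tryCatch(
      compute_ssde(s, segmenter, model, densities, ctdi_vol, thresholds),
      error = function(e) {
        warning("slice ", s$id, " skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) n_failed <- n_failed + 1L else out[[length(out) + 1L]] <- res
  }
  attr(out, "n_failed") <- n_failed
  out
}
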
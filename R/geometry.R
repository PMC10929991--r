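#' Tissue class map
#'
#' Per-pixel tissue labels for an axial slice: 0 = background, 1 = lung,
#' 2 = other (soft) tissue, 3 = bone.
#'
#' @param labels Integer matrix with values in `0:3` (rows = AP direction,
#'   row 1 anterior; columns = LAT direction).
#' @param pixel_spacing Pixel spacing in mm, `c(row, col)`; a scalar is
#'   recycled to both directions.
#' @return An object of class `tissue_class_map`.
#' @export
tissue_class_map <- function(labels, pixel_spacing) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:3)) stop("labels must be in {0, 1, 2, 3}")
  pixel_spacing <- check_spacing(pixel_spacing)
  structure(list(labels = labels, pixel_spacing = pixel_spacing),
            class = "tissue_class_map")
}

check_spacing <- function(pixel_spacing) {
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (length(pixel_spacing) != 2 || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0)) {
    stop("pixel_spacing must be two positive values (mm)")
  }
  pixel_spacing
}

class_names <- c("background", "lung", "tissue", "bone")

#' Extract the body mask from a class map
#'
#' Union of all non-background labels, hole-filled (so internal air such as
#' the trachea stays inside the body region) and reduced to the largest
#' connected component, which discards couch or clothing fragments.
#'
#' @param class_map A [tissue_class_map()].
#' @return A logical matrix, `TRUE` inside the body.
#' @export
extract_body_mask <- function(class_map) {
  labels <- class_map$labels
  mask <- labels > 0L
  if (!any(mask)) stop("empty segmentation: no non-background pixels")
  largest_filled_component(mask)
}

# hole fill + keep largest 4/8-connected component (EBImage morphology)
largest_filled_component <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  comp <- EBImage::bwlabel(m)
  counts <- tabulate(comp[comp > 0])
  keep <- which.max(counts)
  m <- matrix(as.numeric(comp == keep), nrow(mask), ncol(mask))
  m <- EBImage::fillHull(m)
  matrix(m > 0.5, nrow(mask), ncol(mask))
}

#' Body contour geometry: centroid and AP/LAT measurement chords
#'
#' Finds the body centroid (mask centre of mass, in physical coordinates so
#' anisotropic pixels are honoured) and the two orthogonal measurement chords
#' through it, oriented along the mask's principal axes. The chord whose
#' direction lies closer to the image column axis is named LAT, the other AP;
#' for a supine thorax (wider than deep) LAT is therefore the major axis.
#' Near-isotropic masks (principal axis ratio within 1%) fall back to the
#' image row/column axes.
#'
#' @param body_mask Logical matrix from [extract_body_mask()].
#' @param pixel_spacing Pixel spacing in mm, `c(row, col)`.
#' @return A list of class `body_geometry` with `body_mask`, `centroid`
#'   (fractional pixel `c(row, col)`), `ap_line`, `lat_line` (each a list
#'   with fractional-pixel `start`, `end` and `length_mm`), and
#'   `pixel_spacing`.
#' @export
body_axes <- function(body_mask, pixel_spacing) {
  if (!is.matrix(body_mask)) stop("body_mask must be a matrix")
  pixel_spacing <- check_spacing(pixel_spacing)
  idx <- which(body_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty body mask")
  sr <- pixel_spacing[1]; sc <- pixel_spacing[2]
  # physical coordinates of pixel centres (mm): y down the rows, x across
  y <- idx[, 1] * sr
  x <- idx[, 2] * sc
  ctr <- c(mean(y), mean(x))
  cv <- stats::cov(cbind(y - ctr[1], x - ctr[2]))
  eg <- eigen(cv, symmetric = TRUE)
  ratio <- sqrt(max(eg$values[1], 0) / max(eg$values[2], .Machine$double.eps))
  if (!is.finite(ratio) || ratio < 1.01) {
    major <- c(0, 1); minor <- c(1, 0)          # tie: image axes (y, x)
  } else {
    major <- eg$vectors[, 1]; minor <- eg$vectors[, 2]
  }
  # name by image orientation: larger |x-component| -> lateral chord
  if (abs(major[2]) >= abs(minor[2])) {
    lat_dir <- major; ap_dir <- minor
  } else {
    lat_dir <- minor; ap_dir <- major
  }
  step <- 0.5 * min(pixel_spacing)
  lat_line <- trace_chord(body_mask, ctr, lat_dir, pixel_spacing, step)
  ap_line <- trace_chord(body_mask, ctr, ap_dir, pixel_spacing, step)
  structure(list(
    body_mask = body_mask,
    centroid = c(ctr[1] / sr, ctr[2] / sc),
    ap_line = ap_line, lat_line = lat_line,
    pixel_spacing = pixel_spacing
  ), class = "body_geometry")
}

# march from the centroid in +/- dir (unit vector in mm space) until the
# mask is left; returns fractional-pixel endpoints and the chord length
trace_chord <- function(mask, ctr_mm, dir, pixel_spacing, step_mm) {
  dir <- dir / sqrt(sum(dir^2))
  sr <- pixel_spacing[1]; sc <- pixel_spacing[2]
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(p_mm) {
    i <- round(p_mm[1] / sr); j <- round(p_mm[2] / sc)
    i >= 1 && i <= nr && j >= 1 && j <= nc && mask[i, j]
  }
  if (!inside(ctr_mm)) stop("body centroid lies outside the mask")
  extent <- function(sgn) {
    t <- 0
    repeat {
      t_next <- t + step_mm
      if (!inside(ctr_mm + sgn * t_next * dir)) break
      t <- t_next
    }
    # refine the boundary crossing to well below a pixel
    lo <- t; hi <- t_next
    for (k in 1:20) {
      mid <- (lo + hi) / 2
      if (inside(ctr_mm + sgn * mid * dir)) lo <- mid else hi <- mid
    }
    lo
  }
  t_pos <- extent(1); t_neg <- extent(-1)
  p1 <- ctr_mm - t_neg * dir
  p2 <- ctr_mm + t_pos * dir
  list(start = c(p1[1] / sr, p1[2] / sc),
       end = c(p2[1] / sr, p2[2] / sc),
       length_mm = t_pos + t_neg)
}

#' Tissue segment runs along a chord
#'
#' Samples the class map along a measurement line at sub-pixel steps
#' (nearest-neighbour labels), merges consecutive equal labels into runs and
#' converts run lengths to cm. Background samples inside the body mask
#' (internal air such as the trachea) are scored as lung, the closest
#' attenuation class; samples outside the body are dropped.
#'
#' @param class_map A [tissue_class_map()].
#' @param line A chord as returned inside [body_axes()] (`start`, `end` in
#'   fractional pixels, `length_mm`).
#' @param body_mask Optional precomputed body mask; derived from the class
#'   map when omitted.
#' @return A [segment_runs()] table, in geometric order along the line.
#' @export
scan_tissue_runs <- function(class_map, line, body_mask = NULL) {
  if (is.null(body_mask)) body_mask <- extract_body_mask(class_map)
  labels <- class_map$labels
  nr <- nrow(labels); nc <- ncol(labels)
  d <- c(line$end[1] - line$start[1], line$end[2] - line$start[2])
  len_px <- sqrt(sum(d^2))
  if (line$length_mm <= 0 || len_px == 0) return(segment_runs())
  n <- max(2L, as.integer(ceiling(len_px / 0.5)) + 1L)
  tt <- seq(0, 1, length.out = n)
  ri <- pmin(pmax(round(line$start[1] + tt * d[1]), 1L), nr)
  ci <- pmin(pmax(round(line$start[2] + tt * d[2]), 1L), nc)
  flat <- (ci - 1L) * nr + ri
  in_body <- body_mask[flat]
  if (!any(in_body)) return(segment_runs())
  lab <- labels[flat][in_body]
  lab[lab == 0L] <- 1L                       # internal air scored as lung
  seg_len_cm <- (line$length_mm / n) / 10    # per-sample length
  r <- rle(lab)
  segment_runs(class_names[r$values + 1L], r$lengths * seg_len_cm)
}

#' Corrected AP and LAT dimensions of a slice
#'
#' Composes body-mask extraction, axis finding, chord scanning and
#' electron-density weighting into the per-slice size measurement.
#'
#' @param class_map A [tissue_class_map()].
#' @param densities An [electron_density_table()].
#' @return A list of class `axis_measurement` with `ap_corr`, `lat_corr`
#'   (cm), the per-chord `ap_runs` / `lat_runs` tables, and the
#'   `body_geometry`.
#' @export
measure_corrected_dimensions <- function(class_map,
                                         densities = electron_density_table()) {
  mask <- extract_body_mask(class_map)
  geom <- body_axes(mask, class_map$pixel_spacing)
  ap_runs <- scan_tissue_runs(class_map, geom$ap_line, mask)
  lat_runs <- scan_tissue_runs(class_map, geom$lat_line, mask)
  structure(list(
    ap_corr = corrected_dimension(ap_runs, densities),
    lat_corr = corrected_dimension(lat_runs, densities),
    ap_runs = ap_runs, lat_runs = lat_runs,
    geometry = geom
  ), class = "axis_measurement")
}

#' ROI statistics for the water-equivalent diameter
#'
#' Mean CT number and physical area of a pixel region; the inputs of the
#' water-equivalent-diameter formula. The conventional ROI is the hole-filled
#' body mask, so internal air contributes to the mean CT number.
#'
#' @param hu_image Numeric matrix of Hounsfield units.
#' @param body_mask Logical matrix, same shape.
#' @param pixel_spacing Pixel spacing in mm, `c(row, col)`.
#' @return A list of class `roi_stats` with `mean_ct` (HU) and `area`
#'   (cm^2).
#' @export
roi_stats <- function(hu_image, body_mask, pixel_spacing) {
  if (!identical(dim(hu_image), dim(body_mask))) {
    stop("hu_image and body_mask must have the same shape")
  }
  if (!any(body_mask)) stop("empty body mask")
  pixel_spacing <- check_spacing(pixel_spacing)
  px_area_cm2 <- prod(pixel_spacing) / 100
  structure(list(
    mean_ct = mean(hu_image[body_mask]),
    area = sum(body_mask) * px_area_cm2
  ), class = "roi_stats")
}
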
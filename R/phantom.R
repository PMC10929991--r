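#' Synthetic thoracic phantom specification
#'
#' Defines an elliptical soft-tissue body on an air background, two lung
#' ellipses mirrored about the AP axis and a posterior vertebral disc on the
#' AP chord, mimicking the arrangement of a supine thorax so that both
#' measurement chords cross non-tissue classes. All region sizes are in cm;
#' the geometry is exact, so the water-equivalent diameter and the corrected
#' effective diameter have closed forms.
#'
#' Default Hounsfield assignments (air -1000, lung -700, tissue 0,
#' bone +300) sit at least 100 HU inside the threshold segmenter's default
#' brackets, which makes the threshold segmenter an exact oracle on
#' noiseless rasters.
#'
#' @param body_a_lat,body_b_ap Body semi-axes (cm): lateral and AP.
#' @param lung_center_x Lateral offset of each lung centre (cm, mirrored).
#' @param lung_center_y AP offset of the lung centres (cm; 0 = on the LAT
#'   chord).
#' @param lung_a,lung_b Lung semi-axes (cm): lateral and AP.
#' @param bone_center_y AP offset of the vertebral disc centre (cm,
#'   positive = posterior); the disc is centred on the AP chord.
#' @param bone_radius Vertebral disc radius (cm).
#' @param hu Named numeric vector of Hounsfield assignments for
#'   `air`, `lung`, `tissue`, `bone`.
#' @param pixel_spacing Raster pixel spacing in mm, `c(row, col)` or scalar.
#' @param n_pix Raster size (square, pixels).
#' @param ctdi_vol CTDIvol to attach to the slice (mGy).
#' @param noise_sd Gaussian HU noise standard deviation (0 = noiseless).
#' @param id Slice identifier.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(body_a_lat = 15, body_b_ap = 10,
                         lung_center_x = 0.45 * body_a_lat,
                         lung_center_y = 0,
                         lung_a = 0.28 * body_a_lat,
                         lung_b = 0.55 * body_b_ap,
                         bone_center_y = 0.55 * body_b_ap,
                         bone_radius = 0.15 * body_b_ap,
                         hu = c(air = -1000, lung = -700, tissue = 0, bone = 300),
                         pixel_spacing = c(1, 1),
                         n_pix = 416L,
                         ctdi_vol = 8.5,
                         noise_sd = 0,
                         id = "phantom") {
  pixel_spacing <- check_spacing(pixel_spacing)
  spec <- structure(list(
    body_a_lat = body_a_lat, body_b_ap = body_b_ap,
    lung_center_x = lung_center_x, lung_center_y = lung_center_y,
    lung_a = lung_a, lung_b = lung_b,
    bone_center_y = bone_center_y, bone_radius = bone_radius,
    hu = hu, pixel_spacing = pixel_spacing, n_pix = as.integer(n_pix),
    ctdi_vol = ctdi_vol, noise_sd = noise_sd, id = id
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(s) {
  if (s$body_a_lat <= 0 || s$body_b_ap <= 0) stop("body semi-axes must be > 0")
  if (s$lung_a < 0 || s$lung_b < 0 || s$bone_radius < 0) {
    stop("lung semi-axes and bone radius must be >= 0")
  }
  if (xor(s$lung_a == 0, s$lung_b == 0)) {
    stop("lung semi-axes must both be 0 (no lungs) or both positive")
  }
  if (!all(c("air", "lung", "tissue", "bone") %in% names(s$hu))) {
    stop("hu must name air, lung, tissue and bone values")
  }
  # regions strictly inside the body, lungs disjoint from bone (sampled check)
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  in_body <- function(x, y, margin = 0.995) {
    all((x / s$body_a_lat)^2 + (y / s$body_b_ap)^2 < margin^2)
  }
  has_lungs <- s$lung_a > 0
  has_bone <- s$bone_radius > 0
  if (has_lungs) {
    lx <- s$lung_center_x + s$lung_a * cos(th)
    ly <- s$lung_center_y + s$lung_b * sin(th)
    if (!in_body(lx, ly)) stop("lungs must lie strictly inside the body")
  }
  if (has_bone) {
    bx <- s$bone_radius * cos(th)
    by <- s$bone_center_y + s$bone_radius * sin(th)
    if (!in_body(bx, by)) stop("bone must lie strictly inside the body")
    if (has_lungs &&
        (any(((bx - s$lung_center_x) / s$lung_a)^2 +
               ((by - s$lung_center_y) / s$lung_b)^2 <= 1.01) ||
         any(((bx + s$lung_center_x) / s$lung_a)^2 +
               ((by - s$lung_center_y) / s$lung_b)^2 <= 1.01))) {
      stop("bone must be disjoint from the lungs")
    }
  }
  fov <- s$n_pix * s$pixel_spacing / 10   # cm, (AP, LAT)
  if (2 * s$body_b_ap >= fov[1] - 0.4 || 2 * s$body_a_lat >= fov[2] - 0.4) {
    stop("body does not fit in the raster field of view")
  }
  invisible(s)
}

#' Rasterise a phantom and compute its analytic truth
#'
#' Paints the regions back-to-front (body, lungs, bone) on an air background
#' by pixel-centre membership, then adds seeded Gaussian HU noise if
#' requested. The ground truth (class map and analytic sizes) comes from the
#' exact geometry, not from the raster, so rasterisation error is measurable.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional integer seed for the noise.
#' @return A list with `slice` (a [ct_slice()]) and `truth` (class
#'   `phantom_truth`): the exact-geometry class map plus analytic `d_w`,
#'   `ap_corr`, `lat_corr`, `d_eff_corr`, `mean_ct`, `area`.
#' @export
generate_phantom <- function(spec, seed = NULL) {
  validate_phantom_spec(spec)
  n <- spec$n_pix
  sr <- spec$pixel_spacing[1]; sc <- spec$pixel_spacing[2]
  # pixel-centre coordinates (cm), origin at raster centre; y positive = posterior
  yy <- ((seq_len(n) - (n + 1) / 2) * sr) / 10
  xx <- ((seq_len(n) - (n + 1) / 2) * sc) / 10
  Y <- matrix(yy, n, n)          # rows vary
  X <- matrix(xx, n, n, byrow = TRUE)
  lab <- matrix(0L, n, n)
  lab[(X / spec$body_a_lat)^2 + (Y / spec$body_b_ap)^2 <= 1] <- 2L
  if (spec$lung_a > 0) {
    for (sgn in c(-1, 1)) {
      lab[((X - sgn * spec$lung_center_x) / spec$lung_a)^2 +
            ((Y - spec$lung_center_y) / spec$lung_b)^2 <= 1] <- 1L
    }
  }
  if (spec$bone_radius > 0) {
    lab[X^2 + (Y - spec$bone_center_y)^2 <= spec$bone_radius^2] <- 3L
  }
  hu <- matrix(spec$hu[["air"]], n, n)
  hu[lab == 1L] <- spec$hu[["lung"]]
  hu[lab == 2L] <- spec$hu[["tissue"]]
  hu[lab == 3L] <- spec$hu[["bone"]]
  if (spec$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    hu <- hu + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
    hu <- pmax(hu, -1024)   # scanner floor of the HU scale
  }
  dims <- analytic_corrected_dims(spec)
  roi <- analytic_roi(spec)
  truth <- structure(list(
    class_map = tissue_class_map(lab, spec$pixel_spacing),
    d_w = analytic_dw(spec),
    ap_corr = dims$ap_corr, lat_corr = dims$lat_corr,
    d_eff_corr = corrected_effective_diameter(dims$ap_corr, dims$lat_corr),
    mean_ct = roi$mean_ct, area = roi$area
  ), class = "phantom_truth")
  list(
    slice = ct_slice(hu, spec$pixel_spacing, ctdi_vol = spec$ctdi_vol,
                     id = spec$id),
    truth = truth
  )
}

# exact region areas (cm^2) and area-weighted mean HU over the body ellipse
analytic_roi <- function(spec) {
  a_body <- pi * spec$body_a_lat * spec$body_b_ap
  a_lung <- 2 * pi * spec$lung_a * spec$lung_b
  a_bone <- pi * spec$bone_radius^2
  a_tissue <- a_body - a_lung - a_bone
  mean_ct <- (spec$hu[["tissue"]] * a_tissue + spec$hu[["lung"]] * a_lung +
                spec$hu[["bone"]] * a_bone) / a_body
  list(mean_ct = as.numeric(mean_ct), area = a_body)
}

#' Closed-form water-equivalent diameter of a phantom
#'
#' Evaluates the water-equivalent-diameter formula on the exact ellipse/disc
#' areas: the mean CT number is the area-weighted mean of the region HU
#' values over the body ellipse.
#'
#' @param spec A [phantom_spec()].
#' @return Analytic water-equivalent diameter in cm.
#' @export
analytic_dw <- function(spec) {
  roi <- analytic_roi(spec)
  water_equivalent_diameter(roi$mean_ct, roi$area)
}

#' Closed-form corrected AP and LAT dimensions of a phantom
#'
#' Intersects the central AP chord (x = 0) and LAT chord (y = centroid of
#' the body, i.e. y = 0) with each region exactly and applies the relative
#' electron density weights. Tangencies (a chord grazing a region boundary)
#' are rejected as ambiguous.
#'
#' @param spec A [phantom_spec()].
#' @param densities An [electron_density_table()].
#' @return A list with `ap_corr`, `lat_corr` (cm) and the exact `ap_runs`,
#'   `lat_runs` tables.
#' @export
analytic_corrected_dims <- function(spec, densities = electron_density_table()) {
  chord_half <- function(c_perp, semi_perp, semi_along) {
    # half-width of an ellipse cut by a line offset c_perp from its centre
    u <- c_perp / semi_perp
    if (abs(abs(u) - 1) < 1e-9) stop("chord is tangent to a region boundary")
    if (abs(u) >= 1) return(0)
    semi_along * sqrt(1 - u^2)
  }
  # LAT chord: y = 0 across the body
  lat_half <- spec$body_a_lat
  lung_half <- if (spec$lung_a > 0) {
    chord_half(-spec$lung_center_y, spec$lung_b, spec$lung_a)
  } else 0
  bone_on_lat <- if (spec$bone_radius > 0) {
    chord_half(spec$bone_center_y, spec$bone_radius, spec$bone_radius)
  } else 0
  if (bone_on_lat > 0) stop("bone crossing the LAT chord is not supported analytically")
  if (lung_half > 0 &&
      (spec$lung_center_x - lung_half <= 0 ||
       spec$lung_center_x + lung_half >= lat_half)) {
    stop("lung chord intersections are ambiguous on the LAT chord")
  }
  if (lung_half > 0) {
    t_outer <- lat_half - (spec$lung_center_x + lung_half)
    t_inner <- 2 * (spec$lung_center_x - lung_half)
    lat_runs <- segment_runs(
      c("tissue", "lung", "tissue", "lung", "tissue"),
      c(t_outer, 2 * lung_half, t_inner, 2 * lung_half, t_outer))
  } else {
    lat_runs <- segment_runs("tissue", 2 * lat_half)
  }
  # AP chord: x = 0 across the body
  ap_half <- spec$body_b_ap
  lung_on_ap <- if (spec$lung_a > 0) {
    chord_half(spec$lung_center_x, spec$lung_a, spec$lung_b)
  } else 0
  if (lung_on_ap > 0) stop("lungs crossing the AP chord are not supported analytically")
  bone_half <- spec$bone_radius   # disc centred on x = 0
  if (bone_half > 0) {
    if (spec$bone_center_y - bone_half <= -ap_half ||
        spec$bone_center_y + bone_half >= ap_half) {
      stop("bone chord intersections are ambiguous on the AP chord")
    }
    ap_runs <- segment_runs(
      c("tissue", "bone", "tissue"),
      c(ap_half + (spec$bone_center_y - bone_half), 2 * bone_half,
        ap_half - (spec$bone_center_y + bone_half)))
  } else {
    ap_runs <- segment_runs("tissue", 2 * ap_half)
  }
  list(
    ap_corr = corrected_dimension(ap_runs, densities),
    lat_corr = corrected_dimension(lat_runs, densities),
    ap_runs = ap_runs, lat_runs = lat_runs
  )
}

#' Generate a reproducible cohort of phantoms
#'
#' Samples phantom geometries whose analytic corrected effective diameters
#' are uniform over `d_eff_range`. Body aspect ratio and the relative sizes
#' of lungs and bone are drawn from narrow anatomical ranges; because every
#' region scales with the body semi-axes, the body scale that hits the
#' target diameter is solved exactly.
#'
#' @param n Number of phantoms (>= 1).
#' @param d_eff_range Range of corrected effective diameters (cm); the
#'   default spans typical adult thoraces.
#' @param aspect_range Range of AP/LAT body aspect ratios.
#' @param lung_a_frac_range,lung_b_frac_range Lung semi-axes as fractions of
#'   the body semi-axes.
#' @param bone_frac_range Bone radius as a fraction of the AP body semi-axis.
#' @param ctdi_range CTDIvol range (mGy), sampled uniformly per phantom.
#' @param n_pix Raster size (pixels).
#' @param pixel_spacing Pixel spacing in mm.
#' @param noise_sd Gaussian HU noise sd applied to every phantom.
#' @param seed Integer seed; the cohort is reproducible given the seed.
#' @return A list of class `phantom_cohort`: elements with `spec`, `slice`,
#'   `truth`.
#' @export
generate_cohort <- function(n,
                            d_eff_range = c(15.9, 26.7),
                            aspect_range = c(0.60, 0.75),
                            lung_a_frac_range = c(0.24, 0.32),
                            lung_b_frac_range = c(0.50, 0.60),
                            bone_frac_range = c(0.12, 0.18),
                            ctdi_range = c(4.2, 10.5),
                            n_pix = 512L,
                            pixel_spacing = c(1, 1),
                            noise_sd = 20,
                            seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  ranges <- list(d_eff_range, aspect_range, lung_a_frac_range,
                 lung_b_frac_range, bone_frac_range, ctdi_range)
  if (any(vapply(ranges, function(r) {
    length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] || r[1] <= 0
  }, logical(1)))) {
    stop("invalid parameter ranges")
  }
  set.seed(as.integer(seed))
  runif2 <- function(r) stats::runif(1, r[1], r[2])
  out <- vector("list", n)
  for (k in seq_len(n)) {
    aspect <- runif2(aspect_range)
    laf <- runif2(lung_a_frac_range)
    lbf <- runif2(lung_b_frac_range)
    bf <- runif2(bone_frac_range)
    d_target <- runif2(d_eff_range)
    # unit-scale phantom: every dimension proportional to body_a_lat
    unit <- phantom_spec(body_a_lat = 1, body_b_ap = aspect,
                         lung_a = laf, lung_b = lbf * aspect,
                         lung_center_x = 0.45, lung_center_y = 0,
                         bone_center_y = 0.55 * aspect,
                         bone_radius = bf * aspect,
                         n_pix = 64L, pixel_spacing = 0.5)
    ud <- analytic_corrected_dims(unit)
    a_lat <- d_target / corrected_effective_diameter(ud$ap_corr, ud$lat_corr)
    spec <- phantom_spec(
      body_a_lat = a_lat, body_b_ap = aspect * a_lat,
      lung_a = laf * a_lat, lung_b = lbf * aspect * a_lat,
      lung_center_x = 0.45 * a_lat, lung_center_y = 0,
      bone_center_y = 0.55 * aspect * a_lat, bone_radius = bf * aspect * a_lat,
      pixel_spacing = pixel_spacing, n_pix = n_pix,
      ctdi_vol = runif2(ctdi_range), noise_sd = noise_sd,
      id = sprintf("phantom_%03d", k))
    ph <- generate_phantom(spec, seed = sample.int(.Machine$integer.max, 1))
    out[[k]] <- list(spec = spec, slice = ph$slice, truth = ph$truth)
  }
  structure(out, class = "phantom_cohort")
}

#' Save a cohort as plain-text fixtures
#'
#' Writes each phantom as a CSV Hounsfield raster plus a JSON sidecar
#' (pixel spacing, CTDIvol, identifier, analytic truths), the package's
#' portable fixture dialect.
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of fixture stems written.
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stems <- character(length(cohort))
  for (k in seq_along(cohort)) {
    el <- cohort[[k]]
    stem <- file.path(dir, el$slice$id)
    truth <- el$truth
    write_fixture(el$slice, stem, extra = list(
      truth = list(
        d_w = truth$d_w, ap_corr = truth$ap_corr, lat_corr = truth$lat_corr,
        d_eff_corr = truth$d_eff_corr, mean_ct = truth$mean_ct,
        area = truth$area
      ),
      truth_labels_csv = basename(paste0(stem, "_labels.csv"))
    ))
    utils::write.table(truth$class_map$labels,
                       paste0(stem, "_labels.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    stems[k] <- stem
  }
  invisible(stems)
}

#' Load a cohort saved with [save_cohort()]
#'
#' @param dir Directory of fixture pairs.
#' @return A list of elements with `slice`, and `truth` when the sidecar
#'   carries truth values (class map included when the label raster was
#'   saved).
#' @export
load_cohort <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (length(sidecars) == 0) stop("no fixtures found in ", dir)
  lapply(sidecars, function(sc) {
    stem <- sub("\\.json$", "", sc)
    slice <- load_fixture(stem)
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    truth <- NULL
    if (!is.null(meta$truth)) {
      truth <- meta$truth
      if (!is.null(meta$truth_labels_csv)) {
        lab <- as.matrix(utils::read.table(
          file.path(dir, meta$truth_labels_csv), sep = ",", header = FALSE))
        dimnames(lab) <- NULL
        truth$class_map <- tissue_class_map(lab, slice$pixel_spacing)
      }
    }
    list(slice = slice, truth = truth)
  })
}
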
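test_that("body mask extraction fills holes and drops disconnected fragments", {
  # solid tissue ellipse passes through unchanged
  ell <- ellipse_mask(120, 160, 40, 60)
  lab <- matrix(0L, 120, 160)
  lab[ell] <- 2L
  cm <- tissue_class_map(lab, 1)
  expect_identical(extract_body_mask(cm), ell)

  # internal lung/bone labels are absorbed into one solid body
  lab2 <- lab
  lab2[ellipse_mask(120, 160, 15, 20, center = c(60, 60))] <- 1L
  lab2[ellipse_mask(120, 160, 5, 5, center = c(80, 80))] <- 3L
  expect_identical(extract_body_mask(tissue_class_map(lab2, 1)), ell)

  # internal air (label 0) is hole-filled
  lab3 <- lab
  lab3[ellipse_mask(120, 160, 8, 8, center = c(60, 80))] <- 0L
  expect_identical(extract_body_mask(tissue_class_map(lab3, 1)), ell)

  # a small disconnected couch blob is removed (areas compared brute force)
  lab4 <- lab
  blob <- ellipse_mask(120, 160, 6, 10, center = c(110, 80))
  expect_true(sum(blob) < sum(ell))
  lab4[blob] <- 2L
  expect_identical(extract_body_mask(tissue_class_map(lab4, 1)), ell)

  expect_error(extract_body_mask(tissue_class_map(matrix(0L, 4, 4), 1)),
               "empty segmentation")
})

test_that("body axes recover ellipse chords, with image-axis tie-break", {
  # axis-aligned ellipse: 100 px AP semi-axis, 150 px LAT semi-axis
  m <- ellipse_mask(260, 340, 100, 150)
  g <- body_axes(m, c(1, 1))
  expect_equal(g$lat_line$length_mm, 300, tolerance = 1)
  expect_equal(g$ap_line$length_mm, 200, tolerance = 1)
  # LAT runs along columns, AP along rows
  expect_lt(abs(g$lat_line$start[1] - g$lat_line$end[1]), 1e-6)
  expect_lt(abs(g$ap_line$start[2] - g$ap_line$end[2]), 1e-6)

  # circle: tie resolves to image axes, both chords the diameter
  mc <- ellipse_mask(220, 220, 90, 90)
  gc <- body_axes(mc, c(1, 1))
  expect_equal(gc$lat_line$length_mm, 180, tolerance = 1)
  expect_equal(gc$ap_line$length_mm, 180, tolerance = 1)

  # rotated ellipse: chords follow the principal directions
  th <- 30 * pi / 180
  nr <- 360; nc <- 360
  r <- matrix(seq_len(nr), nr, nc) - (nr + 1) / 2
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - (nc + 1) / 2
  u <- c_ * cos(th) + r * sin(th)
  v <- -c_ * sin(th) + r * cos(th)
  mr <- (u / 150)^2 + (v / 90)^2 <= 1
  gr <- body_axes(mr, c(1, 1))
  expect_equal(gr$lat_line$length_mm, 300, tolerance = 2)
  expect_equal(gr$ap_line$length_mm, 180, tolerance = 2)
  dlat <- gr$lat_line$end - gr$lat_line$start
  ang <- atan2(dlat[1], dlat[2])    # (row, col) -> angle from image horizontal
  expect_equal(abs(ang) %% pi, th, tolerance = 0.03)

  # anisotropic pixels: physical lengths are preserved
  ga <- body_axes(ellipse_mask(260, 340, 100, 150), c(2, 1))
  expect_equal(ga$ap_line$length_mm, 400, tolerance = 2)
  expect_equal(ga$lat_line$length_mm, 300, tolerance = 1)
})

test_that("tissue runs along a chord are merged, ordered and scaled", {
  # rectangle body, one row carries tissue|lung|bone|lung|tissue segments
  nr <- 51; nc <- 260
  lab <- matrix(0L, nr, nc)
  lab[6:(nr - 5), 16:245] <- 2L                 # 230 px wide body
  mid <- 26L
  lab[mid, 36:115] <- 1L                        # lung 8 cm
  lab[mid, 116:145] <- 3L                       # bone 3 cm
  lab[mid, 146:225] <- 1L                       # lung 8 cm
  cm <- tissue_class_map(lab, 1)
  line <- list(start = c(mid, 16), end = c(mid, 245), length_mm = 229)
  runs <- scan_tissue_runs(cm, line)
  expect_equal(runs$tissue_class, c("tissue", "lung", "bone", "lung", "tissue"))
  expect_equal(runs$length_cm, c(2, 8, 3, 8, 2), tolerance = 0.12)
  # chord conservation: run lengths sum to the geometric chord length
  expect_equal(sum(runs$length_cm), 22.9, tolerance = 0.1)

  # uniform tissue chord at anisotropic spacing: 10 px at 0.7 mm/px
  lab2 <- matrix(2L, 21, 12)
  cm2 <- tissue_class_map(lab2, c(1, 0.7))
  line2 <- list(start = c(11, 1), end = c(11, 10), length_mm = 9 * 0.7)
  runs2 <- scan_tissue_runs(cm2, line2)
  expect_equal(runs2$tissue_class, "tissue")
  expect_equal(runs2$length_cm, 0.63, tolerance = 1e-9)

  # internal air is scored as lung
  lab3 <- lab
  lab3[mid, 120:130] <- 0L
  runs3 <- scan_tissue_runs(tissue_class_map(lab3, 1), line)
  expect_true("lung" %in% runs3$tissue_class)
  expect_equal(sum(runs3$length_cm), 22.9, tolerance = 0.1)
})

test_that("corrected dimensions compose and respect density bounds", {
  ph <- small_phantom()
  meas <- measure_corrected_dimensions(ph$truth$class_map)
  expect_equal(meas$ap_corr, ph$truth$ap_corr, tolerance = 0.02)
  expect_equal(meas$lat_corr, ph$truth$lat_corr, tolerance = 0.02)
  # lung-containing LAT chord is shorter than geometric; bone-only AP longer
  lat_geom <- meas$geometry$lat_line$length_mm / 10
  ap_geom <- meas$geometry$ap_line$length_mm / 10
  expect_lt(meas$lat_corr, lat_geom)
  expect_gt(meas$ap_corr, ap_geom)

  # all-tissue ellipse: corrected equals geometric (rho_e = 1 limit)
  lab <- matrix(0L, 240, 340)
  lab[ellipse_mask(240, 340, 100, 150)] <- 2L
  meas2 <- measure_corrected_dimensions(tissue_class_map(lab, 1))
  expect_equal(meas2$ap_corr, 20, tolerance = 0.1)
  expect_equal(meas2$lat_corr, 30, tolerance = 0.1)
})

test_that("rotating the raster by 90 degrees swaps AP and LAT", {
  ph <- small_phantom()
  cm <- ph$truth$class_map
  m1 <- measure_corrected_dimensions(cm)
  cm_rot <- tissue_class_map(rot90(cm$labels), rev(cm$pixel_spacing))
  m2 <- measure_corrected_dimensions(cm_rot)
  # swap holds to the sampling resolution (one pixel)
  px_cm <- max(cm$pixel_spacing) / 10
  expect_equal(m2$ap_corr, m1$lat_corr, tolerance = px_cm)
  expect_equal(m2$lat_corr, m1$ap_corr, tolerance = px_cm)
})

test_that("ROI statistics give mean HU and physical area", {
  hu <- matrix(-1000, 100, 100)
  disc <- ellipse_mask(100, 100, 17.8, 17.8)
  hu[disc] <- 0
  n_disc <- sum(disc)
  rs <- roi_stats(hu, disc, c(1, 1))
  expect_equal(rs$mean_ct, 0)
  expect_equal(rs$area, n_disc * 0.01, tolerance = 1e-12)

  # half air / half water mask
  hu2 <- matrix(0, 10, 10)
  hu2[, 1:5] <- -1000
  rs2 <- roi_stats(hu2, matrix(TRUE, 10, 10), c(2, 2))
  expect_equal(rs2$mean_ct, -500)
  expect_equal(rs2$area, 100 * 0.04)
  expect_error(roi_stats(hu2, matrix(FALSE, 10, 10), 1), "empty body mask")

  # phantom body mean HU matches the area-weighted analytic mean within 1%
  ph <- small_phantom()
  mask <- extract_body_mask(ph$truth$class_map)
  rs3 <- roi_stats(ph$slice$hu_pixels, mask, ph$slice$pixel_spacing)
  expect_equal(rs3$mean_ct, ph$truth$mean_ct,
               tolerance = 0.01 * abs(ph$truth$mean_ct))
  expect_equal(rs3$area, ph$truth$area, tolerance = 0.01 * ph$truth$area)
})

test_that("water-only phantom recovers its geometric effective diameter", {
  ph <- generate_phantom(water_disc_spec(r = 10))
  mask <- extract_body_mask(threshold_segment(ph$slice))
  rs <- roi_stats(ph$slice$hu_pixels, mask, ph$slice$pixel_spacing)
  dw <- water_equivalent_diameter(rs$mean_ct, rs$area)
  expect_equal(dw, 20, tolerance = 0.2)  # within 1%
})
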
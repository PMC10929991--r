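test_that("analytic truths match hand-evaluated closed forms", {
  # all-water disc: D_w and D_eff both equal the geometric diameter
  ws <- water_disc_spec(r = 10)
  expect_equal(analytic_dw(ws), 20)
  d <- analytic_corrected_dims(ws)
  expect_equal(corrected_effective_diameter(d$ap_corr, d$lat_corr), 20)

  # body (15,10) all tissue: ap 20, lat 30, d_eff sqrt(600)
  ts <- phantom_spec(body_a_lat = 15, body_b_ap = 10, lung_a = 0, lung_b = 0,
                     bone_radius = 0)
  dt <- analytic_corrected_dims(ts)
  expect_equal(dt$ap_corr, 20)
  expect_equal(dt$lat_corr, 30)
  expect_equal(corrected_effective_diameter(dt$ap_corr, dt$lat_corr),
               sqrt(600))

  # body (15,10) with two (6,4) lungs at -700 HU, no bone:
  # mean HU = -700 * 2*pi*24 / (pi*150) = -224; d_w = 2*sqrt(0.776*150)
  ls <- phantom_spec(body_a_lat = 15, body_b_ap = 10,
                     lung_center_x = 7, lung_center_y = 0,
                     lung_a = 6, lung_b = 4, bone_radius = 0)
  expect_equal(analytic_dw(ls), 2 * sqrt((1 - 224 / 1000) * 150))

  # lung chords on the LAT line: lat_corr = (30 - 24) + 0.3 * 24
  dl <- analytic_corrected_dims(ls)
  expect_equal(dl$lat_corr, 6 + 0.3 * 24)
  expect_equal(dl$ap_corr, 20)

  # bone disc of diameter 3 cm on a 20 cm AP chord: 17 + 1.2 * 3
  bs <- phantom_spec(body_a_lat = 15, body_b_ap = 10, lung_a = 0, lung_b = 0,
                     bone_center_y = 3, bone_radius = 1.5)
  db <- analytic_corrected_dims(bs)
  expect_equal(db$ap_corr, 17 + 1.2 * 3)
})

test_that("phantom truth is internally consistent", {
  ph <- small_phantom()
  tr <- ph$truth
  expect_equal(tr$d_eff_corr, sqrt(tr$ap_corr * tr$lat_corr),
               tolerance = 1e-9)
  expect_equal(tr$d_w, water_equivalent_diameter(tr$mean_ct, tr$area),
               tolerance = 1e-9)
})

test_that("rasterisation converges to the analytic body area", {
  spec <- phantom_spec()       # 30 x 20 cm body at 1 mm pixels
  ph <- generate_phantom(spec)
  raster_area <- sum(ph$truth$class_map$labels > 0) *
    prod(spec$pixel_spacing) / 100
  expect_equal(raster_area, pi * 15 * 10,
               tolerance = 0.02 * pi * 15 * 10)
})

test_that("generation is reproducible and noise is seeded", {
  spec <- phantom_spec(n_pix = 128L, pixel_spacing = 3, noise_sd = 20)
  a <- generate_phantom(spec, seed = 42)
  b <- generate_phantom(spec, seed = 42)
  expect_identical(a$slice$hu_pixels, b$slice$hu_pixels)
  c_ <- generate_phantom(spec, seed = 43)
  expect_false(identical(a$slice$hu_pixels, c_$slice$hu_pixels))
  # noiseless raster carries exactly the configured HU values
  d <- generate_phantom(phantom_spec(n_pix = 128L, pixel_spacing = 3))
  expect_true(all(d$slice$hu_pixels %in% c(-1000, -700, 0, 300)))
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_spec(lung_center_x = 14, lung_a = 6),
               "inside the body")
  expect_error(phantom_spec(bone_center_y = 9.5, bone_radius = 2),
               "inside the body")
  expect_error(phantom_spec(body_a_lat = 25, n_pix = 128L,
                            pixel_spacing = 1),
               "field of view")
})

test_that("cohorts hit the requested diameter range reproducibly", {
  coh <- generate_cohort(20, n_pix = 128L, pixel_spacing = 4, noise_sd = 0,
                         seed = 3)
  d <- vapply(coh, function(x) x$truth$d_eff_corr, numeric(1))
  expect_true(all(d >= 15.9 & d <= 26.7))
  expect_equal(length(unique(round(d, 6))), 20)  # distinct geometries
  coh2 <- generate_cohort(20, n_pix = 128L, pixel_spacing = 4, noise_sd = 0,
                          seed = 3)
  expect_identical(coh2[[7]]$slice$hu_pixels, coh[[7]]$slice$hu_pixels)
  # collapsed range gives n identical diameters
  coh3 <- generate_cohort(4, d_eff_range = c(20, 20), n_pix = 128L,
                          pixel_spacing = 4, noise_sd = 0, seed = 1)
  d3 <- vapply(coh3, function(x) x$truth$d_eff_corr, numeric(1))
  expect_equal(d3, rep(20, 4), tolerance = 1e-9)
  expect_error(generate_cohort(5, d_eff_range = c(26, 16)),
               "invalid parameter ranges")
})

test_that("cohorts round-trip through the fixture format", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(3, n_pix = 96L, pixel_spacing = 5, noise_sd = 0,
                         seed = 2)
  save_cohort(coh, dir)
  back <- load_cohort(dir)
  expect_length(back, 3)
  ids <- vapply(back, function(x) x$slice$id, character(1))
  k <- match(coh[[1]]$slice$id, ids)
  expect_equal(back[[k]]$slice$hu_pixels, coh[[1]]$slice$hu_pixels)
  expect_equal(back[[k]]$truth$d_w, coh[[1]]$truth$d_w, tolerance = 1e-12)
  expect_identical(back[[k]]$truth$class_map$labels,
                   coh[[1]]$truth$class_map$labels)
})
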
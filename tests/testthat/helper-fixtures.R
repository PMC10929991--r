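# Shared fixture builders; everything is generated in code at test time.

# small default thorax phantom (30 x 20 cm body), noiseless
small_phantom <- function(noise_sd = 0, seed = NULL, n_pix = 256L,
                          pixel_spacing = 1.5) {
  spec <- phantom_spec(n_pix = n_pix, pixel_spacing = pixel_spacing,
                       noise_sd = noise_sd)
  generate_phantom(spec, seed = seed)
}

# uniform water disc phantom of radius r cm (no lungs, no bone)
water_disc_spec <- function(r = 10, n_pix = 256L, pixel_spacing = 1,
                            ctdi_vol = 8.5) {
  phantom_spec(body_a_lat = r, body_b_ap = r,
               lung_a = 0, lung_b = 0, bone_radius = 0,
               n_pix = n_pix, pixel_spacing = pixel_spacing,
               ctdi_vol = ctdi_vol)
}

# filled ellipse mask (logical) on an nr x nc raster, semi-axes in pixels
ellipse_mask <- function(nr, nc, ra, rc, center = c((nr + 1) / 2, (nc + 1) / 2)) {
  r <- matrix(seq_len(nr), nr, nc)
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((r - center[1]) / ra)^2 + ((c_ - center[2]) / rc)^2 <= 1
}

# rotate a matrix 90 degrees counter-clockwise
rot90 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

# tiny training cohort at low resolution for network tests
tiny_cohort <- function(n = 12, n_pix = 64L, seed = 5) {
  generate_cohort(n, n_pix = n_pix, pixel_spacing = 8, noise_sd = 0,
                  seed = seed)
}
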
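ref_1000_50 <- function() build_reference_stats(c(950, 1000, 1050), test_key())

test_that("the pixel-wise Z transform follows (T1 - mean)/SD", {
  ref <- ref_1000_50()
  zm <- compute_z_map(t1_map(matrix(1075, 1, 1), platform = ref$key), ref)
  expect_equal(zm$pixels[1, 1], 1.5)

  flat <- compute_z_map(t1_map(matrix(1000, 3, 3), platform = ref$key), ref)
  expect_true(all(flat$pixels == 0))

  # at the lower bound of the outlier-SD normal range: (806 - 1000)/97 = -2
  wide <- structure(list(key = test_key(), mean = 1000, sd = 97,
                         n_subjects = 15, roi_descriptor = "r", usable = TRUE),
                    class = "t1z_ref")
  zw <- compute_z_map(t1_map(matrix(806, 1, 1), platform = ref$key), wide)
  expect_equal(zw$pixels[1, 1], -2)

  # invalid pixels propagate as NA, and the reference snapshot is embedded
  m <- t1_map(matrix(c(1075, 0), 1, 2), platform = ref$key,
              validity_mask = matrix(c(TRUE, FALSE), 1, 2))
  z2 <- compute_z_map(m, ref)
  expect_true(is.na(z2$pixels[1, 2]))
  expect_equal(z2$ref$mean, 1000)
})

test_that("unusable references and key mismatches are rejected", {
  flat <- suppressWarnings(build_reference_stats(c(1000, 1000), test_key()))
  m <- t1_map(matrix(1000, 1, 1), platform = test_key())
  expect_error(compute_z_map(m, flat), "SD is 0")

  other <- build_reference_stats(c(1100, 1150, 1200), test_key(3.0))
  expect_error(compute_z_map(m, other), "mismatch")
  expect_warning(zo <- compute_z_map(m, other, override_key_mismatch = TRUE),
                 "overridden")
  expect_equal(zo$pixels[1, 1], (1000 - 1150) / sd(c(1100, 1150, 1200)))
})

test_that("quantization is x100, half away from zero, sentinel for background", {
  ref <- ref_1000_50()
  m <- t1_map(matrix(c(1075, 1000, 864.25, 0), 2, 2), platform = ref$key,
              validity_mask = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  st <- quantize_z_map(compute_z_map(m, ref))
  expect_identical(st$pixels[1, 1], 150L)  # Z 1.5 presented as 150
  expect_identical(st$pixels[2, 1], 0L)
  expect_identical(st$pixels[1, 2], -272L) # Z -2.715 -> -271.5 -> away from 0
  expect_identical(st$pixels[2, 2], -32768L)
  expect_identical(st$scale_factor, 100L)

  # extreme Z clamps to the signed 16-bit payload with a warning
  big <- t1_map(matrix(1e6, 1, 1), platform = ref$key)
  expect_warning(stb <- quantize_z_map(compute_z_map(big, ref)), "clamped")
  expect_identical(stb$pixels[1, 1], 32767L)
})

test_that("dequantization inverts storage within 0.005 Z units", {
  ref <- ref_1000_50()
  m <- t1_map(matrix(c(1075, 0), 1, 2), platform = ref$key,
              validity_mask = matrix(c(TRUE, FALSE), 1, 2))
  st <- quantize_z_map(compute_z_map(m, ref))
  zback <- dequantize(st)
  expect_equal(zback$pixels[1, 1], 1.5)
  expect_true(is.na(zback$pixels[1, 2]))

  # idempotence on integers: quantize . dequantize . quantize = quantize
  expect_identical(quantize_z_map(dequantize(st))$pixels, st$pixels)

  # random sweep of the round-trip error bound
  set.seed(99)
  z <- runif(1e6, -10, 10)
  zq <- sign(z) * floor(abs(z * 100) + 0.5) / 100
  expect_lte(max(abs(zq - z)), 0.005 + 1e-12)
  zmap <- structure(list(pixels = matrix(z[1:1e4], 100, 100),
                         source_key = ref$key, ref = ref, subject_id = "r",
                         pixel_spacing = 1), class = "t1z_zmap")
  rt <- dequantize(quantize_z_map(zmap))
  expect_lte(max(abs(rt$pixels - zmap$pixels)), 0.005 + 1e-12)

  bad <- quantize_z_map(compute_z_map(m, ref))
  bad$background_sentinel <- -999L
  expect_error(dequantize(bad), "sentinel")
})

test_that("ROI mean Z equals the normalized ROI mean T1 exactly", {
  prof <- test_profile()
  geom <- phantom_geometry(64)
  s <- generate_subject_map(prof, geom, subject_truth("s", 990, seed = 31))
  mask <- septal_core_mask(s$contours, 64, geom)
  ref <- build_reference_stats(c(950, 1000, 1050), prof$key)
  z <- compute_z_map(s$map, ref)

  got <- mean_roi_z(z, mask)$mean
  want <- (roi_statistics(s$map, mask)$mean - ref$mean) / ref$sd
  expect_equal(got, want, tolerance = 1e-12)

  # a subject at exactly mean + 2 SD has mean Z = 2 by linearity
  flat <- t1_map(matrix(ref$mean + 2 * ref$sd, 64, 64), platform = prof$key)
  expect_equal(mean_roi_z(compute_z_map(flat, ref), mask)$mean, 2)

  zero <- t1_map(matrix(ref$mean, 64, 64), platform = prof$key)
  expect_equal(mean_roi_z(compute_z_map(zero, ref), mask)$mean, 0)
})

test_that("the Z map is invariant under affine rescaling of T1 and reference", {
  prof <- test_profile()
  s <- generate_subject_map(prof, phantom_geometry(64),
                            subject_truth("s", 1010, seed = 13))
  ref <- build_reference_stats(c(950, 1000, 1050), prof$key)
  z1 <- compute_z_map(s$map, ref)

  a <- 2.5; b <- 100
  m2 <- t1_map(a * s$map$pixels + b, platform = prof$key,
               validity_mask = s$map$validity_mask)
  ref2 <- build_reference_stats(a * c(950, 1000, 1050) + b, prof$key)
  z2 <- compute_z_map(m2, ref2)
  expect_equal(z2$pixels, z1$pixels, tolerance = 1e-12)
})

test_that("self-referenced cohorts have mean Z = 0 and SD 1", {
  prof <- test_profile()
  geom <- phantom_geometry(64)
  coh <- generate_cohort(prof, geom, 10, master_seed = 17)
  mask <- septal_core_mask(coh[[1]]$contours, 64, geom)
  means <- purrr::map_dbl(coh, ~ roi_statistics(.x$map, mask)$mean)
  ref <- build_reference_stats(means, prof$key)
  z <- purrr::map_dbl(coh, function(s) {
    mean_roi_z(compute_z_map(s$map, ref), mask)$mean
  })
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("rendering anchors Z = 0 at the center color and saturates at clip", {
  pal <- diverging_palette()
  ref <- ref_1000_50()
  mk_z <- function(px, valid = NULL) {
    if (is.null(valid)) valid <- matrix(TRUE, nrow(px), ncol(px))
    m <- t1_map(ref$mean + px * ref$sd, platform = ref$key,
                validity_mask = valid)
    compute_z_map(m, ref)
  }
  z <- mk_z(matrix(c(0, 5, 10, -7), 2, 2))
  img <- render_z_map(z, pal, clip = 5)
  center_rgb <- as.numeric(grDevices::col2rgb("#F7F7F7")) / 255
  expect_equal(as.numeric(img[1, 1, ]), center_rgb)
  expect_equal(img[2, 1, ], img[1, 2, ])  # Z=5 and Z=10 both saturate
  expect_equal(as.numeric(img[2, 2, ]),
               as.numeric(grDevices::col2rgb("#053061")) / 255)

  # invalid pixels render neutral gray
  zi <- mk_z(matrix(0, 1, 2), matrix(c(TRUE, FALSE), 1, 2))
  imgi <- render_z_map(zi, pal)
  expect_equal(as.numeric(imgi[1, 2, ]),
               as.numeric(grDevices::col2rgb("#808080")) / 255)

  # mirrored maps render as color-mirrored images
  set.seed(3)
  zr <- mk_z(matrix(runif(64, -4.9, 4.9), 8, 8))
  zneg <- zr; zneg$pixels <- -zr$pixels
  pal_rev <- diverging_palette(colors = rev(pal$colors))
  expect_equal(render_z_map(zneg, pal), render_z_map(zr, pal_rev))

  expect_error(diverging_palette(breakpoints = c(-2, -1, 0.5),
                                 colors = c("#000000", "#111111", "#222222",
                                            "#333333")),
               "symmetric")
  expect_error(diverging_palette(colors = c("#000000")), "one more")
})
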
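# Shared fixtures: a canonical concentric-annulus geometry and low-friction
# profile/contour constructors. Everything is generated in code.

default_center <- function(grid = 128L) rep((grid - 1) / 2, 2)

annulus_contours <- function(grid = 128L, r_endo = 20, r_epi = 30,
                             n_vertices = 256L) {
  c0 <- default_center(grid)
  contour_pair(circle_polygon(c0, r_endo, n_vertices),
               circle_polygon(c0, r_epi, n_vertices))
}

test_key <- function(fs = 1.5) platform_key(fs, "VendorT", "TestSys", "MOLLI 5s(3s)3s")

test_profile <- function(myo_mean = 1000, between_sd = 30, noise_sd = 20,
                         blood_sd = 30, fs = 1.5) {
  platform_profile(test_key(fs), myo_mean = myo_mean,
                   myo_between_subject_sd = between_sd,
                   myo_within_subject_noise_sd = noise_sd,
                   blood_noise_sd = blood_sd)
}

# Radii of in-mask pixels about the annulus center (0-based coordinates).
mask_radii <- function(mask, center) {
  idx <- which(mask$grid)
  nr <- nrow(mask$grid)
  sqrt(((idx - 1) %% nr - center[[1]])^2 +
         ((idx - 1) %/% nr - center[[2]])^2)
}
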
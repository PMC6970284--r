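#' Platform key for a hardware/software combination
#'
#' Native myocardial T1 depends on field strength, scanner vendor and model,
#' and the MOLLI sampling scheme; reference statistics are therefore keyed by
#' the full tuple and two keys are equal only when every field matches exactly.
#'
#' @param field_strength Main magnet strength in tesla; 1.5 or 3.0.
#' @param vendor Scanner manufacturer label.
#' @param system Scanner model label.
#' @param scheme MOLLI variant label, e.g. `"MOLLI 5s(3s)3s"`.
#' @return A `t1z_platform_key` object.
#' @examples
#' platform_key(1.5, "VendorA", "SystemX", "MOLLI 5s(3s)3s")
#' @export
platform_key <- function(field_strength, vendor, system, scheme) {
  if (!field_strength %in% c(1.5, 3.0)) {
    abort("`field_strength` must be 1.5 or 3.0 (tesla).")
  }
  labels <- c(vendor, system, scheme)
  if (any(!nzchar(labels)) || anyNA(labels)) {
    abort("`vendor`, `system` and `scheme` must be non-empty labels.")
  }
  structure(
    list(field_strength = as.numeric(field_strength),
         vendor = as.character(vendor),
         system = as.character(system),
         scheme = as.character(scheme)),
    class = "t1z_platform_key"
  )
}

#' @export
format.t1z_platform_key <- function(x, ...) {
  sprintf("%gT | %s | %s | %s", x$field_strength, x$vendor, x$system, x$scheme)
}

#' @export
print.t1z_platform_key <- function(x, ...) {
  cat("<platform key>", format(x), "\n")
  invisible(x)
}

# Canonical string form used as a database key.
key_label <- function(key) {
  paste(format(key$field_strength), key$vendor, key$system, key$scheme,
        sep = "|")
}

same_key <- function(a, b) identical(key_label(a), key_label(b))

#' Platform acquisition profile for the synthetic phantom
#'
#' Encodes what a hardware/software combination does to healthy septal T1:
#' the cohort-level mean, the between-subject SD of per-subject septal means
#' (the quantity reference ranges are built from), the within-subject pixel
#' noise, and blood-pool values for the cavity.
#'
#' @param key A [platform_key()].
#' @param myo_mean Healthy septal myocardial mean T1 (ms).
#' @param myo_between_subject_sd Between-subject SD of septal mean T1 (ms).
#' @param myo_within_subject_noise_sd Pixel-level noise SD within one map (ms).
#' @param blood_mean Blood-pool mean T1 (ms); must exceed `myo_mean`.
#' @param blood_noise_sd Blood-pool pixel noise SD (ms).
#' @param background_value Value assigned outside the thorax phantom (ms).
#' @return A `t1z_platform_profile` object.
#' @export
platform_profile <- function(key, myo_mean, myo_between_subject_sd,
                             myo_within_subject_noise_sd = 20,
                             blood_mean = NULL, blood_noise_sd = 30,
                             background_value = 0) {
  stopifnot(inherits(key, "t1z_platform_key"))
  blood_mean <- blood_mean %||% (if (key$field_strength == 1.5) 1600 else 1900)
  sds <- c(myo_between_subject_sd, myo_within_subject_noise_sd, blood_noise_sd)
  if (any(sds < 0)) abort("All SD parameters must be >= 0.")
  if (myo_mean <= 0) abort("`myo_mean` must be positive.")
  if (blood_mean <= myo_mean) {
    abort("`blood_mean` must exceed `myo_mean` (native blood/myocardium contrast).")
  }
  structure(
    list(key = key, myo_mean = myo_mean,
         myo_between_subject_sd = myo_between_subject_sd,
         myo_within_subject_noise_sd = myo_within_subject_noise_sd,
         blood_mean = blood_mean, blood_noise_sd = blood_noise_sd,
         background_value = background_value),
    class = "t1z_platform_profile"
  )
}

#' Built-in platform profiles spanning the published spread of cohort SDs
#'
#' Eleven hardware/scheme combinations: at 1.5 T the between-subject SDs of
#' healthy septal mean T1 lie in 24--33 ms, at 3 T in 44--58 ms, and one 3 T
#' combination is an outlier with SD 97 ms (a MOLLI 3b(3b)5b scheme whose
#' recovery periods are short relative to 3 T myocardial T1). Mean levels are
#' plausible defaults (950 ms at 1.5 T, 1150 ms at 3 T) and are not treated
#' as reference values in themselves.
#'
#' @param as_profiles If `TRUE`, return a named list of
#'   [platform_profile()] objects instead of a tibble.
#' @return A tibble with one row per profile (default), or a named list.
#' @examples
#' builtin_profiles()
#' p <- builtin_profiles(as_profiles = TRUE)[["outlier_3T"]]
#' p$myo_between_subject_sd
#' @export
builtin_profiles <- function(as_profiles = FALSE) {
  tbl <- tibble::tribble(
    ~name,            ~field_strength, ~vendor,   ~system,     ~scheme,              ~myo_mean, ~myo_between_subject_sd,
    "siteA_15T_5s",   1.5, "VendorA", "Aera-like",   "MOLLI 5s(3s)3s",     950, 24,
    "siteA_15T_5b",   1.5, "VendorA", "Aera-like",   "MOLLI 5b(3b)3b",     950, 27,
    "siteB_15T_5s",   1.5, "VendorB", "Achieva-like","MOLLI 5s(3s)3s",     940, 30,
    "siteB_15T_335b", 1.5, "VendorB", "Achieva-like","MOLLI 3b(3b)3b(3b)5b", 945, 33,
    "siteC_15T_5s",   1.5, "VendorA", "Avanto-like", "MOLLI 5s(3s)3s",     955, 28,
    "siteA_3T_5s",    3.0, "VendorA", "Skyra-like",  "MOLLI 5s(3s)3s",    1150, 44,
    "siteA_3T_5b",    3.0, "VendorA", "Skyra-like",  "MOLLI 5b(3b)3b",    1150, 50,
    "siteB_3T_5s",    3.0, "VendorB", "Ingenia-like","MOLLI 5s(3s)3s",    1140, 52,
    "siteB_3T_5b",    3.0, "VendorB", "Ingenia-like","MOLLI 5b(3b)3b",    1140, 58,
    "siteC_3T_5s",    3.0, "VendorA", "Prisma-like", "MOLLI 5s(3s)3s",    1160, 47,
    "outlier_3T",     3.0, "VendorB", "Ingenia-like","MOLLI 3b(3b)3b(3b)5b", 1145, 97
  )
  tbl$blood_mean <- ifelse(tbl$field_strength == 1.5, 1600, 1900)
  tbl$myo_within_subject_noise_sd <- 20
  tbl$blood_noise_sd <- 30
  if (!as_profiles) return(tbl)
  profs <- purrr::pmap(tbl, function(name, field_strength, vendor, system,
                                     scheme, myo_mean, myo_between_subject_sd,
                                     blood_mean, myo_within_subject_noise_sd,
                                     blood_noise_sd) {
    platform_profile(
      platform_key(field_strength, vendor, system, scheme),
      myo_mean = myo_mean,
      myo_between_subject_sd = myo_between_subject_sd,
      myo_within_subject_noise_sd = myo_within_subject_noise_sd,
      blood_mean = blood_mean, blood_noise_sd = blood_noise_sd
    )
  })
  setNames(profs, tbl$name)
}

# Resolve a profile given a profile object or a builtin name.
resolve_profile <- function(profile) {
  if (inherits(profile, "t1z_platform_profile")) return(profile)
  if (is.character(profile) && length(profile) == 1) {
    profs <- builtin_profiles(as_profiles = TRUE)
    if (!profile %in% names(profs)) {
      abort(sprintf("Unknown builtin profile '%s'. See builtin_profiles().",
                    profile))
    }
    return(profs[[profile]])
  }
  abort("`profile` must be a platform_profile or a builtin profile name.")
}

#' Short-axis phantom geometry
#'
#' The phantom is a concentric circular annulus (myocardium) around a disc
#' (LV blood pool) on a square grid; the septum is approximated by an angular
#' sector. Angles are degrees in \[0, 360) measured from the positive column
#' axis towards the positive row axis.
#'
#' @param grid_size Square grid side in pixels.
#' @param center Pixel coordinates `(row, col)` of the LV center (0-based);
#'   defaults to the grid center.
#' @param endo_radius,epi_radius Endo-/epicardial radii in pixels.
#' @param septal_sector Length-2 angle interval in degrees, half-open
#'   `[from, to)`.
#' @return A `t1z_geometry` object.
#' @export
phantom_geometry <- function(grid_size = 128L, center = NULL,
                             endo_radius = 20, epi_radius = 30,
                             septal_sector = c(120, 240)) {
  center <- center %||% rep((grid_size - 1) / 2, 2)
  if (!(endo_radius > 0 && endo_radius < epi_radius &&
        epi_radius < grid_size / 2)) {
    abort("Require 0 < endo_radius < epi_radius < grid_size/2.")
  }
  width <- (septal_sector[[2]] - septal_sector[[1]]) %% 360
  if (width == 0 && septal_sector[[2]] != septal_sector[[1]] + 360) {
    abort("Septal sector width must lie in (0, 360] degrees.")
  }
  structure(
    list(grid_size = as.integer(grid_size), center = as.numeric(center),
         endo_radius = endo_radius, epi_radius = epi_radius,
         septal_sector = as.numeric(septal_sector)),
    class = "t1z_geometry"
  )
}

#' Ground truth for one synthetic subject
#'
#' @param subject_id Subject label.
#' @param true_septal_mean The subject's noise-free septal mean T1 (ms).
#' @param disease_shift Additive global T1 elevation (ms), 0 for healthy.
#' @param seed RNG seed for this subject's pixel noise.
#' @return A `t1z_subject_truth` object.
#' @export
subject_truth <- function(subject_id, true_septal_mean, disease_shift = 0,
                          seed = 1L) {
  if (disease_shift < 0) abort("`disease_shift` must be >= 0.")
  if (true_septal_mean <= 0) abort("`true_septal_mean` must be positive.")
  structure(
    list(subject_id = as.character(subject_id),
         true_septal_mean = true_septal_mean,
         disease_shift = disease_shift, seed = as.integer(seed)),
    class = "t1z_subject_truth"
  )
}

# Draw the per-subject ground truths of one cohort (list of subject_truth).
# Separated from map generation so the pipeline can stream subjects without
# holding every map in memory.
cohort_truths <- function(profile, n_subjects, disease_shift, master_seed,
                          id_prefix = "subj") {
  if (n_subjects < 2) {
    abort("`n_subjects` must be >= 2 (cohort SD is undefined otherwise).")
  }
  set.seed(master_seed)
  true_means <- pmax(rnorm(n_subjects, profile$myo_mean,
                           profile$myo_between_subject_sd), 1)
  purrr::map(seq_len(n_subjects), function(i) {
    subject_truth(sprintf("%s%03d", id_prefix, i), true_means[[i]],
                  disease_shift = disease_shift,
                  seed = subject_seed(master_seed, i))
  })
}

# Deterministic per-subject seed derived from the cohort master seed.
# Linear-congruential style mix; stable across platforms and R versions.
subject_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) %% 2147483647 * 48271 +
                index * 104729) %% 2147483647)
}

#' Generate one synthetic short-axis T1 map with its contours
#'
#' Rasterizes the phantom geometry into background, blood pool and myocardial
#' annulus, then draws pixel values: blood ~ Normal(blood_mean, blood_noise_sd),
#' myocardium ~ Normal(true_septal_mean + disease_shift, within-subject noise),
#' truncated at 0 ms. The returned contours are exactly the circles used for
#' rasterization, so contour copying downstream reproduces the generating
#' masks. Identical inputs give bit-identical output.
#'
#' @param profile A [platform_profile()] or builtin profile name.
#' @param geometry A [phantom_geometry()].
#' @param truth A [subject_truth()].
#' @return A list with elements `map` (a `t1z_map`), `contours`
#'   (a [contour_pair()]) and `truth`.
#' @examples
#' s <- generate_subject_map("siteA_15T_5s", phantom_geometry(64),
#'                           subject_truth("s1", 950, seed = 7))
#' range(s$map$pixels[s$map$validity_mask])
#' @export
generate_subject_map <- function(profile, geometry, truth) {
  profile <- resolve_profile(profile)
  stopifnot(inherits(geometry, "t1z_geometry"),
            inherits(truth, "t1z_subject_truth"))
  n <- geometry$grid_size
  endo <- circle_polygon(geometry$center, geometry$endo_radius)
  epi <- circle_polygon(geometry$center, geometry$epi_radius)
  pts <- pixel_centers(c(n, n))
  in_endo <- points_in_polygon(pts, endo)
  in_epi <- points_in_polygon(pts, epi)
  myo <- in_epi & !in_endo

  pixels <- matrix(profile$background_value, n, n)
  set.seed(truth$seed)
  # Fixed draw order (blood first, then myocardium, matrix-index order within
  # each region) makes output reproducible bit-for-bit.
  pixels[in_endo] <- rnorm(sum(in_endo), profile$blood_mean,
                           profile$blood_noise_sd)
  pixels[myo] <- rnorm(sum(myo), truth$true_septal_mean + truth$disease_shift,
                       profile$myo_within_subject_noise_sd)
  pixels <- pmax(pixels, 0)

  map <- t1_map(pixels, platform = profile$key, subject_id = truth$subject_id,
                validity_mask = matrix(in_endo | myo, n, n))
  list(map = map, contours = contour_pair(endo, epi), truth = truth)
}

#' Generate a synthetic cohort of subjects on one platform
#'
#' Per-subject true septal means are drawn from
#' Normal(`myo_mean`, `myo_between_subject_sd`); each subject then gets an
#' independent map via [generate_subject_map()] with a seed derived
#' deterministically from `master_seed`.
#'
#' @inheritParams generate_subject_map
#' @param n_subjects Number of subjects (>= 2).
#' @param disease_shift Additive T1 elevation applied to every subject (ms).
#' @param master_seed Cohort seed; all randomness derives from it.
#' @param id_prefix Prefix for subject labels.
#' @return A `t1z_cohort`: a list of subject lists (`map`, `contours`,
#'   `truth`) with the generating `profile`, `geometry` and `master_seed`
#'   attached as attributes.
#' @export
generate_cohort <- function(profile, geometry, n_subjects, disease_shift = 0,
                            master_seed = 1L, id_prefix = "subj") {
  profile <- resolve_profile(profile)
  truths <- cohort_truths(profile, n_subjects, disease_shift, master_seed,
                          id_prefix)
  subjects <- purrr::map(truths, generate_subject_map,
                         profile = profile, geometry = geometry)
  structure(subjects, class = "t1z_cohort", profile = profile,
            geometry = geometry, master_seed = master_seed)
}

#' Per-subject ground truth of a cohort as a tibble
#'
#' @param x A `t1z_cohort`.
#' @param ... Unused.
#' @return A tibble with one row per subject.
#' @export
tidy.t1z_cohort <- function(x, ...) {
  purrr::map_dfr(x, function(s) {
    tibble(subject_id = s$truth$subject_id,
           true_septal_mean = s$truth$true_septal_mean,
           disease_shift = s$truth$disease_shift,
           seed = s$truth$seed)
  })
}
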
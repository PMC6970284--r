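#' Configuration for the end-to-end demonstration pipeline
#'
#' Describes a complete synthetic study: per platform, a healthy cohort that
#' both defines the reference statistics and serves as the disease-negative
#' sample (the self-referenced evaluation design), and a diseased cohort
#' with a global T1 elevation expressed in multiples of the platform's
#' between-subject SD (an amyloidosis-like large effect is 6 SDs). All
#' randomness flows from `seed`.
#'
#' @param profiles Character vector of builtin profile names, or a list of
#'   [platform_profile()] objects.
#' @param n_healthy Healthy subjects per platform (build the reference and
#'   are classified against it).
#' @param n_diseased Diseased subjects per platform.
#' @param disease_shift_sd Disease T1 elevation in units of the platform's
#'   between-subject SD.
#' @param seed Master seed.
#' @param geometry A [phantom_geometry()].
#' @param exclude_fraction Transmural layer exclusion for the septal ROI.
#' @param z_threshold Classification threshold on |mean Z|.
#' @param epsilon TOST region-of-similarity half-width (Z units).
#' @param out_dir Optional directory; when set, [run_pipeline()] writes the
#'   reference DB, per-subject table and reports there.
#' @return A `t1z_config` list.
#' @export
pipeline_config <- function(profiles = c("siteA_15T_5s", "siteA_3T_5s"),
                            n_healthy = 15, n_diseased = 25,
                            disease_shift_sd = 6, seed = 1L,
                            geometry = phantom_geometry(),
                            exclude_fraction = 0.20, z_threshold = 2,
                            epsilon = 0.75, out_dir = NULL) {
  if (is.character(profiles)) {
    profiles <- setNames(purrr::map(profiles, resolve_profile), profiles)
  }
  stopifnot(length(profiles) >= 1,
            all(purrr::map_lgl(profiles, inherits, "t1z_platform_profile")))
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- purrr::map_chr(profiles, ~ key_label(.x$key))
  }
  structure(
    list(profiles = profiles, n_healthy = n_healthy,
         n_diseased = n_diseased, disease_shift_sd = disease_shift_sd,
         seed = as.integer(seed), geometry = geometry,
         exclude_fraction = exclude_fraction, z_threshold = z_threshold,
         epsilon = epsilon, out_dir = out_dir),
    class = "t1z_config"
  )
}

#' Run the full synthetic study: phantoms, reference, Z-maps, classification
#'
#' Per platform: generate the healthy cohort, measure per-subject septal
#' core mean T1 under the generated contours, build the platform reference,
#' generate the diseased cohort, compute each subject's mean septal Z via a
#' per-subject Z-map with copied contours, classify at the Z threshold, and
#' tabulate sensitivity/specificity. Across platforms the healthy mean-Z
#' samples are compared by independent t-test and TOST equivalence (the
#' cross-platform consistency claim Z-scoring exists for). Fully
#' reproducible from the config seed; any stage failure aborts with the
#' stage name.
#'
#' Subjects are streamed one at a time, so cohort size is limited by time,
#' not memory.
#'
#' @param config A [pipeline_config()].
#' @return A `t1z_pipeline` with elements `reference` (tibble),
#'   `subjects` (per-subject table), `performance` (per platform),
#'   `comparisons` (between-platform tests) and `config`.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(n_healthy = 8, n_diseased = 8,
#'                                     geometry = phantom_geometry(64),
#'                                     seed = 7))
#' glance(res)
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "t1z_config"))
  geometry <- config$geometry
  mask <- pipeline_stage("roi-mask", {
    cp <- contour_pair(circle_polygon(geometry$center, geometry$endo_radius),
                       circle_polygon(geometry$center, geometry$epi_radius))
    septal_core_mask(cp, geometry$grid_size, geometry,
                     config$exclude_fraction)
  })

  refs <- list()
  subjects <- list()
  for (i in seq_along(config$profiles)) {
    pname <- names(config$profiles)[[i]]
    profile <- config$profiles[[i]]
    seed_h <- subject_seed(config$seed, 2L * i - 1L)
    seed_d <- subject_seed(config$seed, 2L * i)
    shift <- config$disease_shift_sd * profile$myo_between_subject_sd

    healthy <- pipeline_stage(paste0("healthy-cohort:", pname), {
      stream_cohort_means(profile, geometry, mask, config$n_healthy,
                          disease_shift = 0, master_seed = seed_h,
                          id_prefix = paste0(pname, "_h"))
    })
    ref <- pipeline_stage(paste0("build-ref:", pname), {
      build_reference_stats(healthy$t1_mean, profile$key)
    })
    diseased <- if (config$n_diseased >= 2) {
      pipeline_stage(paste0("diseased-cohort:", pname), {
        stream_cohort_means(profile, geometry, mask, config$n_diseased,
                            disease_shift = shift, master_seed = seed_d,
                            id_prefix = paste0(pname, "_d"))
      })
    } else NULL

    tab <- dplyr::bind_rows(
      dplyr::mutate(healthy, cohort = "healthy", truth = "normal"),
      if (!is.null(diseased)) {
        dplyr::mutate(diseased, cohort = "diseased", truth = "abnormal")
      }
    )
    tab <- pipeline_stage(paste0("zmap-classify:", pname), {
      out <- classify_subjects(tab, t1_mean, ref = ref,
                               k = config$z_threshold)
      # mean ROI Z under copied contours equals (ROI mean T1 - ref mean)/SD
      # exactly (linearity of the pixel-wise transform), so subjects can be
      # streamed without retaining their Z-maps.
      dplyr::mutate(out, z_mean = .data$z,
                    platform = pname, ref_mean = ref$mean, ref_sd = ref$sd)
    })
    refs[[pname]] <- ref
    subjects[[pname]] <- dplyr::select(tab, "platform", "subject_id",
                                       "cohort", "truth", "t1_mean",
                                       "z_mean", "label", "ref_mean",
                                       "ref_sd")
    if (!is.null(config$out_dir)) {
      pipeline_stage(paste0("write-zmaps:", pname), {
        write_cohort_zmaps(profile, geometry, ref, config, pname,
                           seed_h, seed_d, shift)
      })
    }
  }
  subjects <- dplyr::bind_rows(subjects)

  performance <- pipeline_stage("diagnostics", {
    subjects |>
      dplyr::group_by(.data$platform) |>
      dplyr::group_modify(~ diagnostic_performance(.x, truth, label)) |>
      dplyr::ungroup()
  })

  comparisons <- NULL
  if (length(config$profiles) >= 2) {
    comparisons <- pipeline_stage("compare-platforms", {
      healthy_z <- dplyr::filter(subjects, .data$cohort == "healthy")
      pairs <- utils::combn(names(config$profiles), 2)
      purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
        d <- dplyr::filter(healthy_z, .data$platform %in% pairs[, j])
        tt <- independent_t_test(d, z_mean, platform)
        eq <- tost_equivalence(d, z_mean, platform,
                               epsilon = config$epsilon)
        tibble(platform1 = pairs[1, j], platform2 = pairs[2, j],
               t_statistic = tt$statistic, t_p = tt$p_value,
               tost_epsilon = eq$epsilon, tost_p = eq$p_tost,
               tost_ci_lower = eq$ci_lower, tost_ci_upper = eq$ci_upper,
               equivalent = eq$equivalent)
      })
    })
  }

  result <- structure(
    list(reference = purrr::map_dfr(refs,
                                    ~ dplyr::mutate(tidy(.x), .before = 1,
                                                    platform = key_label(.x$key))),
         reference_db = structure(unname(refs), class = "t1z_refdb"),
         subjects = subjects, performance = performance,
         comparisons = comparisons, config = config),
    class = "t1z_pipeline"
  )
  if (!is.null(config$out_dir)) write_pipeline_report(result, config$out_dir)
  result
}

# Generate a cohort subject by subject, returning the per-subject table of
# septal core ROI mean T1 (map-measured, via the shared mask).
stream_cohort_means <- function(profile, geometry, mask, n_subjects,
                                disease_shift, master_seed, id_prefix) {
  truths <- cohort_truths(profile, n_subjects, disease_shift, master_seed,
                          id_prefix)
  purrr::map_dfr(truths, function(tr) {
    s <- generate_subject_map(profile, geometry, tr)
    st <- roi_statistics(s$map, mask)
    tibble(subject_id = tr$subject_id, t1_mean = st$mean,
           t1_sd = st$sd, n_pixels = st$n_pixels,
           true_septal_mean = tr$true_septal_mean)
  })
}

# Regenerate each subject's map deterministically from its truth and write
# the T1 map, the stored Z-map and a contour file under out_dir/maps/.
write_cohort_zmaps <- function(profile, geometry, ref, config, pname,
                               seed_h, seed_d, shift) {
  dir <- file.path(config$out_dir, "maps")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sets <- list(
    list(truths = cohort_truths(profile, config$n_healthy, 0, seed_h,
                                paste0(pname, "_h"))),
    if (config$n_diseased >= 2) {
      list(truths = cohort_truths(profile, config$n_diseased, shift, seed_d,
                                  paste0(pname, "_d")))
    }
  )
  for (set in sets) {
    if (is.null(set)) next
    for (tr in set$truths) {
      s <- generate_subject_map(profile, geometry, tr)
      write_map(s$map, file.path(dir, paste0(tr$subject_id, "_t1.pgm")))
      zm <- compute_z_map(s$map, ref)
      write_map(zm, file.path(dir, paste0(tr$subject_id, "_z.pgm")))
      write_contours(s$contours,
                     file.path(dir, paste0(tr$subject_id, "_contours.json")))
    }
  }
  invisible(dir)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' @export
print.t1z_pipeline <- function(x, ...) {
  cat(sprintf("<t1zmap pipeline> %d platform(s), %d subjects\n",
              length(x$config$profiles), nrow(x$subjects)))
  print(x$performance)
  if (!is.null(x$comparisons)) {
    cat("Between-platform healthy mean-Z comparisons:\n")
    print(x$comparisons)
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `t1z_pipeline`.
#' @param ... Unused.
#' @return A one-row tibble: subject counts, pooled sensitivity and
#'   specificity, and the worst-case between-platform TOST p.
#' @export
glance.t1z_pipeline <- function(x, ...) {
  pooled <- diagnostic_performance(x$subjects, truth, label)
  tibble(n_platforms = length(x$config$profiles),
         n_subjects = nrow(x$subjects),
         sensitivity = pooled$sensitivity, specificity = pooled$specificity,
         z_threshold = x$config$z_threshold,
         max_tost_p = if (is.null(x$comparisons)) NA_real_
         else max(x$comparisons$tost_p))
}

#' Subject-level table of a pipeline run
#'
#' @param x A `t1z_pipeline`.
#' @param ... Unused.
#' @return The per-subject tibble.
#' @export
tidy.t1z_pipeline <- function(x, ...) x$subjects

#' Write pipeline artifacts to a directory
#'
#' Emits `refdb.json`, `subjects.csv`, `performance.csv`,
#' `comparisons.csv` (when present) and `report.json`. Byte-identical for
#' identical runs.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(result, dir) {
  stopifnot(inherits(result, "t1z_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_reference_db(result$reference_db, file.path(dir, "refdb.json"))
  utils::write.csv(result$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(result$performance, file.path(dir, "performance.csv"),
                   row.names = FALSE)
  if (!is.null(result$comparisons)) {
    utils::write.csv(result$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(glance = glance(result), performance = result$performance,
         comparisons = result$comparisons),
    file.path(dir, "report.json"), digits = I(17), dataframe = "rows",
    na = "null"
  )
  invisible(dir)
}

#' Boxplot of per-subject mean Z by platform and cohort
#'
#' @param object A `t1z_pipeline`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.t1z_pipeline <- function(object, ...) {
  ggplot2::ggplot(object$subjects,
                  ggplot2::aes(x = .data$platform, y = .data$z_mean,
                               fill = .data$cohort)) +
    ggplot2::geom_hline(yintercept = c(-2, 0, 2), linetype = c(3, 2, 3)) +
    ggplot2::geom_boxplot(outlier.shape = 21) +
    ggplot2::labs(y = "mean septal Z", x = NULL) +
    ggplot2::theme_minimal()
}
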
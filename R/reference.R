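#' Build reference statistics from healthy per-subject septal means
#'
#' The reference mean and SD are the arithmetic mean and sample SD
#' (n - 1 denominator) of per-subject septal mean T1 values from a healthy
#' cohort on one platform — the between-subject spread, not a pooled pixel
#' SD. These two numbers anchor the Z-score transform for that platform.
#'
#' @param subject_means Numeric vector of per-subject septal mean T1 (ms),
#'   or a data frame with a column named by `value`.
#' @param key The [platform_key()] the cohort was acquired on.
#' @param roi_descriptor Free-text description of the ROI definition used,
#'   recorded so a database entry is only reused with the same ROI rule.
#' @param value Column name when `subject_means` is a data frame.
#' @return A `t1z_ref` object; `usable` is `FALSE` when the cohort SD is 0
#'   (a degenerate reference that cannot normalize).
#' @examples
#' build_reference_stats(c(950, 1000, 1050),
#'                       platform_key(1.5, "V", "S", "MOLLI 5s(3s)3s"))
#' @export
build_reference_stats <- function(subject_means, key,
                                  roi_descriptor = "septal core, outer 20% excluded",
                                  value = "value") {
  if (is.data.frame(subject_means)) subject_means <- subject_means[[value]]
  subject_means <- as.numeric(subject_means)
  if (length(subject_means) < 2) {
    abort("At least 2 subject means are required to build reference statistics.")
  }
  if (any(!is.finite(subject_means)) || any(subject_means <= 0)) {
    abort("Subject means must be finite and positive (ms).")
  }
  stopifnot(inherits(key, "t1z_platform_key"))
  s <- sd(subject_means)
  if (s == 0) {
    warn("Degenerate cohort: SD of subject means is 0; reference flagged unusable.")
  }
  structure(
    list(key = key, mean = mean(subject_means), sd = s,
         n_subjects = length(subject_means),
         roi_descriptor = as.character(roi_descriptor), usable = s > 0),
    class = "t1z_ref"
  )
}

#' @export
print.t1z_ref <- function(x, ...) {
  cat(sprintf("<reference stats> mean %.1f ms, SD %.1f ms (n = %d)%s\n",
              x$mean, x$sd, x$n_subjects,
              if (x$usable) "" else " [UNUSABLE: sd = 0]"))
  cat("  platform:", format(x$key), "\n  ROI:", x$roi_descriptor, "\n")
  invisible(x)
}

#' @export
tidy.t1z_ref <- function(x, ...) {
  tibble(field_strength = x$key$field_strength, vendor = x$key$vendor,
         system = x$key$system, scheme = x$key$scheme,
         mean = x$mean, sd = x$sd, n_subjects = x$n_subjects,
         roi = x$roi_descriptor, usable = x$usable)
}

#' Normal range of a reference: (mean - k SD, mean + k SD)
#'
#' @param stats A usable [build_reference_stats()] result.
#' @param k SD multiplier; the conventional normal range uses k = 2.
#' @return A one-row tibble with `lower`, `upper`, `k`.
#' @examples
#' r <- build_reference_stats(c(970, 1000, 1030),
#'                            platform_key(1.5, "V", "S", "M"))
#' normal_range(r)
#' @export
normal_range <- function(stats, k = 2) {
  stopifnot(inherits(stats, "t1z_ref"))
  if (!stats$usable) abort("Reference is unusable (sd = 0): no normal range.")
  if (k <= 0) abort("`k` must be positive.")
  tibble(lower = stats$mean - k * stats$sd,
         upper = stats$mean + k * stats$sd, k = k)
}

#' Persist a reference database as schema-versioned JSON
#'
#' One human-auditable JSON file per site:
#' `{"schema": 1, "entries": [{"key": {...}, "mean": ..., "sd": ...,
#' "n_subjects": ..., "roi": ...}]}`. Floats round-trip exactly.
#'
#' @param stats_list A list of `t1z_ref` objects with pairwise-distinct keys.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_reference_db <- function(stats_list, path) {
  if (inherits(stats_list, "t1z_ref")) stats_list <- list(stats_list)
  stopifnot(all(purrr::map_lgl(stats_list, inherits, "t1z_ref")))
  labels <- purrr::map_chr(stats_list, ~ key_label(.x$key))
  if (anyDuplicated(labels)) {
    abort("Duplicate platform keys in the reference database.")
  }
  entries <- purrr::map(stats_list, function(r) {
    list(key = list(field_strength = r$key$field_strength,
                    vendor = r$key$vendor, system = r$key$system,
                    scheme = r$key$scheme),
         mean = r$mean, sd = r$sd, n_subjects = r$n_subjects,
         roi = r$roi_descriptor)
  })
  jsonlite::write_json(list(schema = 1L, entries = entries), path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a reference database written by [save_reference_db()]
#'
#' @param path JSON file path.
#' @return A `t1z_refdb`: a list of `t1z_ref` entries.
#' @export
load_reference_db <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema) || obj$schema != 1) {
    abort("Unsupported reference database schema.")
  }
  entries <- purrr::map(obj$entries, function(e) {
    structure(
      list(key = platform_key(e$key$field_strength, e$key$vendor,
                              e$key$system, e$key$scheme),
           mean = as.numeric(e$mean), sd = as.numeric(e$sd),
           n_subjects = as.integer(e$n_subjects),
           roi_descriptor = e$roi, usable = e$sd > 0),
      class = "t1z_ref"
    )
  })
  structure(entries, class = "t1z_refdb")
}

#' Look up reference statistics for a platform key
#'
#' A missing entry is a hard error: platforms are not interchangeable, so
#' there is never a silent cross-platform fallback.
#'
#' @param db A `t1z_refdb` (or plain list of `t1z_ref`).
#' @param key A [platform_key()].
#' @return The matching `t1z_ref`.
#' @export
lookup_reference <- function(db, key) {
  stopifnot(inherits(key, "t1z_platform_key"))
  hit <- purrr::detect(db, ~ same_key(.x$key, key))
  if (is.null(hit)) {
    abort(sprintf("No reference statistics for platform [%s]; refusing any cross-platform fallback.",
                  format(key)), class = "t1z_missing_reference")
  }
  hit
}

#' @export
tidy.t1z_refdb <- function(x, ...) purrr::map_dfr(x, tidy)
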
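#' Write a map as a 16-bit PGM raster plus JSON sidecar
#'
#' The canonical on-disk form is a binary P5 PGM (maxval 65535, big-endian)
#' with a JSON sidecar describing how to decode it:
#'
#' * T1 maps: `units = "ms"`, pixel = round(T1) (half away from zero),
#'   invalid pixels carry the sentinel 65535.
#' * Z maps: `units = "Zx100"`, pixel = stored Z (`round(Z x 100)`) plus an
#'   offset of 32768 so the signed payload fits an unsigned raster; the
#'   sidecar records `scale_factor`, `offset` and the background sentinel
#'   (-32768 before offset). This mirrors DICOM rescale-slope semantics.
#'
#' Out-of-range values after scaling are clamped and logged, never fatal.
#' Output bytes are deterministic for fixed input.
#'
#' @param map A `t1z_map`, `t1z_zmap` or `t1z_stored_zmap` (float Z-maps
#'   are quantized on the way out).
#' @param path Output `.pgm` path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  if (inherits(map, "t1z_zmap")) map <- quantize_z_map(map)
  if (inherits(map, "t1z_map")) {
    stored <- round_half_away(map$pixels)
    n_clamped <- sum(stored > 65534 | stored < 0, na.rm = TRUE)
    if (n_clamped > 0) {
      warn(sprintf("%d T1 pixel(s) clamped to [0, 65534] ms for storage.",
                   n_clamped))
    }
    stored <- pmin(pmax(stored, 0), 65534)
    stored[!map$validity_mask] <- 65535
    sidecar <- list(units = "ms", scale_factor = 1L, offset = 0L,
                    sentinel = 65535L,
                    pixel_spacing = map$pixel_spacing,
                    subject_id = map$subject_id,
                    platform = key_to_list(map$platform),
                    provenance = "t1zmap write_map")
  } else if (inherits(map, "t1z_stored_zmap")) {
    stored <- map$pixels + 32768L
    sidecar <- list(units = "Zx100", scale_factor = map$scale_factor,
                    offset = 32768L, sentinel = map$background_sentinel,
                    pixel_spacing = map$pixel_spacing,
                    subject_id = map$subject_id,
                    platform = key_to_list(map$source_key),
                    ref = ref_to_list(map$ref),
                    provenance = "t1zmap write_map")
  } else {
    abort("Unsupported map type for write_map().")
  }
  write_pgm16(stored, path)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' Read a map written by [write_map()]
#'
#' Decodes the raster through the sidecar's units, scale factor, offset and
#' sentinel. A missing sidecar or an unknown units label is rejected with an
#' explicit message; a raster whose pixel count does not match its header is
#' rejected as corrupt.
#'
#' @param path `.pgm` path.
#' @param sidecar_path Sidecar path; defaults to `paste0(path, ".json")`.
#' @return A `t1z_map` (units `"ms"`) or `t1z_stored_zmap` (units
#'   `"Zx100"`).
#' @export
read_map <- function(path, sidecar_path = paste0(path, ".json")) {
  if (!file.exists(sidecar_path)) {
    abort(sprintf("Missing sidecar '%s': cannot decode raster units.",
                  sidecar_path))
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  raw <- read_pgm16(path)
  platform <- list_to_key(sc$platform)
  if (identical(sc$units, "ms")) {
    valid <- raw != sc$sentinel
    px <- raw * as.numeric(sc$scale_factor)
    px[!valid] <- 0
    t1_map(px, pixel_spacing = sc$pixel_spacing %||% 1, platform = platform,
           subject_id = sc$subject_id %||% NA_character_,
           validity_mask = valid)
  } else if (identical(sc$units, "Zx100")) {
    stored <- raw - sc$offset
    ref <- if (!is.null(sc$ref)) list_to_ref(sc$ref) else NULL
    structure(
      list(pixels = matrix(as.integer(stored), nrow(stored), ncol(stored)),
           scale_factor = as.integer(sc$scale_factor),
           background_sentinel = as.integer(sc$sentinel),
           source_key = platform, ref = ref,
           subject_id = sc$subject_id %||% NA_character_,
           pixel_spacing = sc$pixel_spacing %||% 1),
      class = "t1z_stored_zmap"
    )
  } else {
    abort(sprintf("Unit mismatch: sidecar declares unknown units '%s'.",
                  sc$units))
  }
}

#' Write a rendered Z-map to PNG
#'
#' @param img A [render_z_map()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_render_png <- function(img, path) {
  stopifnot(inherits(img, "t1z_rgb"))
  png::writePNG(unclass(img), path)
  invisible(path)
}

# --- PGM-16 primitives ----------------------------------------------------
# Binary P5, maxval 65535, big-endian, rows written top to bottom. No
# pre-installed R package reads PGM, and the format is 3 header tokens plus
# raw samples, so it is implemented here.

write_pgm16 <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  v <- as.vector(t(pixels))  # row-major
  if (any(v < 0 | v > 65535)) abort("PGM-16 samples must lie in [0, 65535].")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n65535\n", ncol(pixels), nrow(pixels)), con,
            eos = NULL)
  v_signed <- ifelse(v > 32767, v - 65536, v)  # two's-complement shorts
  writeBin(as.integer(v_signed), con, size = 2L, endian = "big")
  invisible(path)
}

read_pgm16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  buf <- character(0)
  while (length(tokens) < 4) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0) abort("Corrupt PGM: truncated header.")
    if (grepl("[[:space:]]", ch)) {
      if (nchar(paste(buf, collapse = ""))) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else buf <- c(buf, ch)
  }
  if (tokens[[1]] != "P5") abort("Corrupt PGM: expected binary P5 magic.")
  w <- as.integer(tokens[[2]]); h <- as.integer(tokens[[3]])
  maxval <- as.integer(tokens[[4]])
  if (is.na(w) || is.na(h) || maxval != 65535) {
    abort("Corrupt PGM: bad dimensions or maxval (expected 65535).")
  }
  v <- readBin(con, "integer", n = w * h, size = 2L, signed = FALSE,
               endian = "big")
  if (length(v) != w * h) {
    abort("Corrupt PGM: raster length does not match header dimensions.")
  }
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

# --- sidecar helpers ------------------------------------------------------

key_to_list <- function(key) {
  if (is.null(key)) return(NULL)
  list(field_strength = key$field_strength, vendor = key$vendor,
       system = key$system, scheme = key$scheme)
}

list_to_key <- function(x) {
  if (is.null(x) || is.null(x$vendor)) return(NULL)
  platform_key(x$field_strength, x$vendor, x$system, x$scheme)
}

ref_to_list <- function(ref) {
  if (is.null(ref)) return(NULL)
  list(key = key_to_list(ref$key), mean = ref$mean, sd = ref$sd,
       n_subjects = ref$n_subjects, roi = ref$roi_descriptor)
}

list_to_ref <- function(x) {
  structure(
    list(key = list_to_key(x$key), mean = as.numeric(x$mean),
         sd = as.numeric(x$sd), n_subjects = as.integer(x$n_subjects),
         roi_descriptor = x$roi, usable = x$sd > 0),
    class = "t1z_ref"
  )
}
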
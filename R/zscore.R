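#' Transform a T1 map into a pixel-wise Z-score map
#'
#' For every valid pixel, `Z = (T1 - mean) / SD` with the reference mean and
#' SD of healthy septal T1 for the acquiring platform. Z is dimensionless
#' and directly comparable across field strengths, systems and MOLLI
#' schemes. Non-tissue pixels become `NA`. The reference snapshot is
#' embedded in the result for provenance.
#'
#' The map's platform key must equal the reference key; mismatches are
#' rejected unless explicitly overridden (and then warned about), because
#' normalizing against another platform's statistics silently invalidates
#' the Z scale.
#'
#' @param map A [t1_map()].
#' @param ref A usable [build_reference_stats()] result.
#' @param override_key_mismatch Allow a mismatched platform key (logged).
#' @return A `t1z_zmap`.
#' @examples
#' ref <- build_reference_stats(c(950, 1000, 1050),
#'                              platform_key(1.5, "V", "S", "M"))
#' m <- t1_map(matrix(1075, 1, 1), platform = ref$key)
#' compute_z_map(m, ref)$pixels  # (1075 - 1000) / 50 = 1.5
#' @export
compute_z_map <- function(map, ref, override_key_mismatch = FALSE) {
  stopifnot(inherits(map, "t1z_map"), inherits(ref, "t1z_ref"))
  if (!ref$usable) abort("Reference SD is 0: Z-scores are undefined.")
  if (!is.null(map$platform) && !same_key(map$platform, ref$key)) {
    if (!override_key_mismatch) {
      abort(sprintf("Platform key mismatch: map [%s] vs reference [%s]. Pass override_key_mismatch = TRUE only if you mean it.",
                    format(map$platform), format(ref$key)))
    }
    warn("Platform key mismatch overridden: Z-scores use another platform's reference.")
  }
  z <- (map$pixels - ref$mean) / ref$sd
  z[!map$validity_mask] <- NA_real_
  structure(
    list(pixels = z, source_key = map$platform, ref = ref,
         subject_id = map$subject_id, pixel_spacing = map$pixel_spacing),
    class = "t1z_zmap"
  )
}

#' @export
print.t1z_zmap <- function(x, ...) {
  v <- x$pixels[!is.na(x$pixels)]
  cat(sprintf("<Z-score map> %dx%d px, subject %s, Z range %.2f to %.2f\n",
              nrow(x$pixels), ncol(x$pixels), x$subject_id,
              min(v), max(v)))
  cat(sprintf("  reference: mean %.1f ms, SD %.1f ms (n = %d)\n",
              x$ref$mean, x$ref$sd, x$ref$n_subjects))
  invisible(x)
}

Z_SENTINEL <- -32768L

#' Quantize a Z-map for integer storage
#'
#' DICOM pixel intensities are integers, so Z is stored as
#' `round(Z x 100)` — a Z-score of 1.5 is stored as 150. Rounding is half
#' away from zero (symmetric for negative Z), values are clamped to the
#' signed 16-bit payload range \[-32767, 32767\] (clamping is logged, not
#' fatal), and background/invalid pixels carry the sentinel -32768.
#'
#' @param z A `t1z_zmap`.
#' @return A `t1z_stored_zmap` with `scale_factor` 100.
#' @examples
#' ref <- build_reference_stats(c(950, 1000, 1050),
#'                              platform_key(1.5, "V", "S", "M"))
#' zm <- compute_z_map(t1_map(matrix(1075, 1, 1), platform = ref$key), ref)
#' quantize_z_map(zm)$pixels  # 150
#' @export
quantize_z_map <- function(z) {
  stopifnot(inherits(z, "t1z_zmap"))
  stored <- round_half_away(z$pixels * 100)
  n_clamped <- sum(abs(stored) > 32767, na.rm = TRUE)
  if (n_clamped > 0) {
    warn(sprintf("%d pixel(s) clamped to the signed 16-bit range.", n_clamped))
  }
  stored <- pmin(pmax(stored, -32767), 32767)
  stored[is.na(stored)] <- Z_SENTINEL
  structure(
    list(pixels = matrix(as.integer(stored), nrow(z$pixels), ncol(z$pixels)),
         scale_factor = 100L, background_sentinel = Z_SENTINEL,
         source_key = z$source_key, ref = z$ref, subject_id = z$subject_id,
         pixel_spacing = z$pixel_spacing),
    class = "t1z_stored_zmap"
  )
}

#' Recover a float Z-map from integer storage
#'
#' `Z = stored / scale_factor`; sentinel pixels become `NA`. The
#' quantize/dequantize round trip errs by at most 0.005 Z units.
#'
#' @param stored A `t1z_stored_zmap`.
#' @return A `t1z_zmap`.
#' @export
dequantize <- function(stored) {
  stopifnot(inherits(stored, "t1z_stored_zmap"))
  if (!identical(stored$background_sentinel, Z_SENTINEL)) {
    abort("Unknown background sentinel convention in stored Z-map.")
  }
  z <- stored$pixels / stored$scale_factor
  z[stored$pixels == stored$background_sentinel] <- NA_real_
  structure(
    list(pixels = z, source_key = stored$source_key, ref = stored$ref,
         subject_id = stored$subject_id, pixel_spacing = stored$pixel_spacing),
    class = "t1z_zmap"
  )
}

#' Mean septal Z from a Z-map under copied contours
#'
#' ROI statistics of a Z-map under the same (copied) contour-derived mask
#' used on the T1 map. By linearity of the Z transform this equals
#' `(ROI-mean T1 - ref mean) / ref SD` exactly.
#'
#' @param z A `t1z_zmap`.
#' @param mask A `t1z_mask` on the same grid.
#' @return A one-row tibble: `mean`, `sd`, `n_pixels` (Z units).
#' @export
mean_roi_z <- function(z, mask) {
  stopifnot(inherits(z, "t1z_zmap"))
  roi_statistics(z, mask)
}

#' Symmetric diverging palette for Z-map rendering
#'
#' An 11-class blue-white-red scheme: the middle class (white) is centered
#' on Z = 0, classes are 1 Z unit wide, and values beyond the outermost
#' interior breakpoints (+/- 4.5 by default) take the end colors. Colors are
#' a ColorBrewer-style RdBu ramp reversed so that elevated T1 (positive Z)
#' is red.
#'
#' @param breakpoints Interior class boundaries, strictly increasing and
#'   symmetric about 0; one fewer than `colors`.
#' @param colors Hex colors, one more than the interior breakpoints.
#' @return A `t1z_palette`.
#' @export
diverging_palette <- function(breakpoints = seq(-4.5, 4.5, by = 1),
                              colors = c("#053061", "#2166AC", "#4393C3",
                                         "#92C5DE", "#D1E5F0", "#F7F7F7",
                                         "#FDDBC7", "#F4A582", "#D6604D",
                                         "#B2182B", "#67001F")) {
  if (length(colors) != length(breakpoints) + 1) {
    abort("Need exactly one more color than interior breakpoints.")
  }
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    abort("Breakpoints must be strictly increasing.")
  }
  if (max(abs(breakpoints + rev(breakpoints))) > 1e-9) {
    abort("Palette must be symmetric about Z = 0.")
  }
  structure(list(breakpoints = breakpoints, colors = colors, center = 0),
            class = "t1z_palette")
}

#' Render a Z-map to an RGB raster with a diverging color scheme
#'
#' Z = 0 renders exactly as the palette's center color, |Z| at or beyond
#' `clip` saturates at the end colors, and invalid/background pixels render
#' neutral gray. Rendering is deterministic.
#'
#' @param z A `t1z_zmap`.
#' @param palette A [diverging_palette()].
#' @param clip Saturation limit in Z units.
#' @param na_color Hex color for invalid pixels.
#' @return A `rows x cols x 3` numeric array in \[0, 1\] (class
#'   `t1z_rgb`), suitable for [png::writePNG()].
#' @export
render_z_map <- function(z, palette = diverging_palette(), clip = 5,
                         na_color = "#808080") {
  stopifnot(inherits(z, "t1z_zmap"), inherits(palette, "t1z_palette"))
  if (clip <= 0) abort("`clip` must be positive.")
  v <- pmin(pmax(z$pixels, -clip), clip)
  cls <- findInterval(v, palette$breakpoints) + 1L
  lut <- t(grDevices::col2rgb(palette$colors)) / 255
  na_rgb <- as.numeric(grDevices::col2rgb(na_color)) / 255
  nr <- nrow(z$pixels); nc <- ncol(z$pixels)
  img <- array(NA_real_, c(nr, nc, 3))
  for (ch in 1:3) {
    plane <- lut[cls, ch]
    plane[is.na(cls)] <- na_rgb[[ch]]
    img[, , ch] <- matrix(plane, nr, nc)
  }
  structure(img, class = "t1z_rgb")
}

#' Plot a Z-score map with its diverging scale
#'
#' @param object A `t1z_zmap`.
#' @param clip Saturation limit in Z units.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.t1z_zmap <- function(object, clip = 5, ...) {
  df <- zmap_to_df(object$pixels, "z")
  pal <- diverging_palette()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_stepsn(colors = pal$colors,
                               breaks = pal$breakpoints,
                               limits = c(-clip, clip), oob = scales::squish,
                               na.value = "grey50", name = "Z") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Z-score map (subject %s)",
                                  object$subject_id),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a T1 map
#'
#' @param object A `t1z_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.t1z_map <- function(object, ...) {
  px <- object$pixels
  px[!object$validity_mask] <- NA_real_
  df <- zmap_to_df(px, "t1")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$t1)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", name = "T1 [ms]") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("T1 map (subject %s)", object$subject_id),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

zmap_to_df <- function(px, value_name) {
  df <- tibble(
    row = rep(seq_len(nrow(px)) - 1, times = ncol(px)),
    col = rep(seq_len(ncol(px)) - 1, each = nrow(px)),
    value = as.vector(px)
  )
  names(df)[names(df) == "value"] <- value_name
  df
}
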
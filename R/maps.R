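#' T1 parametric map
#'
#' A 2D raster of native T1 values in milliseconds with pixel spacing, the
#' acquiring platform key, and a validity mask (FALSE for background or
#' otherwise non-tissue pixels).
#'
#' @param pixels Numeric matrix of T1 values (ms); finite and non-negative
#'   wherever valid.
#' @param pixel_spacing In-plane pixel spacing in mm.
#' @param platform A [platform_key()] or `NULL`.
#' @param subject_id Subject label.
#' @param validity_mask Logical matrix matching `pixels`; defaults to all
#'   `TRUE`.
#' @return A `t1z_map` object.
#' @export
t1_map <- function(pixels, pixel_spacing = 1, platform = NULL,
                   subject_id = NA_character_, validity_mask = NULL) {
  stopifnot(is.matrix(pixels))
  validity_mask <- validity_mask %||% matrix(TRUE, nrow(pixels), ncol(pixels))
  stopifnot(is.logical(validity_mask),
            identical(dim(validity_mask), dim(pixels)))
  if (pixel_spacing <= 0) abort("`pixel_spacing` must be positive (mm).")
  v <- pixels[validity_mask]
  if (any(!is.finite(v)) || any(v < 0)) {
    abort("Valid T1 pixels must be finite and non-negative (ms).")
  }
  structure(
    list(pixels = pixels, pixel_spacing = pixel_spacing, platform = platform,
         subject_id = subject_id, validity_mask = validity_mask),
    class = "t1z_map"
  )
}

#' @export
print.t1z_map <- function(x, ...) {
  cat(sprintf("<T1 map> %dx%d px, spacing %g mm, subject %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing, x$subject_id))
  if (!is.null(x$platform)) cat("  platform:", format(x$platform), "\n")
  v <- x$pixels[x$validity_mask]
  if (length(v)) {
    cat(sprintf("  valid px: %d, T1 range %.0f-%.0f ms\n",
                length(v), min(v), max(v)))
  }
  invisible(x)
}

#' Endocardial/epicardial contour pair
#'
#' Ordered closed polygons in 0-based `(row, col)` pixel coordinates; the
#' closing edge (last vertex back to first) is implicit. The endocardial
#' contour must lie strictly inside the epicardial one.
#'
#' @param endo,epi Numeric matrices with >= 3 rows and 2 columns.
#' @return A `t1z_contours` object.
#' @export
contour_pair <- function(endo, epi) {
  endo <- as.matrix(endo); epi <- as.matrix(epi)
  if (nrow(endo) < 3 || nrow(epi) < 3 || ncol(endo) != 2 || ncol(epi) != 2) {
    abort("Contours must be (row, col) polygons with at least 3 vertices.")
  }
  if (!all(points_in_polygon(endo, epi))) {
    abort("Endocardial contour must lie strictly inside the epicardial one.")
  }
  structure(list(endo = unname(endo), epi = unname(epi)),
            class = "t1z_contours")
}

#' @export
print.t1z_contours <- function(x, ...) {
  cat(sprintf("<contour pair> endo %d vertices, epi %d vertices\n",
              nrow(x$endo), nrow(x$epi)))
  invisible(x)
}

#' Write contours to a JSON point-list file
#'
#' Schema: `{"endo": [[r, c], ...], "epi": [[r, c], ...]}`, polygons closed
#' implicitly.
#'
#' @param contours A [contour_pair()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  stopifnot(inherits(contours, "t1z_contours"))
  jsonlite::write_json(list(endo = contours$endo, epi = contours$epi), path,
                       digits = I(17))
  invisible(path)
}

#' Read contours from a JSON point-list file
#'
#' @param path File written by [write_contours()].
#' @return A [contour_pair()].
#' @export
read_contours <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("endo", "epi") %in% names(obj))) {
    abort("Contour file must contain 'endo' and 'epi' point lists.")
  }
  contour_pair(obj$endo, obj$epi)
}

# Extract the raw pixel matrix from a map-like object.
map_pixels <- function(map) {
  if (inherits(map, c("t1z_map", "t1z_zmap"))) return(map$pixels)
  if (is.matrix(map)) return(map)
  abort("Expected a t1z_map, t1z_zmap or plain matrix.")
}
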
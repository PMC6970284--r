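#' Rasterize a contour pair into a myocardial mask
#'
#' A pixel belongs to the myocardium when its center lies inside the
#' epicardial polygon and outside (or on) the endocardial one; membership is
#' tested at pixel centers with the even-odd rule.
#'
#' The returned mask keeps the generating contours attached so that
#' transmural depth can be measured exactly against the contour geometry.
#'
#' @param contours A [contour_pair()].
#' @param grid_shape Integer `(rows, cols)` of the target raster (a single
#'   number means a square grid).
#' @return A `t1z_mask` with provenance `"full"`.
#' @examples
#' cp <- contour_pair(circle_polygon(c(63.5, 63.5), 20),
#'                    circle_polygon(c(63.5, 63.5), 30))
#' m <- rasterize_mask(cp, 128)
#' sum(m$grid)  # ~ pi * (30^2 - 20^2)
#' @export
rasterize_mask <- function(contours, grid_shape) {
  stopifnot(inherits(contours, "t1z_contours"))
  if (length(grid_shape) == 1) grid_shape <- rep(grid_shape, 2)
  grid_shape <- as.integer(grid_shape)
  pts <- pixel_centers(grid_shape)
  inside <- points_in_polygon(pts, contours$epi) &
    !points_in_polygon(pts, contours$endo)
  grid <- matrix(inside, grid_shape[[1]], grid_shape[[2]])
  if (!any(grid)) {
    abort("Degenerate contours: rasterization produced an empty myocardial mask.")
  }
  new_mask(grid, "full", contours)
}

new_mask <- function(grid, provenance, contours, depth = NULL) {
  structure(list(grid = grid, provenance = provenance, contours = contours,
                 depth = depth),
            class = "t1z_mask")
}

#' @export
print.t1z_mask <- function(x, ...) {
  cat(sprintf("<myocardial mask> %dx%d px, %d in mask, provenance '%s'\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid), x$provenance))
  invisible(x)
}

#' Normalized transmural depth of each myocardial pixel
#'
#' For every pixel in the mask, depth `d = d_endo / (d_endo + d_epi)` where
#' `d_endo` and `d_epi` are the exact Euclidean distances from the pixel
#' center to the endocardial and epicardial contour polylines. Depth is 0 at
#' the endocardium and 1 at the epicardium; on a concentric annulus it equals
#' the analytic radial position `(r - r_endo) / (r_epi - r_endo)`.
#'
#' @param mask A full-provenance [rasterize_mask()] result.
#' @return A numeric matrix of depths in \[0, 1\], `NA` outside the mask.
#' @export
transmural_depth <- function(mask) {
  stopifnot(inherits(mask, "t1z_mask"))
  if (!any(mask$grid)) abort("Empty mask: transmural depth is undefined.")
  if (!identical(mask$provenance, "full")) {
    abort("Transmural depth is computed on the full myocardial mask.")
  }
  idx <- which(mask$grid)
  nr <- nrow(mask$grid)
  pts <- cbind((idx - 1) %% nr, (idx - 1) %/% nr)  # 0-based (row, col)
  d_endo <- point_polygon_distance(pts, mask$contours$endo)
  d_epi <- point_polygon_distance(pts, mask$contours$epi)
  depth <- matrix(NA_real_, nr, ncol(mask$grid))
  depth[idx] <- d_endo / (d_endo + d_epi)
  depth
}

#' Exclude the outer subendocardial and subepicardial layers
#'
#' Retains pixels whose transmural depth lies in
#' `[exclude_fraction, 1 - exclude_fraction]`. The default 0.20 discards the
#' outer 20% layer at each surface, the standard guard against partial-volume
#' contamination from blood pool and extra-myocardial tissue. Exclusion is a
#' transmural proportion, not an erosion by a fixed pixel count, so it adapts
#' to wall thickness.
#'
#' @param mask A full-provenance mask.
#' @param exclude_fraction Proportion in \[0, 0.5) excluded at each surface.
#' @return A `t1z_mask` with provenance `"core"` (depth raster attached).
#' @export
core_mask <- function(mask, exclude_fraction = 0.20) {
  stopifnot(inherits(mask, "t1z_mask"))
  if (exclude_fraction < 0 || exclude_fraction >= 0.5) {
    abort("`exclude_fraction` must lie in [0, 0.5); 0.5 would retain nothing.")
  }
  depth <- transmural_depth(mask)
  keep <- !is.na(depth) & depth >= exclude_fraction &
    depth <= 1 - exclude_fraction
  new_mask(mask$grid & keep, "core", mask$contours, depth = depth)
}

#' Restrict a mask to an angular (septal) sector
#'
#' Retains pixels whose polar angle about `center` lies in the half-open
#' interval `[from, to)` degrees. Angles are measured from the positive
#' column axis towards the positive row axis, modulo 360; intervals may wrap
#' through 0.
#'
#' @param mask A `t1z_mask`.
#' @param center `(row, col)` pixel coordinates of the rotation center
#'   (0-based).
#' @param angle_interval Length-2 numeric, degrees; width in (0, 360\].
#' @return A `t1z_mask`; provenance `"sector_core"` when the input is a core
#'   mask, `"sector"` otherwise.
#' @export
sector_mask <- function(mask, center, angle_interval) {
  stopifnot(inherits(mask, "t1z_mask"))
  from <- angle_interval[[1]]; to <- angle_interval[[2]]
  width <- (to - from) %% 360
  full_circle <- width == 0 && to != from
  if (to == from) abort("Zero-width sector interval.")
  idx <- which(mask$grid)
  keep <- mask$grid
  if (!full_circle) {
    nr <- nrow(mask$grid)
    drow <- (idx - 1) %% nr - center[[1]]
    dcol <- (idx - 1) %/% nr - center[[2]]
    ang <- (atan2(drow, dcol) * 180 / pi) %% 360
    rel <- (ang - from) %% 360
    keep[idx] <- rel < width
  }
  provenance <- if (identical(mask$provenance, "core")) "sector_core"
  else "sector"
  new_mask(mask$grid & keep, provenance, mask$contours, depth = mask$depth)
}

#' ROI statistics over a masked map
#'
#' Mean and sample SD (n - 1 denominator) of the map values under the mask.
#' With a single pixel the SD is undefined and returned as `NA` with a
#' warning.
#'
#' @param map A `t1z_map`, `t1z_zmap` or plain numeric matrix.
#' @param mask A `t1z_mask` on the same grid.
#' @return A one-row tibble: `mean`, `sd`, `n_pixels`.
#' @examples
#' m <- matrix(c(990, 1010), 1, 2)
#' msk <- structure(list(grid = matrix(TRUE, 1, 2), provenance = "full"),
#'                  class = "t1z_mask")
#' roi_statistics(m, msk)
#' @export
roi_statistics <- function(map, mask) {
  stopifnot(inherits(mask, "t1z_mask"))
  px <- map_pixels(map)
  if (!identical(dim(px), dim(mask$grid))) {
    abort("Map and mask grids have different shapes.")
  }
  v <- px[mask$grid]
  v <- v[!is.na(v)]
  if (length(v) == 0) abort("Empty mask: ROI statistics are undefined.")
  s <- if (length(v) >= 2) sd(v) else {
    warn("ROI has a single pixel; SD is undefined.")
    NA_real_
  }
  tibble(mean = mean(v), sd = s, n_pixels = length(v))
}

#' Full septal-core ROI mask in one call
#'
#' Convenience composition: rasterize, exclude the outer layers, restrict to
#' the septal sector of a phantom geometry (or an explicit sector).
#'
#' @param contours A [contour_pair()].
#' @param grid_shape Raster shape as in [rasterize_mask()].
#' @param geometry Optional [phantom_geometry()] supplying center and septal
#'   sector; when `NULL` the sector step is skipped.
#' @param exclude_fraction Passed to [core_mask()].
#' @return A `t1z_mask`.
#' @export
septal_core_mask <- function(contours, grid_shape, geometry = NULL,
                             exclude_fraction = 0.20) {
  m <- core_mask(rasterize_mask(contours, grid_shape), exclude_fraction)
  if (is.null(geometry)) return(m)
  sector_mask(m, geometry$center, geometry$septal_sector)
}
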
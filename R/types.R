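# Core domain types: calibrated 3D grids, binary nucleus masks, point
# patterns and the global analysis configuration.

#' Calibrated 3D image
#'
#' A 3D scalar image together with its physical voxel spacing. The array is
#' indexed `[x, y, z]`; the center of voxel `(i, j, k)` sits at
#' `((i - 0.5) * sx, (j - 0.5) * sy, (k - 0.5) * sz)` micrometres. Anisotropy
#' (axial spacing different from lateral) is permitted and honored by every
#' distance-based computation.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric length-3, micrometres per voxel along (x, y, z).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing) {
  if (length(dim(data)) != 3L)
    stop("not a 3D stack: 'data' must have exactly 3 axes")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (micrometres per voxel)")
  structure(list(data = data, spacing = spacing), class = "voxel_grid")
}

#' Binary nucleus mask
#'
#' The bounded domain of all spatial analysis: a 3D logical array with voxel
#' spacing, `TRUE` inside the nucleus.
#'
#' @param data 3D logical array.
#' @param spacing micrometres per voxel along (x, y, z).
#' @return An object of class `nucleus_mask`.
#' @export
nucleus_mask <- function(data, spacing) {
  if (length(dim(data)) != 3L)
    stop("not a 3D stack: 'data' must have exactly 3 axes")
  storage.mode(data) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values")
  structure(list(data = data, spacing = spacing), class = "nucleus_mask")
}

#' Spatial point pattern
#'
#' A set of points in physical micrometre coordinates, optionally carrying a
#' per-point hardcore radius (the equivalent spherical radius of a
#' chromocenter; absent for diffraction-limited centromeric spots).
#'
#' @param points numeric matrix with 3 columns (x, y, z) in micrometres.
#' @param radii optional numeric vector of non-negative hardcore radii, one
#'   per point.
#' @return An object of class `point_pattern`.
#' @export
point_pattern <- function(points, radii = NULL) {
  points <- matrix(as.numeric(points), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (!is.null(radii)) {
    radii <- as.numeric(radii)
    if (length(radii) != nrow(points))
      stop("radii must have one entry per point")
    if (any(!is.finite(radii)) || any(radii < 0))
      stop("radii must be finite and >= 0")
  }
  structure(list(points = points, radii = radii), class = "point_pattern")
}

#' Number of points in a pattern
#' @param pattern a [point_pattern()].
#' @export
npoints <- function(pattern) nrow(pattern$points)

#' Analysis configuration
#'
#' Holds the Monte-Carlo budgets and the test level used throughout the
#' spatial analysis: `n_eval` evaluation points for the empty-space function,
#' `p1` replicates for the reference function, `p2` replicates for the
#' deviation distribution, and the level `alpha` of the population test.
#'
#' @param n_eval number of F-function evaluation points (default 10000).
#' @param p1 reference-set replicate count (default 500).
#' @param p2 deviation-set replicate count (default 500).
#' @param seed optional integer seed applied before Monte-Carlo sampling.
#' @param alpha level of the population-level test (default 0.05).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(n_eval = 10000L, p1 = 500L, p2 = 500L,
                            seed = NULL, alpha = 0.05) {
  n_eval <- as.integer(n_eval); p1 <- as.integer(p1); p2 <- as.integer(p2)
  if (n_eval < 1L || p1 < 1L || p2 < 1L)
    stop("n_eval, p1 and p2 must all be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  structure(list(n_eval = n_eval, p1 = p1, p2 = p2,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 alpha = alpha),
            class = "analysis_config")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %.4g/%.4g/%.4g um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
print.nucleus_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<nucleus_mask> %d x %d x %d voxels, %d foreground, volume %.2f um^3\n",
    d[1], d[2], d[3], sum(x$data), mask_volume(x)))
  invisible(x)
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("<point_pattern> %d points%s\n", npoints(x),
              if (is.null(x$radii)) "" else " with hardcore radii"))
  invisible(x)
}

# ---- internal geometry helpers ------------------------------------------

# physical coordinates (um) of the centers of all foreground voxels
fg_coords <- function(mask) {
  idx <- which(mask$data)
  if (length(idx) == 0)
    stop("empty mask: no foreground voxel")
  ai <- arrayInd(idx, dim(mask$data))
  cbind(x = (ai[, 1] - 0.5) * mask$spacing[1],
        y = (ai[, 2] - 0.5) * mask$spacing[2],
        z = (ai[, 3] - 0.5) * mask$spacing[3])
}

#' Mask volume
#' @param mask a [nucleus_mask()].
#' @return Volume in cubic micrometres (voxel count times voxel volume).
#' @export
mask_volume <- function(mask) {
  sum(mask$data) * prod(mask$spacing)
}

# diagonal of the foreground bounding box, in um
mask_bbox_diagonal <- function(mask) {
  idx <- which(mask$data)
  if (length(idx) == 0) stop("empty mask")
  ai <- arrayInd(idx, dim(mask$data))
  ext <- (apply(ai, 2, max) - apply(ai, 2, min) + 1) * mask$spacing
  sqrt(sum(ext^2))
}

stopifnot_grid <- function(x) {
  if (!inherits(x, "voxel_grid")) stop("expected a voxel_grid")
  invisible(x)
}

stopifnot_mask <- function(x) {
  if (!inherits(x, "nucleus_mask")) stop("expected a nucleus_mask")
  invisible(x)
}
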
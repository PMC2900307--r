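# Nuclear morphometry: volume, surface area, compactness, principal axes,
# flatness, elongation and main flattening/elongation directions.

#' Compactness (sphericity index)
#'
#' `C = 36 * pi * V^2 / S^3`. Takes its maximum value 1 for a sphere and
#' decreases toward 0 as the surface becomes less regular; dimensionless and
#' scale-invariant.
#'
#' @param V volume in um^3.
#' @param S surface area in um^2.
#' @export
compactness <- function(V, S) {
  if (!is.finite(V) || !is.finite(S) || V <= 0 || S <= 0)
    stop("V and S must be positive")
  36 * pi * V^2 / S^3
}

#' Principal axes of a mask
#'
#' Eigen-decomposition of the covariance matrix of foreground voxel center
#' coordinates (in micrometres). The axis length along eigenvector k is the
#' full axis of the uniform ellipsoid with the same covariance,
#' `2 * sqrt(5 * lambda_k)`, sorted in decreasing order.
#'
#' @param mask a [nucleus_mask()] with at least 4 foreground voxels.
#' @return List with `lengths` (decreasing, um) and `directions` (3x3 matrix,
#'   unit eigenvectors as columns matching `lengths`).
#' @export
principal_axes <- function(mask) {
  co <- fg_coords(mask)
  if (nrow(co) < 4) stop("mask too small for principal axes (< 4 voxels)")
  cv <- stats::cov(co)
  e <- eigen(cv, symmetric = TRUE)
  lens <- 2 * sqrt(5 * pmax(e$values, 0))
  list(lengths = lens, directions = e$vectors)
}

#' Flatness and elongation from sorted axis lengths
#'
#' Flatness is the ratio of the intermediate to the shortest axis length;
#' elongation the ratio of the longest to the intermediate. Both are >= 1
#' and invariant to uniform scaling and rigid rotation.
#'
#' @param lengths axis lengths sorted in decreasing order.
#' @export
shape_indices <- function(lengths) {
  if (length(lengths) != 3) stop("need 3 axis lengths")
  if (lengths[3] <= 0) stop("zero shortest axis")
  list(flatness = lengths[2] / lengths[3],
       elongation = lengths[1] / lengths[2])
}

#' Main flattening and elongation directions
#'
#' The flattening (resp. elongation) axis is the coordinate-frame axis
#' closest (largest absolute cosine) to the shortest (resp. longest)
#' principal axis. Ties break toward the earlier axis in (X, Y, Z) order.
#'
#' @param directions 3x3 matrix of unit eigenvectors (columns sorted by
#'   decreasing axis length).
#' @return List with `flattening_axis` and `elongation_axis` in
#'   `c("X","Y","Z")`.
#' @export
main_axis_assignment <- function(directions) {
  axes <- c("X", "Y", "Z")
  closest <- function(v) axes[which.max(abs(v))]
  list(flattening_axis = closest(directions[, 3]),
       elongation_axis = closest(directions[, 1]))
}

#' Full morphometric record for one nucleus
#'
#' @param mask a [nucleus_mask()].
#' @param ... passed to [nuclear_surface()] (e.g. `smooth_sigma`).
#' @return One-row data.frame: volume, surface, compactness, the three axis
#'   lengths, flatness, elongation, and the flattening/elongation axes.
#' @export
morphometry <- function(mask, ...) {
  V <- mask_volume(mask)
  mesh <- nuclear_surface(mask, ...)
  S <- mesh$area
  ax <- principal_axes(mask)
  si <- shape_indices(ax$lengths)
  dir <- main_axis_assignment(ax$directions)
  data.frame(volume = V, surface = S, compactness = compactness(V, S),
             axis_long = ax$lengths[1], axis_mid = ax$lengths[2],
             axis_short = ax$lengths[3],
             flatness = si$flatness, elongation = si$elongation,
             flattening_axis = dir$flattening_axis,
             elongation_axis = dir$elongation_axis,
             stringsAsFactors = FALSE)
}
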
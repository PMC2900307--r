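# Intensity filtering primitives on calibrated 3D grids.

grid_dims <- function(g) dim(g$data)

apply_kernel <- function(g, fun) {
  d <- dim(g$data)
  out <- fun(as.numeric(g$data), d[1], d[2], d[3])
  voxel_grid(array(out, d), g$spacing)
}

#' 3D median filter
#' @param grid a [voxel_grid()].
#' @param radius neighborhood half-width in voxels (box window).
#' @export
median_filter <- function(grid, radius = 1L) {
  stopifnot_grid(grid)
  apply_kernel(grid, function(v, nx, ny, nz)
    cpp_median_filter(v, nx, ny, nz, as.integer(radius)))
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k / sum(k)
}

gaussian_deriv_kernel_1d <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  x <- -half:half
  g <- exp(-x^2 / (2 * sigma^2))
  k <- -x / sigma^2 * g
  # normalize so a unit ramp has unit derivative
  k / sum(-x * k) * 1
}

# per-axis sigmas in voxels; the z sigma is scaled by the spacing ratio so
# the physical smoothing scale matches the lateral one
sigma_voxels <- function(spacing, sigma_xy_vox) {
  c(sigma_xy_vox, sigma_xy_vox, sigma_xy_vox * spacing[1] / spacing[3])
}

#' Separable 3D Gaussian filter
#' @param grid a [voxel_grid()].
#' @param sigma smoothing scale in XY voxels; the axial sigma is scaled by
#'   the spacing ratio so smoothing is isotropic in physical units.
#' @export
gaussian_filter <- function(grid, sigma = 2) {
  stopifnot_grid(grid)
  if (sigma <= 0) return(grid)
  sig <- sigma_voxels(grid$spacing, sigma)
  d <- dim(grid$data)
  v <- as.numeric(grid$data)
  for (ax in 0:2)
    v <- cpp_convolve_axis(v, d[1], d[2], d[3],
                           gaussian_kernel_1d(sig[ax + 1]), ax)
  voxel_grid(array(v, d), grid$spacing)
}

#' Gaussian gradient magnitude
#'
#' Magnitude of the Gaussian-derivative gradient, in intensity units per
#' micrometre (each axis derivative is divided by the voxel spacing).
#'
#' @param grid a [voxel_grid()].
#' @param sigma derivative scale in XY voxels (axial scale follows the
#'   spacing ratio).
#' @export
gaussian_gradient_magnitude <- function(grid, sigma = 2) {
  stopifnot_grid(grid)
  sig <- sigma_voxels(grid$spacing, sigma)
  d <- dim(grid$data)
  v0 <- as.numeric(grid$data)
  acc <- numeric(length(v0))
  for (deriv_ax in 0:2) {
    v <- v0
    for (ax in 0:2) {
      k <- if (ax == deriv_ax) gaussian_deriv_kernel_1d(sig[ax + 1])
           else gaussian_kernel_1d(sig[ax + 1])
      v <- cpp_convolve_axis(v, d[1], d[2], d[3], k, ax)
    }
    acc <- acc + (v / grid$spacing[deriv_ax + 1])^2
  }
  voxel_grid(array(sqrt(acc), d), grid$spacing)
}

#' Grayscale area opening
#'
#' Removes bright structures whose flat zones are smaller than `min_volume`
#' cubic micrometres at every intensity level.
#'
#' @param grid a [voxel_grid()].
#' @param min_volume criterion in um^3.
#' @param connectivity 6 or 26.
#' @export
area_opening <- function(grid, min_volume, connectivity = 26L) {
  stopifnot_grid(grid)
  lambda <- max(1L, as.integer(round(min_volume / prod(grid$spacing))))
  apply_kernel(grid, function(v, nx, ny, nz)
    cpp_area_opening(v, nx, ny, nz, lambda, as.integer(connectivity)))
}

#' White top-hat by size
#'
#' Subtracts the area opening from the image, keeping only bright structures
#' smaller than `min_volume`; the large-scale background is removed and the
#' result is non-negative and pointwise bounded by the input.
#'
#' @inheritParams area_opening
#' @export
tophat_by_size <- function(grid, min_volume, connectivity = 26L) {
  op <- area_opening(grid, min_volume, connectivity)
  voxel_grid(grid$data - op$data, grid$spacing)
}

#' Regional maxima
#'
#' Labels the connected plateaus that are strictly higher than all their
#' neighbors (26-connectivity by default), restricted to `mask` when given.
#'
#' @param grid a [voxel_grid()].
#' @param mask optional [nucleus_mask()] restricting the search.
#' @param connectivity 6 or 26.
#' @return Integer label array of the same dimension (0 outside maxima).
#' @export
regional_maxima <- function(grid, mask = NULL, connectivity = 26L) {
  stopifnot_grid(grid)
  d <- dim(grid$data)
  m <- if (is.null(mask)) rep(TRUE, prod(d)) else as.logical(mask$data)
  lab <- cpp_regional_maxima(as.numeric(grid$data), m, d[1], d[2], d[3],
                             as.integer(connectivity))
  array(lab, d)
}

# grayscale reconstruction by dilation (marker under ceiling)
reconstruct_dilation <- function(marker, ceiling, dims, connectivity = 6L) {
  cpp_reconstruct(as.numeric(marker), as.numeric(ceiling),
                  dims[1], dims[2], dims[3], as.integer(connectivity))
}

# h-maxima seeds: regional maxima after suppressing maxima shallower than h
hmaxima_labels <- function(values, dims, h, mask, connectivity = 26L) {
  rec <- reconstruct_dilation(values - h, values, dims, 6L)
  cpp_regional_maxima(rec, mask, dims[1], dims[2], dims[3],
                      as.integer(connectivity))
}
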
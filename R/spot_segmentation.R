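# Centromeric spot detection in the CENP channel: enhancement, masking,
# the two thresholding recipes (count-constrained search for embryo nuclei,
# regional-maxima rule for mammary nuclei), and reduction to pattern points.

#' Spot detection parameters
#'
#' @param min_spot_volume smallest retained object, um^3 (default 0.02;
#'   strictly smaller objects are removed).
#' @param max_count upper bound on the object count in the incremental
#'   threshold search (default 44, the rabbit chromosome number).
#' @param dilation_radius nuclear-mask enlargement radius, um, compensating
#'   the axial elongation of spots by the point spread function.
#' @param tophat_volume size criterion of the top-hat background removal,
#'   um^3.
#' @param maxima_count number of brightest regional maxima entering the
#'   median (default 11).
#' @param maxima_divisor divisor of that median (default 4).
#' @param median_radius,gaussian_sigma denoising filter sizes (voxels).
#' @export
spot_params <- function(min_spot_volume = 0.02, max_count = 44L,
                        dilation_radius = 0.5, tophat_volume = 0.2,
                        maxima_count = 11L, maxima_divisor = 4,
                        median_radius = 1L, gaussian_sigma = 1) {
  stopifnot(min_spot_volume >= 0, max_count >= 1, maxima_count >= 1,
            maxima_divisor > 0)
  list(min_spot_volume = min_spot_volume, max_count = as.integer(max_count),
       dilation_radius = dilation_radius, tophat_volume = tophat_volume,
       maxima_count = as.integer(maxima_count),
       maxima_divisor = maxima_divisor,
       median_radius = as.integer(median_radius),
       gaussian_sigma = gaussian_sigma)
}

#' Enhance punctate spots
#'
#' Median filter, Gaussian filter, then a white top-hat by size (area
#' opening with a volume criterion) that removes any background structure
#' larger than `tophat_volume`. The output is integer-valued and
#' non-negative; a constant image degenerates to all zeros.
#'
#' @param grid raw spot channel, a [voxel_grid()].
#' @param params a [spot_params()].
#' @export
enhance_spots <- function(grid, params = spot_params()) {
  stopifnot_grid(grid)
  out <- grid
  if (params$median_radius > 0) out <- median_filter(out, params$median_radius)
  if (params$gaussian_sigma > 0)
    out <- gaussian_filter(out, params$gaussian_sigma)
  out <- tophat_by_size(out, params$tophat_volume)
  voxel_grid(pmax(round(out$data), 0), grid$spacing)
}

#' Restrict an enhanced spot image to the (enlarged) nucleus
#'
#' The nuclear mask is enlarged by a morphological dilation so that spots
#' protruding axially from the mask (a point-spread-function artifact) are
#' not truncated; intensities outside the enlarged mask are zeroed, and
#' connected objects strictly smaller than `min_spot_volume` are removed.
#'
#' @param enhanced output of [enhance_spots()].
#' @param mask the [nucleus_mask()].
#' @param params a [spot_params()].
#' @export
mask_and_filter <- function(enhanced, mask, params = spot_params()) {
  stopifnot_grid(enhanced); stopifnot_mask(mask)
  if (!any(mask$data)) stop("empty mask")
  dil <- dilate_ball(mask, params$dilation_radius)
  v <- enhanced$data
  v[!dil$data] <- 0
  lab <- array(cpp_label3d(v > 0, dim(v)[1], dim(v)[2], dim(v)[3], 26L),
               dim(v))
  if (max(lab) > 0L) {
    vol <- tabulate(lab[lab > 0L]) * prod(enhanced$spacing)
    sel <- which(lab > 0L)
    v[sel[vol[lab[sel]] < params$min_spot_volume]] <- 0
  }
  voxel_grid(v, enhanced$spacing)
}

# label objects at >= t with the minimum-volume filter applied
label_at_threshold <- function(v, spacing, t, min_volume) {
  d <- dim(v)
  lab <- array(cpp_label3d(v >= t, d[1], d[2], d[3], 26L), d)
  relabel(filter_small_components(lab, spacing, min_volume))
}

relabel <- function(labels) {
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (length(ids) == 0) return(labels)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  labels[labels > 0L] <- map[labels[labels > 0L]]
  labels
}

#' Count-constrained incremental threshold search
#'
#' Starting from a threshold of 1 and incrementing by 1, returns the
#' smallest integer threshold at which the image contains at most
#' `max_count` connected objects. The minimum-volume filter is applied
#' inside the search so that the count criterion refers to the countable
#' final objects. Used when per-image contrast precludes a fixed threshold
#' but the chromosome number bounds the expected count.
#'
#' @param enhanced_masked integer-valued [voxel_grid()] from
#'   [mask_and_filter()].
#' @param params a [spot_params()].
#' @return List with `threshold` and `labels` (integer array).
#' @export
threshold_search_max_count <- function(enhanced_masked,
                                       params = spot_params()) {
  stopifnot_grid(enhanced_masked)
  v <- enhanced_masked$data
  if (any(v != round(v))) stop("enhanced image must be integer-valued")
  top <- max(v)
  if (top < 1) {
    return(list(threshold = 1L, labels = array(0L, dim(v))))
  }
  for (t in seq_len(top + 1L)) {
    lab <- label_at_threshold(v, enhanced_masked$spacing, t,
                              params$min_spot_volume)
    if (max(lab) <= params$max_count)
      return(list(threshold = as.integer(t), labels = lab))
  }
  list(threshold = as.integer(top + 1L), labels = array(0L, dim(v)))
}

#' Regional-maxima threshold rule
#'
#' The threshold is the median intensity of the `maxima_count` brightest 3D
#' regional maxima (26-connectivity) divided by `maxima_divisor`; when fewer
#' maxima exist, the median of all available maxima is used. Connected
#' objects at or above the threshold are labeled and volume-filtered.
#'
#' @inheritParams threshold_search_max_count
#' @return List with `threshold` and `labels`.
#' @export
threshold_from_maxima <- function(enhanced_masked, params = spot_params()) {
  stopifnot_grid(enhanced_masked)
  v <- enhanced_masked$data
  d <- dim(v)
  maxlab <- cpp_regional_maxima(as.numeric(v), v > 0, d[1], d[2], d[3], 26L)
  nmax <- max(maxlab)
  if (nmax < 1) stop("no regional maximum in the image")
  peak_vals <- vapply(seq_len(nmax),
                      function(i) v[which(maxlab == i)[1]], numeric(1))
  top <- sort(peak_vals, decreasing = TRUE)
  top <- top[seq_len(min(params$maxima_count, length(top)))]
  thr <- median(top) / params$maxima_divisor
  lab <- label_at_threshold(v, enhanced_masked$spacing, thr,
                            params$min_spot_volume)
  list(threshold = thr, labels = lab)
}

#' Reduce labeled regions to a point pattern
#'
#' One point per labeled region at its center of gravity (intensity-weighted
#' over the region's voxels when an intensity grid is given, else the binary
#' centroid), in micrometres, ordered by label id. A center falling
#' marginally outside the nucleus mask (within one voxel) is clipped to the
#' nearest foreground voxel center; farther out is an error.
#'
#' @param labels integer label array.
#' @param grid optional intensity [voxel_grid()] for weighting.
#' @param mask the [nucleus_mask()]; also supplies the spacing.
#' @param weighted use intensity weighting (default `TRUE` when `grid`
#'   given).
#' @return A [point_pattern()].
#' @export
regions_to_pattern <- function(labels, grid = NULL, mask,
                               weighted = !is.null(grid)) {
  stopifnot_mask(mask)
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (length(ids) == 0) return(point_pattern(matrix(0, 0, 3)))
  spacing <- mask$spacing
  d <- dim(mask$data)
  pts <- t(vapply(ids, function(id) {
    vox <- which(labels == id)
    ai <- arrayInd(vox, d)
    w <- if (weighted && !is.null(grid)) grid$data[vox] else rep(1, length(vox))
    if (sum(w) <= 0) w <- rep(1, length(vox))
    colSums((ai - 0.5) * matrix(spacing, nrow(ai), 3, byrow = TRUE) * w) / sum(w)
  }, numeric(3)))
  # clip marginally outside centers into the mask
  for (i in seq_len(nrow(pts))) {
    vi <- pmin(pmax(round(pts[i, ] / spacing + 0.5), 1), d)
    if (!mask$data[vi[1], vi[2], vi[3]]) {
      fg <- fg_coords(mask)
      dd <- sqrt(colSums((t(fg) - pts[i, ])^2))
      j <- which.min(dd)
      if (dd[j] > max(spacing) * sqrt(3))
        stop("region center lies more than one voxel outside the mask")
      pts[i, ] <- fg[j, ]
    }
  }
  point_pattern(pts)
}
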
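# Nucleus segmentation: the three labeling regimes (HP1beta-labeled embryo
# stacks, DAPI rim-stained mammary stacks, DAPI-stained isolated plant
# nuclei) and the surface model of the nuclear envelope.

#' Nucleus segmentation parameters
#'
#' @param median_radius denoising median half-width, voxels.
#' @param gaussian_sigma denoising Gaussian scale, XY voxels.
#' @param min_nucleus_volume minimum retained nucleus volume, um^3.
#' @param closing_radius closing ball radius (um) bridging rim gaps in the
#'   DAPI path ("large round kernel").
#' @param opening_radius,closing_radius_at opening/closing ball radii (um)
#'   for the plant-path cleanup.
#' @param rats_sigma Gaussian-derivative scale (XY voxels) of the
#'   gradient-weighted threshold.
#' @param watershed_h depth (um) below which distance-map maxima are merged
#'   before seeding the watershed split (suppresses over-splitting).
#' @export
segmentation_params <- function(median_radius = 1L, gaussian_sigma = 2,
                                min_nucleus_volume = 200,
                                closing_radius = 1.0,
                                opening_radius = 0.2,
                                closing_radius_at = 0.2,
                                rats_sigma = 2,
                                watershed_h = NULL) {
  stopifnot(median_radius >= 0, gaussian_sigma >= 0,
            min_nucleus_volume >= 0, closing_radius >= 0,
            opening_radius >= 0, closing_radius_at >= 0)
  list(median_radius = as.integer(median_radius),
       gaussian_sigma = gaussian_sigma,
       min_nucleus_volume = min_nucleus_volume,
       closing_radius = closing_radius,
       opening_radius = opening_radius,
       closing_radius_at = closing_radius_at,
       rats_sigma = rats_sigma,
       watershed_h = watershed_h)
}

#' Gradient-weighted automatic threshold (RATS)
#'
#' Robust automatic threshold selection: the mean of the image intensities
#' weighted by their Gaussian gradient magnitude,
#' `t = sum(I * |grad I|) / sum(|grad I|)`. The weights concentrate on the
#' object boundary, so the threshold lands mid-edge regardless of the
#' relative object/background sizes; it is invariant to blurring scale on a
#' two-valued phantom.
#'
#' @param grid a [voxel_grid()], ideally pre-cleaned of small bright/dark
#'   interior structure.
#' @param sigma gradient scale in XY voxels.
#' @return The threshold intensity.
#' @export
rats_threshold <- function(grid, sigma = 2) {
  stopifnot_grid(grid)
  g <- gaussian_gradient_magnitude(grid, sigma)
  w <- sum(g$data)
  if (!is.finite(w) || w <= 1e-12 * length(g$data))
    stop("no edges: total gradient magnitude is zero (constant image?)")
  sum(grid$data * g$data) / w
}

# denoise with median then Gaussian filters
denoise <- function(grid, params) {
  out <- grid
  if (params$median_radius > 0) out <- median_filter(out, params$median_radius)
  if (params$gaussian_sigma > 0) out <- gaussian_filter(out, params$gaussian_sigma)
  out
}

# split touching binary objects by a watershed on the inside distance map,
# seeded at h-maxima of the map
watershed_split <- function(binary, spacing, h = NULL) {
  d <- dim(binary)
  m <- nucleus_mask(binary, spacing)
  if (!any(binary)) return(array(0L, d))
  dmap <- distance_map(m, inside = TRUE)
  if (is.null(h)) h <- max(spacing) # one voxel step on the coarsest axis
  seeds <- hmaxima_labels(as.numeric(dmap), d, h, as.logical(binary))
  array(cpp_watershed(as.numeric(-dmap), seeds, as.logical(binary),
                      d[1], d[2], d[3], 6L), d)
}

#' Segment nuclei from an HP1beta-labeled stack
#'
#' Denoises (median + Gaussian), binarizes at the gradient-weighted
#' threshold, separates touching nuclei by a watershed on the distance map,
#' and removes nuclei truncated at the image border (any of the six faces)
#' as well as objects smaller than `min_nucleus_volume` (default 200 um^3).
#'
#' @param grid a [voxel_grid()] (nuclear channel).
#' @param params a [segmentation_params()].
#' @return List of [nucleus_mask()], possibly empty.
#' @export
segment_nuclei_hp1 <- function(grid, params = segmentation_params()) {
  stopifnot_grid(grid)
  den <- denoise(grid, params)
  thr <- rats_threshold(den, params$rats_sigma)
  binary <- den$data >= thr
  labels <- watershed_split(binary, grid$spacing, params$watershed_h)
  drop <- labels_touching_border(labels)
  labels[labels %in% drop] <- 0L
  labels <- filter_small_components(labels, grid$spacing,
                                    params$min_nucleus_volume)
  labels_to_masks(labels, grid$spacing)
}

#' Segment nuclei from a rim-stained DAPI stack
#'
#' The DAPI signal of mammary nuclei concentrates at the nuclear rim, so a
#' plain threshold yields a broken shell. The recipe closes the rim with a
#' ball kernel, fills the interior with a binary hole filling, and separates
#' touching nuclei with a watershed on the distance map. The threshold is
#' supplied by the caller (the original procedure is interactive), and so is
#' any selection among the returned nuclei.
#'
#' @param grid a [voxel_grid()] (DAPI channel).
#' @param manual_threshold intensity threshold.
#' @param params a [segmentation_params()]; `closing_radius` (um) must be
#'   large enough to bridge rim gaps, else components stay fragmented.
#' @return List of [nucleus_mask()].
#' @export
segment_nucleus_dapi <- function(grid, manual_threshold,
                                 params = segmentation_params()) {
  stopifnot_grid(grid)
  den <- denoise(grid, params)
  m <- nucleus_mask(den$data >= manual_threshold, grid$spacing)
  m <- close_ball(m, params$closing_radius)
  m <- fill_holes(m)
  labels <- watershed_split(m$data, grid$spacing, params$watershed_h)
  labels_to_masks(labels, grid$spacing)
}

#' Segment a single plant nucleus (isodata with mean - 2 SD correction)
#'
#' For stacks containing one nucleus: the stack is cropped to a bounding box
#' around a preliminary foreground, a preliminary threshold is computed with
#' the isodata algorithm, and -- because that threshold is biased upward by
#' the dominant background -- the final threshold is set to `m - 2s`, where
#' `m` and `s` are the mean and standard deviation of the intensities over
#' the preliminary foreground. Hole filling, opening and closing then
#' regularize the binary image, and the largest connected component is kept.
#'
#' @param grid a [voxel_grid()] (DAPI channel, one nucleus).
#' @param params a [segmentation_params()].
#' @param crop_margin margin (voxels) kept around the preliminary bounding
#'   box.
#' @return List with `mask` (a [nucleus_mask()] in the cropped frame),
#'   `correction` (list `m`, `s`, `corrected_threshold`), and `bbox`
#'   (index ranges of the crop in the input frame).
#' @export
segment_nucleus_arabidopsis <- function(grid, params = segmentation_params(),
                                        crop_margin = 4L) {
  stopifnot_grid(grid)
  den <- denoise(grid, params)
  t_pre0 <- isodata_threshold(den$data)
  fg0 <- which(den$data >= t_pre0, arr.ind = TRUE)
  if (nrow(fg0) == 0) stop("empty preliminary foreground")
  d <- dim(den$data)
  bbox <- lapply(1:3, function(a)
    max(1L, min(fg0[, a]) - crop_margin):min(d[a], max(fg0[, a]) + crop_margin))
  cropped <- den$data[bbox[[1]], bbox[[2]], bbox[[3]], drop = FALSE]

  t_pre <- isodata_threshold(cropped)
  pre_mask <- cropped >= t_pre
  if (!any(pre_mask)) stop("empty preliminary foreground")
  m <- mean(cropped[pre_mask])
  s <- sd(cropped[pre_mask])
  if (!is.finite(s)) s <- 0
  t_cor <- m - 2 * s
  mask <- nucleus_mask(cropped >= t_cor, grid$spacing)
  mask <- fill_holes(mask)
  if (params$opening_radius > 0) mask <- open_ball(mask, params$opening_radius)
  if (params$closing_radius_at > 0)
    mask <- close_ball(mask, params$closing_radius_at)
  labels <- label_components(mask, 26L)
  if (max(labels) > 0L) {
    keep <- which.max(tabulate(labels[labels > 0L]))
    mask <- nucleus_mask(labels == keep, grid$spacing)
  }
  list(mask = mask,
       correction = list(m = m, s = s, corrected_threshold = t_cor),
       bbox = bbox)
}

#' Isodata threshold
#'
#' Iterative intermeans: the threshold is moved to the midpoint of the two
#' class means until stable; ties resolve toward the lower threshold.
#'
#' @param x numeric vector or array of intensities.
#' @export
isodata_threshold <- function(x) {
  x <- as.numeric(x)
  t <- mean(range(x))
  for (i in 1:200) {
    lo <- x[x <= t]
    hi <- x[x > t]
    if (length(lo) == 0 || length(hi) == 0) break
    tn <- (mean(lo) + mean(hi)) / 2
    if (abs(tn - t) < 1e-9 * max(1, abs(t))) { t <- min(t, tn); break }
    t <- tn
  }
  t
}
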
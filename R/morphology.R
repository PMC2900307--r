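# Binary morphology with Euclidean (ball) structuring elements, implemented
# through the exact anisotropic distance transform, plus hole filling and
# connected-component utilities.

#' Euclidean distance map
#'
#' Distance (um) from every voxel to the nearest voxel of the feature set.
#' With `inside = TRUE` the feature set is the mask complement, giving the
#' distance from each foreground voxel to the background.
#'
#' @param mask a [nucleus_mask()].
#' @param inside if `TRUE`, distance to background measured inside the mask.
#' @return Numeric array of distances in micrometres.
#' @export
distance_map <- function(mask, inside = TRUE) {
  stopifnot_mask(mask)
  d <- dim(mask$data)
  feat <- if (inside) !mask$data else mask$data
  array(cpp_edt(as.logical(feat), d[1], d[2], d[3],
                mask$spacing[1], mask$spacing[2], mask$spacing[3]), d)
}

edt_from_feature <- function(feature, dims, spacing) {
  array(cpp_edt(as.logical(feature), dims[1], dims[2], dims[3],
                spacing[1], spacing[2], spacing[3]), dims)
}

#' Binary dilation / erosion / opening / closing with a ball
#'
#' The structuring element is a Euclidean ball of radius `r` micrometres
#' (exact under anisotropic spacing, via the distance transform).
#'
#' @param mask a [nucleus_mask()].
#' @param r ball radius in micrometres.
#' @export
dilate_ball <- function(mask, r) {
  stopifnot_mask(mask)
  if (r <= 0) return(mask)
  d <- edt_from_feature(mask$data, dim(mask$data), mask$spacing)
  nucleus_mask(d <= r, mask$spacing)
}

#' @rdname dilate_ball
#' @export
erode_ball <- function(mask, r) {
  stopifnot_mask(mask)
  if (r <= 0) return(mask)
  d <- edt_from_feature(!mask$data, dim(mask$data), mask$spacing)
  nucleus_mask(mask$data & d > r, mask$spacing)
}

#' @rdname dilate_ball
#' @export
open_ball <- function(mask, r) dilate_ball(erode_ball(mask, r), r)

#' @rdname dilate_ball
#' @export
close_ball <- function(mask, r) erode_ball(dilate_ball(mask, r), r)

#' Fill interior holes of a binary mask
#'
#' Background components not connected (6-connectivity) to the array border
#' are turned into foreground.
#'
#' @param mask a [nucleus_mask()].
#' @export
fill_holes <- function(mask) {
  stopifnot_mask(mask)
  d <- dim(mask$data)
  bg <- !mask$data
  lab <- array(cpp_label3d(as.logical(bg), d[1], d[2], d[3], 6L), d)
  border_labels <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                            lab[, , c(1, d[3])]))
  border_labels <- setdiff(border_labels, 0L)
  holes <- bg & !(lab %in% border_labels)
  nucleus_mask(mask$data | array(holes, d), mask$spacing)
}

#' Label connected components
#' @param mask a [nucleus_mask()] (or logical array with `spacing`).
#' @param connectivity 6 or 26.
#' @return Integer label array (0 = background), labels in scan order.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot_mask(mask)
  d <- dim(mask$data)
  array(cpp_label3d(as.logical(mask$data), d[1], d[2], d[3],
                    as.integer(connectivity)), d)
}

# drop labeled components whose physical volume is below min_volume (um^3);
# returns the filtered label array (original ids kept)
filter_small_components <- function(labels, spacing, min_volume) {
  if (max(labels) == 0L) return(labels)
  vol <- tabulate(labels) * prod(spacing)
  keep <- which(vol >= min_volume)
  labels[!(labels %in% keep)] <- 0L
  labels
}

# TRUE for labels touching any face of the array
labels_touching_border <- function(labels) {
  d <- dim(labels)
  setdiff(unique(c(labels[c(1, d[1]), , ], labels[, c(1, d[2]), ],
                   labels[, , c(1, d[3])])), 0L)
}

# split a label array into one nucleus_mask per label id (ascending)
labels_to_masks <- function(labels, spacing) {
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  lapply(ids, function(id) nucleus_mask(labels == id, spacing))
}
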
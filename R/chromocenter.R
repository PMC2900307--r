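# Chromocenter detection in DAPI-stained plant nuclei: watershed partition
# of the nucleus, region-adjacency-graph merging and closing, and a
# shape/contrast index separating the bright compact chromocenters from
# other regions (including the dark nucleolus).

#' Watershed partition of a nucleus into a region adjacency graph
#'
#' The nucleus is partitioned by a 3D watershed of the Gaussian gradient
#' magnitude (flooded from its regional minima, restricted to the mask).
#' Each region is assigned a value equal to the average intensity in a ball
#' neighborhood around its barycenter, its voxel count, and its adjacency
#' (6-connectivity contacts) to the other regions.
#'
#' @param grid the DAPI [voxel_grid()].
#' @param mask the [nucleus_mask()].
#' @param sigma gradient scale in XY voxels.
#' @param neighborhood_radius ball radius (um) of the barycenter
#'   neighborhood used for the region value.
#' @return A `region_graph`: list with `labels` (integer array), `value`,
#'   `size` (voxel counts), `adjacency` (list of neighbor ids), `spacing`.
#' @export
watershed_partition <- function(grid, mask, sigma = 2,
                                neighborhood_radius = 0.15) {
  stopifnot_grid(grid); stopifnot_mask(mask)
  if (!any(mask$data)) stop("empty mask")
  d <- dim(grid$data)
  gm <- gaussian_gradient_magnitude(grid, sigma)
  seeds <- cpp_regional_maxima(-as.numeric(gm$data), as.logical(mask$data),
                               d[1], d[2], d[3], 26L)
  labels <- array(cpp_watershed(as.numeric(gm$data), seeds,
                                as.logical(mask$data), d[1], d[2], d[3], 6L),
                  d)
  labels <- relabel(labels)
  n <- max(labels)
  size <- tabulate(labels[labels > 0L], n)
  value <- vapply(seq_len(n), function(id)
    region_neighborhood_value(grid, labels, id, neighborhood_radius),
    numeric(1))
  structure(list(labels = labels, value = value, size = size,
                 adjacency = adjacency_from_labels(labels),
                 spacing = grid$spacing),
            class = "region_graph")
}

# mean intensity in a ball around the region's barycenter (clipped to the
# labeled partition so the value reflects in-nucleus signal)
region_neighborhood_value <- function(grid, labels, id, radius) {
  d <- dim(labels)
  vox <- which(labels == id)
  ai <- arrayInd(vox, d)
  bc <- colMeans(ai)
  rv <- pmax(1, round(radius / grid$spacing))
  rng <- lapply(1:3, function(a)
    max(1, round(bc[a]) - rv[a]):min(d[a], round(bc[a]) + rv[a]))
  sub <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  dd <- sweep(sub, 2, bc) %*% diag(grid$spacing)
  keep <- rowSums(dd^2) <= max(radius, max(grid$spacing))^2
  sub <- sub[keep, , drop = FALSE]
  inlab <- labels[sub] > 0L
  if (!any(inlab)) return(mean(grid$data[vox]))
  mean(grid$data[sub[inlab, , drop = FALSE]])
}

# symmetric adjacency list from 6-neighbor label contacts
adjacency_from_labels <- function(labels) {
  n <- max(labels)
  pairs <- NULL
  d <- dim(labels)
  for (ax in 1:3) {
    idx_a <- lapply(seq_along(d), function(a)
      if (a == ax) seq_len(d[a] - 1L) else seq_len(d[a]))
    idx_b <- lapply(seq_along(d), function(a)
      if (a == ax) 1L + seq_len(d[a] - 1L) else seq_len(d[a]))
    a <- labels[idx_a[[1]], idx_a[[2]], idx_a[[3]]]
    b <- labels[idx_b[[1]], idx_b[[2]], idx_b[[3]]]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel))
      pairs <- rbind(pairs, unique(cbind(pmin(a[sel], b[sel]),
                                         pmax(a[sel], b[sel]))))
  }
  adj <- rep(list(integer(0)), n)
  if (!is.null(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      adj[[pairs[i, 1]]] <- c(adj[[pairs[i, 1]]], pairs[i, 2])
      adj[[pairs[i, 2]]] <- c(adj[[pairs[i, 2]]], pairs[i, 1])
    }
    adj <- lapply(adj, function(x) sort(unique(x)))
  }
  adj
}

#' Merge adjacent regions with similar values
#'
#' Repeatedly merges the adjacent pair with the smallest absolute value
#' difference while that difference is below `merge_threshold` (ties break
#' toward the smallest label pair). The merged value is the size-weighted
#' mean; the merged region keeps the smaller id. Terminates after at most
#' (number of regions - 1) merges, leaving every adjacent difference at or
#' above the threshold. Corrects watershed over-segmentation of
#' chromocenters and nucleoli.
#'
#' @param graph a `region_graph`.
#' @param merge_threshold value-difference threshold (intensity units).
#' @export
merge_regions <- function(graph, merge_threshold) {
  value <- graph$value
  size <- as.numeric(graph$size)
  adj <- graph$adjacency
  n <- length(value)
  root <- seq_len(n)
  active <- rep(TRUE, n)
  repeat {
    best <- NULL
    best_diff <- merge_threshold
    for (a in which(active)) {
      for (b in adj[[a]]) {
        if (b <= a) next
        dif <- abs(value[a] - value[b])
        # ascending (a, b) scan: the first pair at the minimum difference
        # wins, giving the smallest-label tie-break
        if (dif < best_diff) {
          best <- c(a, b)
          best_diff <- dif
        }
      }
    }
    if (is.null(best)) break
    a <- best[1]; b <- best[2]
    value[a] <- (size[a] * value[a] + size[b] * value[b]) / (size[a] + size[b])
    size[a] <- size[a] + size[b]
    adj[[a]] <- setdiff(sort(unique(c(adj[[a]], adj[[b]]))), c(a, b))
    for (x in adj[[b]]) adj[[x]] <- sort(unique(c(setdiff(adj[[x]], b),
                                                  if (x != a) a)))
    adj[[b]] <- integer(0)
    active[b] <- FALSE
    root[root == b] <- a
  }
  labels <- graph$labels
  labels[labels > 0L] <- root[labels[labels > 0L]]
  labels <- relabel(labels)
  ids <- which(active)
  structure(list(labels = labels, value = value[ids], size = size[ids],
                 adjacency = remap_adjacency(adj[ids], ids),
                 spacing = graph$spacing),
            class = "region_graph")
}

remap_adjacency <- function(adj, ids) {
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  lapply(adj, function(x) sort(map[x]))
}

#' Morphological closing on the region adjacency graph
#'
#' Grayscale closing of the region values over the adjacency structure:
#' each region's value is replaced by the minimum, over its closed
#' neighborhood, of the neighborhood maxima (a dilation followed by an
#' erosion, self included). Dark basins such as the nucleolus are raised to
#' their surroundings, so they stop inflating the contrast of adjacent
#' non-chromocenter regions. Extensive: no value decreases.
#'
#' @param graph a `region_graph`.
#' @export
region_closing <- function(graph) {
  v <- graph$value
  n <- length(v)
  nb <- lapply(seq_len(n), function(i) c(i, graph$adjacency[[i]]))
  dil <- vapply(seq_len(n), function(i) max(v[nb[[i]]]), numeric(1))
  clo <- vapply(seq_len(n), function(i) min(dil[nb[[i]]]), numeric(1))
  graph$value <- clo
  graph
}

#' Shape/contrast score of every region
#'
#' The contrast of a region is the average difference between its value and
#' those of its neighbors, weighted by the neighbor sizes (limiting the
#' influence of small extreme regions); a region with no neighbor has
#' contrast 0. The index is the contrast multiplied by the region's
#' compactness (same `36 pi V^2 / S^3` form as nuclear morphometry, surface
#' from the region's own mesh), which enhances the compact ellipsoidal
#' chromocenters over irregular regions of similar contrast.
#'
#' @param graph a `region_graph`.
#' @return data.frame with columns `id`, `contrast`, `compactness`, `index`.
#' @export
score_regions <- function(graph) {
  n <- length(graph$value)
  contrast <- vapply(seq_len(n), function(i) {
    nb <- graph$adjacency[[i]]
    if (length(nb) == 0) return(0)
    w <- as.numeric(graph$size[nb])
    sum(w * (graph$value[i] - graph$value[nb])) / sum(w)
  }, numeric(1))
  comp <- vapply(seq_len(n), function(i)
    region_compactness(graph$labels, i, graph$spacing), numeric(1))
  data.frame(id = seq_len(n), contrast = contrast, compactness = comp,
             index = contrast * comp)
}

region_compactness <- function(labels, id, spacing) {
  d <- dim(labels)
  vox <- which(labels == id)
  ai <- arrayInd(vox, d)
  rng <- lapply(1:3, function(a) min(ai[, a]):max(ai[, a]))
  sub <- array(FALSE, vapply(rng, length, integer(1)))
  sub[cbind(ai[, 1] - min(ai[, 1]) + 1L, ai[, 2] - min(ai[, 2]) + 1L,
            ai[, 3] - min(ai[, 3]) + 1L)] <- TRUE
  m <- nucleus_mask(sub, spacing)
  mesh <- nuclear_surface(m, smooth_sigma = 1)
  min(compactness(mask_volume(m), mesh$area), 1)
}

#' Extract chromocenters from scored regions
#'
#' Regions whose shape/contrast index reaches `index_threshold` become
#' chromocenters (minus any ids on the exclusion list, the file-based
#' replacement of interactive false-positive removal). Each chromocenter
#' contributes a pattern point at its center of gravity carrying its
#' equivalent spherical radius `(3V / 4 pi)^(1/3)`.
#'
#' @param graph a `region_graph`.
#' @param scores output of [score_regions()].
#' @param index_threshold selection threshold on the index.
#' @param grid optional intensity grid for weighted centers of gravity.
#' @param exclude integer region ids to drop (identified false positives).
#' @return List with `labels` (relabeled 1..m) and `pattern` (a
#'   [point_pattern()] with radii).
#' @export
extract_chromocenters <- function(graph, scores, index_threshold,
                                  grid = NULL, exclude = integer(0)) {
  sel <- scores$id[scores$index >= index_threshold]
  sel <- setdiff(sel, exclude)
  labels <- graph$labels
  labels[!(labels %in% sel)] <- 0L
  labels <- relabel(labels)
  if (max(labels) == 0L)
    return(list(labels = labels,
                pattern = point_pattern(matrix(0, 0, 3), numeric(0))))
  mask <- nucleus_mask(graph$labels > 0L, graph$spacing)
  pat <- regions_to_pattern(labels, grid = grid, mask = mask)
  vols <- tabulate(labels[labels > 0L]) * prod(graph$spacing)
  pat$radii <- (3 * vols / (4 * pi))^(1 / 3)
  list(labels = labels, pattern = pat)
}
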
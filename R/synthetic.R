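# Ground-truthed synthetic nuclei: masks, point patterns and rendered image
# stacks emulating the three imaged systems (HP1beta/CENP-labeled embryo
# nuclei, DAPI rim-stained mammary nuclei, DAPI-stained plant nuclei), so
# the full pipeline is testable without any image download.

#' Phantom specification
#'
#' Defaults emulate a mid-sized imaged nucleus: a 5 um-radius nucleus
#' sampled at 0.1 um laterally and 0.24 um axially, some tens of points,
#' an anisotropic Gaussian point spread (wider axially, which pushes
#' peripheral spots partly outside the mask as in real confocal stacks),
#' and additive Gaussian noise.
#'
#' @param shape one of `"sphere"`, `"ellipsoid"`, `"invaginated"`,
#'   `"elongated"`.
#' @param semi_axes ellipsoid semi-axes (um); a single value for a sphere.
#' @param spacing voxel spacing (um).
#' @param pattern_model `"crbpp"`, `"hardcore"` or `"cluster"`.
#' @param k number of points.
#' @param hardcore_radii radii (um) for the hardcore model (recycled to k).
#' @param cluster_count,cluster_sigma parents and Gaussian spread (um) of
#'   the cluster model.
#' @param spot_sigma_xy,spot_sigma_z anisotropic point-spread sigmas (um).
#' @param background_level,spot_amplitude,nuclear_amplitude,noise_sigma
#'   rendering intensities.
#' @param rim_weighted render the nuclear channel as a bright rim (the
#'   mammary DAPI regime) instead of a filled volume.
#' @param seed optional seed fixing the phantom.
#' @export
phantom_spec <- function(shape = c("sphere", "ellipsoid", "invaginated",
                                   "elongated"),
                         semi_axes = 5, spacing = c(0.1, 0.1, 0.24),
                         pattern_model = c("crbpp", "hardcore", "cluster"),
                         k = 20L, hardcore_radii = 0.5,
                         cluster_count = 3L, cluster_sigma = 0.5,
                         spot_sigma_xy = 0.1, spot_sigma_z = 0.3,
                         background_level = 20, spot_amplitude = 200,
                         nuclear_amplitude = 100, noise_sigma = 4,
                         rim_weighted = FALSE, seed = NULL) {
  shape <- match.arg(shape)
  pattern_model <- match.arg(pattern_model)
  if (length(semi_axes) == 1) semi_axes <- rep(semi_axes, 3)
  if (shape == "elongated" && length(unique(semi_axes)) == 1)
    semi_axes <- semi_axes * c(2.6, 1, 1)
  stopifnot(k >= 0, pattern_model != "cluster" || cluster_count <= k,
            all(spacing > 0),
            all(semi_axes > 0))
  structure(list(shape = shape, semi_axes = semi_axes, spacing = spacing,
                 pattern_model = pattern_model, k = as.integer(k),
                 hardcore_radii = hardcore_radii,
                 cluster_count = as.integer(cluster_count),
                 cluster_sigma = cluster_sigma,
                 spot_sigma_xy = spot_sigma_xy, spot_sigma_z = spot_sigma_z,
                 background_level = background_level,
                 spot_amplitude = spot_amplitude,
                 nuclear_amplitude = nuclear_amplitude,
                 noise_sigma = noise_sigma, rim_weighted = rim_weighted,
                 seed = seed),
            class = "phantom_spec")
}

#' Voxelized nucleus mask of a phantom
#'
#' Ellipsoid voxelization at the requested (anisotropic) spacing; the
#' invaginated variant carves 1-3 smooth spherical lobes into the boundary
#' (mimicking deep nuclear invaginations); the elongated variant is a
#' high-aspect ellipsoid. Deterministic for a fixed spec (the lobes use the
#' spec seed).
#'
#' @param spec a [phantom_spec()].
#' @param margin clearance (um) between the ellipsoid and the array border.
#' @return A [nucleus_mask()].
#' @export
make_mask <- function(spec, margin = 0.5) {
  s <- spec$spacing
  a <- spec$semi_axes
  dims <- pmax(ceiling(2 * (a + margin) / s), 4L)
  cen <- dims / 2 * s
  cx <- ((seq_len(dims[1]) - 0.5) * s[1] - cen[1]) / a[1]
  cy <- ((seq_len(dims[2]) - 0.5) * s[2] - cen[2]) / a[2]
  cz <- ((seq_len(dims[3]) - 0.5) * s[3] - cen[3]) / a[3]
  q <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  m <- q <= 1
  if (spec$shape == "invaginated") {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    nlobe <- sample(1:3, 1)
    for (i in seq_len(nlobe)) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      lc <- cen + u * a # lobe centered on the boundary
      lr <- 0.45 * min(a)
      lx <- ((seq_len(dims[1]) - 0.5) * s[1] - lc[1])^2
      ly <- ((seq_len(dims[2]) - 0.5) * s[2] - lc[2])^2
      lz <- ((seq_len(dims[3]) - 0.5) * s[3] - lc[3])^2
      m <- m & (outer(outer(lx, ly, "+"), lz, "+") > lr^2)
    }
  }
  if (!any(m)) stop("mask empty at the given spacing")
  nucleus_mask(m, s)
}

#' Ground-truthed point pattern in a phantom nucleus
#'
#' `crbpp` places points uniformly and independently; `hardcore` enforces
#' the spec radii against other points and the envelope (rejection
#' sampling); `cluster` draws `cluster_count` uniform parents and scatters
#' the k offspring isotropically (Gaussian `cluster_sigma`) around them,
#' truncated to the mask.
#'
#' @param mask a [nucleus_mask()].
#' @param spec a [phantom_spec()].
#' @return List with `pattern` (a [point_pattern()]) and `parent` (integer
#'   parent labels; all 0 for non-cluster models).
#' @export
make_pattern <- function(mask, spec) {
  k <- spec$k
  if (spec$pattern_model == "crbpp") {
    pat <- sample_crbpp(mask, k)
    return(list(pattern = pat, parent = integer(k)))
  }
  if (spec$pattern_model == "hardcore") {
    radii <- rep_len(spec$hardcore_radii, k)
    pat <- sample_crbpp(mask, k, radii)
    return(list(pattern = pat, parent = integer(k)))
  }
  # cluster model
  parents <- sample_uniform_in_mask(mask, spec$cluster_count)
  assign <- sample.int(spec$cluster_count, k, replace = TRUE)
  d <- dim(mask$data)
  pts <- matrix(NA_real_, k, 3)
  for (i in seq_len(k)) {
    for (try in 1:10000) {
      p <- parents[assign[i], ] + rnorm(3, sd = spec$cluster_sigma)
      vi <- pmin(pmax(round(p / mask$spacing + 0.5), 1), d)
      if (mask$data[vi[1], vi[2], vi[3]]) { pts[i, ] <- p; break }
    }
    if (is.na(pts[i, 1])) stop("cluster offspring sampling failed")
  }
  list(pattern = point_pattern(pts), parent = assign)
}

#' Render synthetic nuclear and spot channels
#'
#' The nuclear channel is the mask at `nuclear_amplitude` (or, when
#' `rim_weighted`, an exponential rim profile emulating peripheral DAPI)
#' over `background_level`, plus Gaussian noise. The spot channel adds one
#' anisotropic Gaussian of amplitude `spot_amplitude` per pattern point
#' (sigma `spot_sigma_xy` laterally, `spot_sigma_z` axially, reproducing
#' the axial elongation of real point spread functions). Patterns carrying
#' radii are additionally rendered as bright spherical bodies in the
#' nuclear channel (the chromocenter regime). Intensities are clamped at 0
#' and rounded.
#'
#' @param mask a [nucleus_mask()].
#' @param pattern a [point_pattern()].
#' @param spec a [phantom_spec()].
#' @return List of two [voxel_grid()]: `nuclear` and `spots`.
#' @export
render_stack <- function(mask, pattern, spec) {
  s <- mask$spacing
  d <- dim(mask$data)
  nuc <- array(spec$background_level, d)
  if (spec$rim_weighted) {
    dmap <- distance_map(mask, inside = TRUE)
    rim <- exp(-pmax(dmap - s[1], 0) / 0.3)
    nuc <- nuc + spec$nuclear_amplitude * rim * mask$data
  } else {
    nuc <- nuc + spec$nuclear_amplitude * mask$data
  }
  if (!is.null(pattern$radii) && npoints(pattern) > 0) {
    for (i in seq_len(npoints(pattern)))
      nuc <- add_ball(nuc, s, pattern$points[i, ], pattern$radii[i],
                      spec$spot_amplitude)
  }
  spots <- array(spec$background_level, d)
  if (npoints(pattern) > 0) {
    for (i in seq_len(npoints(pattern)))
      spots <- add_gaussian_spot(spots, s, pattern$points[i, ],
                                 spec$spot_amplitude,
                                 spec$spot_sigma_xy, spec$spot_sigma_z)
  }
  if (spec$noise_sigma > 0) {
    nuc <- nuc + rnorm(length(nuc), sd = spec$noise_sigma)
    spots <- spots + rnorm(length(spots), sd = spec$noise_sigma)
  }
  list(nuclear = voxel_grid(pmax(round(nuc), 0), s),
       spots = voxel_grid(pmax(round(spots), 0), s))
}

# add an anisotropic Gaussian of peak `amp` at point p (um) into arr
add_gaussian_spot <- function(arr, spacing, p, amp, sigma_xy, sigma_z) {
  d <- dim(arr)
  sig <- c(sigma_xy, sigma_xy, sigma_z)
  half <- ceiling(4 * sig / spacing)
  cv <- p / spacing + 0.5 # continuous voxel coordinate of the point
  rng <- lapply(1:3, function(a)
    max(1, floor(cv[a] - half[a])):min(d[a], ceiling(cv[a] + half[a])))
  if (any(vapply(rng, length, integer(1)) == 0)) return(arr)
  gx <- exp(-(((rng[[1]] - 0.5) * spacing[1] - p[1])^2) / (2 * sig[1]^2))
  gy <- exp(-(((rng[[2]] - 0.5) * spacing[2] - p[2])^2) / (2 * sig[2]^2))
  gz <- exp(-(((rng[[3]] - 0.5) * spacing[3] - p[3])^2) / (2 * sig[3]^2))
  arr[rng[[1]], rng[[2]], rng[[3]]] <-
    arr[rng[[1]], rng[[2]], rng[[3]]] + amp * outer(outer(gx, gy), gz)
  arr
}

# add a solid ball of intensity `amp` and radius r (um) at p
add_ball <- function(arr, spacing, p, r, amp) {
  d <- dim(arr)
  half <- ceiling(r / spacing) + 1
  cv <- p / spacing + 0.5
  rng <- lapply(1:3, function(a)
    max(1, floor(cv[a] - half[a])):min(d[a], ceiling(cv[a] + half[a])))
  bx <- ((rng[[1]] - 0.5) * spacing[1] - p[1])^2
  by <- ((rng[[2]] - 0.5) * spacing[2] - p[2])^2
  bz <- ((rng[[3]] - 0.5) * spacing[3] - p[3])^2
  inside <- outer(outer(bx, by, "+"), bz, "+") <= r^2
  arr[rng[[1]], rng[[2]], rng[[3]]] <-
    arr[rng[[1]], rng[[2]], rng[[3]]] + amp * inside
  arr
}

#' Simulate a full phantom (mask, pattern, rendered channels)
#'
#' Convenience wrapper: builds the mask, draws the ground-truth pattern and
#' renders both channels, seeding the RNG from the spec when set.
#'
#' @param spec a [phantom_spec()].
#' @return List with `mask`, `pattern`, `parent`, `nuclear`, `spots`.
#' @export
simulate_phantom <- function(spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  mask <- make_mask(spec)
  mp <- make_pattern(mask, spec)
  ch <- render_stack(mask, mp$pattern, spec)
  list(mask = mask, pattern = mp$pattern, parent = mp$parent,
       nuclear = ch$nuclear, spots = ch$spots)
}
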
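# Shared phantom builders for the test suite. Everything is generated in
# code; no fixture files.

# digitized ball mask centered in its array
ball_mask <- function(r_um, spacing, margin = 0.5) {
  make_mask(phantom_spec(shape = "sphere", semi_axes = r_um,
                         spacing = spacing), margin = margin)
}

# two-valued image: `fgv` inside the given spheres, `bg` outside
spheres_image <- function(dims, spacing, centers, radii, bg = 100,
                          fgv = 200, noise = 0) {
  xs <- (seq_len(dims[1]) - 0.5) * spacing[1]
  ys <- (seq_len(dims[2]) - 0.5) * spacing[2]
  zs <- (seq_len(dims[3]) - 0.5) * spacing[3]
  img <- array(bg, dims)
  for (i in seq_along(radii)) {
    cen <- centers[[i]]
    inside <- outer(outer((xs - cen[1])^2, (ys - cen[2])^2, "+"),
                    (zs - cen[3])^2, "+") <= radii[i]^2
    img[inside] <- fgv
  }
  if (noise > 0) img <- img + rnorm(length(img), 0, noise)
  voxel_grid(img, spacing)
}

# integer spot image: isolated cubic spots of side `side` voxels at given
# voxel corners, each with its own value, zero background
cube_spots_image <- function(dims, spacing, corners, values, side = 3L) {
  img <- array(0, dims)
  for (i in seq_len(nrow(corners))) {
    ix <- corners[i, 1] + seq_len(side) - 1L
    iy <- corners[i, 2] + seq_len(side) - 1L
    iz <- corners[i, 3] + seq_len(side) - 1L
    img[ix, iy, iz] <- values[i]
  }
  voxel_grid(img, spacing)
}

# hand-built region adjacency graph (labels laid out along x, adjacency as
# given; used to unit-test the graph operations in isolation)
test_graph <- function(values, sizes, edges, spacing = c(1, 1, 1)) {
  labels <- array(rep(seq_along(values), sizes), c(sum(sizes), 1, 1))
  adj <- rep(list(integer(0)), length(values))
  if (length(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- sort(unique(c(adj[[a]], b)))
      adj[[b]] <- sort(unique(c(adj[[b]], a)))
    }
  }
  structure(list(labels = labels, value = as.numeric(values),
                 size = as.integer(sizes), adjacency = adj,
                 spacing = spacing),
            class = "region_graph")
}

# the 44-spot centromere phantom used for the count-constrained search
render_centromere_phantom <- function(seed = 9, k = 44L, noise_sigma = 4) {
  set.seed(seed)
  spec <- phantom_spec(shape = "sphere", semi_axes = 6,
                       spacing = c(0.1, 0.1, 0.24),
                       pattern_model = "hardcore", k = k,
                       hardcore_radii = 0.5, spot_amplitude = 200,
                       background_level = 20, noise_sigma = noise_sigma)
  mask <- make_mask(spec)
  mp <- make_pattern(mask, spec)
  ch <- render_stack(mask, mp$pattern, spec)
  list(mask = mask, truth = mp$pattern, spots = ch$spots)
}

# plant nucleus with rendered chromocenters and a dark nucleolus placed in
# the largest empty region
render_plant_phantom <- function(seed = 21, k = 8L, cc_radius = 0.3,
                                 nucleolus_radius = 0.6) {
  set.seed(seed)
  spec <- phantom_spec(shape = "sphere", semi_axes = 2.5,
                       spacing = c(0.06, 0.06, 0.15),
                       pattern_model = "hardcore", k = k,
                       hardcore_radii = 0.5, nuclear_amplitude = 100,
                       background_level = 10, noise_sigma = 3,
                       spot_amplitude = 120)
  mask <- make_mask(spec)
  mp <- make_pattern(mask, spec)
  mp$pattern$radii <- rep(cc_radius, k)
  ch <- render_stack(mask, mp$pattern, spec)
  dmap <- distance_map(mask, inside = TRUE)
  fg <- nucspat:::fg_coords(mask)
  clearance <- pmin(nucspat:::cpp_min_dists(fg, mp$pattern$points),
                    dmap[mask$data])
  ncen <- fg[which.max(clearance), ]
  nuc <- nucspat:::add_ball(ch$nuclear$data, mask$spacing, ncen,
                            nucleolus_radius, -80)
  list(mask = mask, truth = mp$pattern,
       nuclear = voxel_grid(pmax(nuc, 0), mask$spacing),
       nucleolus_center = ncen)
}
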
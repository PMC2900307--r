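test_that("gradient-weighted threshold lands mid-edge and is blur-tolerant", {
  sp <- c(0.2, 0.2, 0.2)
  m <- ball_mask(4, sp)
  img <- voxel_grid(100 + 100 * m$data, sp)
  thr <- rats_threshold(img)
  expect_lt(abs(thr - 150), 5)
  # blurring the edge with a larger sigma barely moves the threshold
  thr_blur <- rats_threshold(gaussian_filter(img, 3))
  expect_lt(abs(thr_blur - thr), 5)
  expect_error(rats_threshold(voxel_grid(array(7, c(10, 10, 5)), sp)),
               "no edges")
})

test_that("HP1 recipe splits touching nuclei, drops border and small ones", {
  set.seed(31)
  sp <- c(0.2, 0.2, 0.3)
  # two overlapping r = 5 um spheres, centers 8 um apart
  img <- spheres_image(c(120, 70, 50), sp, list(c(7, 7, 7), c(15, 7, 7)),
                       c(5, 5), noise = 2)
  out <- segment_nuclei_hp1(img)
  expect_length(out, 2)
  for (msk in out)
    expect_equal(mask_volume(msk), 4 / 3 * pi * 125, tolerance = 0.05)
  # sphere clipped by the image border is removed
  img2 <- spheres_image(c(60, 60, 40), sp, list(c(1.5, 6, 5)), 5, noise = 2)
  expect_length(segment_nuclei_hp1(img2), 0)
  # object below the 200 um^3 volume cutoff is removed; above is kept
  r150 <- (3 * 150 / (4 * pi))^(1 / 3)
  r300 <- (3 * 300 / (4 * pi))^(1 / 3)
  img3 <- spheres_image(c(60, 60, 40), sp, list(c(6, 6, 5)), r150, noise = 2)
  expect_length(segment_nuclei_hp1(img3), 0)
  img4 <- spheres_image(c(60, 60, 40), sp, list(c(6, 6, 5)), r300, noise = 2)
  expect_length(segment_nuclei_hp1(img4), 1)
})

test_that("HP1 recipe is translation- and affine-intensity-invariant", {
  set.seed(32)
  sp <- c(0.2, 0.2, 0.3)
  img <- spheres_image(c(60, 60, 40), sp, list(c(5, 5, 5)), 4, noise = 2)
  base <- segment_nuclei_hp1(img)
  expect_length(base, 1)
  # translate the object by whole voxels
  sh <- c(5L, 3L, 2L)
  arr <- array(100, dim(img$data))
  arr[(sh[1] + 1):60, (sh[2] + 1):60, (sh[3] + 1):40] <-
    img$data[1:(60 - sh[1]), 1:(60 - sh[2]), 1:(40 - sh[3])]
  shifted <- segment_nuclei_hp1(voxel_grid(arr, sp))
  expect_length(shifted, 1)
  expect_equal(mask_volume(shifted[[1]]), mask_volume(base[[1]]),
               tolerance = 0.02)
  # affine intensity rescaling: identical masks
  resc <- segment_nuclei_hp1(voxel_grid(3 * img$data + 40, sp))
  expect_length(resc, 1)
  expect_equal(resc[[1]]$data, base[[1]]$data)
})

test_that("DAPI recipe closes rim-only signal into a solid nucleus", {
  sp <- c(0.1, 0.1, 0.24)
  spec <- phantom_spec(shape = "sphere", semi_axes = 3, spacing = sp,
                       rim_weighted = TRUE, nuclear_amplitude = 200,
                       background_level = 10, noise_sigma = 0, k = 0)
  m <- make_mask(spec)
  ch <- render_stack(m, point_pattern(matrix(0, 0, 3)), spec)
  p <- segmentation_params(median_radius = 0L, gaussian_sigma = 0,
                           closing_radius = 0.5)
  out <- segment_nucleus_dapi(ch$nuclear, manual_threshold = 100, params = p)
  expect_length(out, 1)
  # the hollow shell is filled: recovered volume matches the solid truth
  expect_equal(mask_volume(out[[1]]), mask_volume(m), tolerance = 0.01)
  expect_equal(sum(out[[1]]$data & !m$data) / sum(m$data), 0,
               tolerance = 0.01)
})

test_that("DAPI recipe is idempotent on solid objects", {
  sp <- c(0.1, 0.1, 0.24)
  m <- ball_mask(3, sp)
  img <- voxel_grid(10 + 200 * m$data, sp)
  # with no closing the solid mask passes through exactly
  out0 <- segment_nucleus_dapi(img, 100,
                               segmentation_params(median_radius = 0L,
                                                   gaussian_sigma = 0,
                                                   closing_radius = 0))
  expect_identical(out0[[1]]$data, m$data)
  # with a closing ball the mask changes by at most a thin boundary sliver
  out1 <- segment_nucleus_dapi(img, 100,
                               segmentation_params(median_radius = 0L,
                                                   gaussian_sigma = 0,
                                                   closing_radius = 0.5))
  expect_lt(sum(xor(out1[[1]]$data, m$data)) / sum(m$data), 0.01)
})

test_that("DAPI recipe separates two close shells into two nuclei", {
  sp <- c(0.15, 0.15, 0.3)
  spec <- phantom_spec(shape = "sphere", semi_axes = 2.5, spacing = sp,
                       rim_weighted = TRUE, nuclear_amplitude = 200,
                       background_level = 10, noise_sigma = 0, k = 0)
  m1 <- make_mask(spec)
  d1 <- dim(m1$data)
  # place two spheres side by side, 1 voxel apart
  d <- c(2L * d1[1] + 1L, d1[2], d1[3])
  arr <- array(FALSE, d)
  arr[seq_len(d1[1]), , ] <- m1$data
  arr[d1[1] + 1L + seq_len(d1[1]), , ] <- m1$data
  both <- nucleus_mask(arr, sp)
  ch <- render_stack(both, point_pattern(matrix(0, 0, 3)), spec)
  out <- segment_nucleus_dapi(ch$nuclear, 100,
                              segmentation_params(median_radius = 0L,
                                                  gaussian_sigma = 0,
                                                  closing_radius = 0.3))
  expect_length(out, 2)
})

test_that("plant recipe applies the mean - 2 SD correction", {
  set.seed(5)
  sp <- c(0.2, 0.2, 0.2)
  m <- ball_mask(4, sp)
  d <- dim(m$data)
  arr <- array(rnorm(prod(d), 50, 5), d)
  arr[m$data] <- rnorm(sum(m$data), 150, 20)
  res <- segment_nucleus_arabidopsis(
    voxel_grid(arr, sp),
    segmentation_params(median_radius = 0L, gaussian_sigma = 0))
  # recompute m and s independently over the preliminary foreground
  bbox <- res$bbox
  cropped <- arr[bbox[[1]], bbox[[2]], bbox[[3]]]
  t_pre <- isodata_threshold(cropped)
  fg <- cropped[cropped >= t_pre]
  expect_equal(res$correction$m, mean(fg))
  expect_equal(res$correction$s, sd(fg))
  expect_equal(res$correction$corrected_threshold, mean(fg) - 2 * sd(fg))
  expect_equal(res$correction$corrected_threshold, 150 - 2 * 20,
               tolerance = 0.05)
  # single connected component after cleanup
  expect_equal(max(label_components(res$mask, 26L)), 1)
})

test_that("plant recipe with a noiseless image reduces to the isodata mask", {
  sp <- c(0.2, 0.2, 0.2)
  m <- ball_mask(3, sp)
  img <- voxel_grid(50 + 100 * m$data, sp)
  res <- segment_nucleus_arabidopsis(
    img, segmentation_params(median_radius = 0L, gaussian_sigma = 0,
                             opening_radius = 0, closing_radius_at = 0))
  expect_equal(res$correction$s, 0)
  expect_equal(res$correction$corrected_threshold, res$correction$m)
  bbox <- res$bbox
  expect_identical(res$mask$data,
                   m$data[bbox[[1]], bbox[[2]], bbox[[3]]])
})

test_that("isodata converges to the intermeans fixed point", {
  x <- c(rep(10, 400), rep(30, 100))
  t <- isodata_threshold(x)
  expect_equal(t, 20, tolerance = 1e-6)
})
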
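test_that("top-hat enhancement removes background, keeps the spot peak", {
  sp <- c(0.1, 0.1, 0.24)
  # constant image degenerates to all zeros
  const <- voxel_grid(array(37, c(20, 20, 10)), sp)
  expect_true(all(enhance_spots(const)$data == 0))
  # ramp background + one Gaussian spot: ramp removed, peak kept in place
  d <- c(40, 40, 16)
  ramp <- array(rep(seq(0, 60, length.out = d[1]), times = d[2] * d[3]), d)
  g <- voxel_grid(ramp, sp)
  g$data <- nucspat:::add_gaussian_spot(g$data, sp, c(2.0, 2.0, 1.9),
                                        200, 0.1, 0.3)
  enh <- enhance_spots(voxel_grid(round(g$data), sp),
                       spot_params(median_radius = 0L, gaussian_sigma = 0))
  peak_in <- arrayInd(which.max(g$data), d)
  peak_out <- arrayInd(which.max(enh$data), d)
  expect_lte(max(abs(peak_in - peak_out)), 1)
  # far side of the ramp is flattened to (near) zero
  expect_lt(max(enh$data[35:40, , ]), 5)
  # top-hat is anti-extensive after background subtraction
  expect_true(all(enh$data <= round(g$data)))
})

test_that("mask dilation retains peripheral spots; small objects drop", {
  sp <- c(0.1, 0.1, 0.24)
  m <- ball_mask(2, sp)
  d <- dim(m$data)
  cen <- d / 2 * sp
  # spot centered 1 voxel beyond the mask boundary along z (PSF elongation)
  zedge <- cen[3] + 2 + 1.0 * sp[3]
  img <- array(0, d)
  img <- nucspat:::add_gaussian_spot(img, sp, c(cen[1], cen[2], zedge),
                                     100, 0.1, 0.3)
  enh <- voxel_grid(round(img), sp)
  out <- mask_and_filter(enh, m, spot_params(dilation_radius = 0.5))
  expect_gt(max(out$data), 50) # retained inside the dilated mask
  out0 <- mask_and_filter(enh, m, spot_params(dilation_radius = 0))
  expect_lt(sum(out0$data > 0), sum(out$data > 0)) # truncated without it
  # volume filter: strictly-smaller-than semantics at 0.02 um^3
  sp2 <- c(0.1, 0.1, 0.2) # voxel volume 0.002 um^3 divides 0.02 exactly
  m2 <- ball_mask(2, sp2)
  d2 <- dim(m2$data)
  ic <- round(d2 / 2)
  img2 <- array(0, d2)
  img2[ic[1] + 0:4, ic[2], ic[3]] <- 50      # 5 voxels = 0.010 um^3
  img2[ic[1] + 0:9, ic[2], ic[3] + 4L] <- 50 # 10 voxels = 0.020 um^3 exactly
  out2 <- mask_and_filter(voxel_grid(img2, sp2), m2, spot_params())
  expect_equal(sum(out2$data[, , ic[3]] > 0), 0) # 0.01 < 0.02: removed
  expect_equal(sum(out2$data[, , ic[3] + 4L] > 0), 10) # exactly 0.02: kept
  expect_error(mask_and_filter(enh, nucleus_mask(array(FALSE, d), sp)),
               "empty mask")
})

test_that("incremental threshold search stops at the count bound", {
  sp <- c(0.1, 0.1, 0.24)
  d <- c(64, 64, 24)
  # 50 cubic spots on a grid: 44 at level 10, 6 at level 3
  corners <- as.matrix(expand.grid(x = seq(2, 58, by = 8),
                                   y = seq(2, 58, by = 8),
                                   z = c(4, 16)))[1:50, ]
  values <- c(rep(10, 44), rep(3, 6))
  img <- cube_spots_image(d, sp, corners, values)
  res <- threshold_search_max_count(img, spot_params(max_count = 44L))
  expect_equal(res$threshold, 4L) # first level excluding the 6 dim spots
  expect_equal(max(res$labels), 44)
  # raising max_count to 50 lets the search stop at 1
  res50 <- threshold_search_max_count(img, spot_params(max_count = 50L))
  expect_equal(res50$threshold, 1L)
  expect_lte(res50$threshold, res$threshold) # monotone in max_count
  # empty image: threshold 1, no labels
  empty <- voxel_grid(array(0, c(10, 10, 5)), sp)
  rese <- threshold_search_max_count(empty)
  expect_equal(rese$threshold, 1L)
  expect_equal(max(rese$labels), 0)
})

test_that("regional-maxima rule computes median of brightest 11 over 4", {
  sp <- c(0.1, 0.1, 0.24)
  d <- c(48, 48, 12)
  vals <- c(100, 96, 92, 88, 84, 80, 76, 72, 68, 64, 60, 20, 10)
  corners <- cbind(seq(2, by = 3, length.out = 13), 5L, 5L)
  img <- cube_spots_image(d, sp, corners, vals, side = 1L)
  res <- threshold_from_maxima(img, spot_params(min_spot_volume = 0))
  expect_equal(res$threshold, 80 / 4) # median of top 11 = 80
  expect_equal(max(res$labels), sum(vals >= 20))
  # 11 identical maxima of 40 -> threshold 10
  img2 <- cube_spots_image(d, sp, cbind(seq(2, by = 4, length.out = 11),
                                        9L, 8L), rep(40, 11), side = 1L)
  expect_equal(threshold_from_maxima(img2,
                                     spot_params(min_spot_volume = 0))$threshold,
               10)
  # fewer than 11 maxima: median of all available
  vals7 <- c(80, 70, 60, 50, 40, 30, 20)
  img3 <- cube_spots_image(d, sp, cbind(seq(2, by = 5, length.out = 7),
                                        15L, 4L), vals7, side = 1L)
  expect_equal(threshold_from_maxima(img3,
                                     spot_params(min_spot_volume = 0))$threshold,
               median(vals7) / 4)
  expect_error(threshold_from_maxima(voxel_grid(array(0, d), sp)),
               "no regional maximum")
})

test_that("regions reduce to centers of gravity in physical units", {
  sp <- c(0.1, 0.1, 0.2)
  d <- c(8, 8, 4)
  lab <- array(0L, d)
  lab[1:2, 1, 1] <- 1L # two voxels along x
  lab[5:6, 5:6, 2:3] <- 2L # symmetric 2x2x2 block
  m <- nucleus_mask(array(TRUE, d), sp)
  pat <- regions_to_pattern(lab, mask = m)
  expect_equal(npoints(pat), 2)
  # midpoint of voxel centers (0.05, 0.05, 0.1) and (0.15, 0.05, 0.1)
  expect_equal(unname(pat$points[1, ]), c(0.10, 0.05, 0.1))
  # symmetric block: center at its symmetry center (voxel centers 0.45/0.55
  # in x and y, 0.3/0.5 in z)
  expect_equal(unname(pat$points[2, ]), c(0.5, 0.5, 0.4))
  # intensity weighting moves the center toward the bright voxel
  g <- voxel_grid(array(1, d), sp)
  g$data[1, 1, 1] <- 3
  patw <- regions_to_pattern(lab, grid = g, mask = m)
  expect_lt(patw$points[1, 1], 0.10)
  # empty labeling -> empty pattern
  expect_equal(npoints(regions_to_pattern(array(0L, d), mask = m)), 0)
})

test_that("spot recovery on a rendered 44-spot nucleus is near-perfect", {
  ph <- render_centromere_phantom(seed = 9)
  enh <- enhance_spots(ph$spots)
  msk <- mask_and_filter(enh, ph$mask)
  res <- threshold_search_max_count(msk)
  expect_lte(max(res$labels), 44)
  pat <- regions_to_pattern(res$labels, grid = msk,
                            mask = dilate_ball(ph$mask, 0.5))
  d_match <- nucspat:::cpp_min_dists(pat$points, ph$truth$points)
  recall <- sum(nucspat:::cpp_min_dists(ph$truth$points, pat$points) < 0.3) /
    npoints(ph$truth)
  precision <- sum(d_match < 0.3) / npoints(pat)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})
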
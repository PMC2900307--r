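test_that("G-function enumerates nearest-neighbor distances", {
  pat <- point_pattern(rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)))
  g <- g_function(pat)
  expect_equal(g$distances, c(1, 1, 2))
  expect_equal(df_eval(g, c(0.5, 1, 1.99, 2, 5)),
               c(0, 2 / 3, 2 / 3, 1, 1))
  # two points: a single step at their distance
  g2 <- g_function(point_pattern(rbind(c(0, 0, 0), c(0, 0, 1.5))))
  expect_equal(df_eval(g2, c(1.49, 1.5)), c(0, 1))
  # rigid motion invariance
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- point_pattern(pat$points %*% t(R) +
                           matrix(c(5, -2, 1), 3, 3, byrow = TRUE))
  expect_equal(g_function(moved)$distances, g$distances)
  expect_error(g_function(point_pattern(matrix(0, 1, 3))), "at least 2")
})

test_that("uniform mask sampling is inside, uniform, and reproducible", {
  m <- ball_mask(2, c(0.1, 0.1, 0.2))
  set.seed(10)
  pts <- sample_uniform_in_mask(m, 1e5)
  d <- dim(m$data)
  vi <- sapply(1:3, function(a)
    pmin(pmax(ceiling(pts[, a] / m$spacing[a]), 1), d[a]))
  expect_true(all(m$data[vi]))
  # per-octant counts around the center agree with multinomial expectation
  cen <- d / 2 * m$spacing
  oct <- 1 + (pts[, 1] > cen[1]) + 2 * (pts[, 2] > cen[2]) +
    4 * (pts[, 3] > cen[3])
  expect_gt(chisq.test(tabulate(oct, 8))$p.value, 1e-4)
  set.seed(10)
  expect_identical(sample_uniform_in_mask(m, 1e5), pts)
})

test_that("F-function matches the analytic law in a sphere", {
  R <- 2
  m <- ball_mask(R, c(0.05, 0.05, 0.05))
  cen <- dim(m$data) / 2 * m$spacing
  pat <- point_pattern(matrix(cen, 1, 3))
  set.seed(11)
  f <- f_function(pat, m, n_eval = 1e4)
  # single central point: F(y) = (y/R)^3
  for (frac in c(0.3, 0.5, 0.8))
    expect_lt(abs(df_eval(f, frac * R) - frac^3), 0.01)
  expect_equal(df_eval(f, 0), 0)
  expect_equal(df_eval(f, 2 * R), 1)
  expect_error(f_function(point_pattern(matrix(0, 0, 3)), m), "empty")
})

test_that("Monte-Carlo and distance-map F estimates agree", {
  set.seed(13)
  # acquisition-scale voxel sizes: rounding to the grid is then negligible
  m <- ball_mask(2, c(0.05, 0.05, 0.122))
  r <- seq(0, 6, length.out = 500)
  for (i in 1:5) {
    pat <- sample_crbpp(m, 20)
    fmc <- f_function(pat, m, n_eval = 1e4)
    fed <- f_function_edm_oracle(pat, m)
    expect_lt(max(abs(df_eval(fmc, r) - df_eval(fed, r))), 0.02)
  }
  expect_equal(df_eval(fed, max(fed$distances)), 1)
  # at a coarse grid the difference is bounded by the point-rounding error
  mc <- ball_mask(2, c(0.1, 0.1, 0.24))
  pat <- sample_crbpp(mc, 20)
  sup <- max(abs(df_eval(f_function(pat, mc, 1e4), r) -
                   df_eval(f_function_edm_oracle(pat, mc), r)))
  expect_lt(sup, 0.06)
})

test_that("hardcore sampling honors its contract and degenerates cleanly", {
  m <- ball_mask(5, c(0.2, 0.2, 0.3))
  set.seed(14)
  for (i in 1:5) {
    pat <- sample_crbpp(m, 2, radii = c(1, 1))
    expect_equal(npoints(pat), 2)
    expect_gte(sqrt(sum((pat$points[1, ] - pat$points[2, ])^2)), 2)
    # at least 1 um from the envelope
    dmap <- distance_map(m, inside = TRUE)
    expect_true(all(nucspat:::interp3(dmap, m$spacing, pat$points) >= 1))
  }
  # radii all zero reduce to the unconstrained case: same NN-distance law
  # (compared through per-pattern mean NN distances, which are iid)
  set.seed(15)
  nn0 <- replicate(60, mean(g_function(sample_crbpp(m, 10,
                                                    radii = rep(0, 10)))$distances))
  nnU <- replicate(60, mean(g_function(sample_crbpp(m, 10))$distances))
  expect_gt(suppressWarnings(ks.test(nn0, nnU))$p.value, 0.01)
  # infeasible packing fails with a clear error
  small <- ball_mask(1, c(0.1, 0.1, 0.1))
  expect_error(sample_crbpp(small, 5, radii = rep(2, 5),
                            max_attempts = 200),
               "packing failed")
})

test_that("reference function is monotone with envelopes around the mean", {
  m <- ball_mask(2, c(0.1, 0.1, 0.2))
  set.seed(16)
  ref <- reference_function(m, k = 1, kind = "F", p1 = 100, n_eval = 2000)
  expect_true(all(diff(ref$mean) >= 0))
  expect_equal(max(ref$mean), 1)
  expect_true(all(ref$envelope_low <= ref$mean + 1e-12))
  expect_true(all(ref$envelope_high >= ref$mean - 1e-12))
  # k = 1 in a sphere: the mean F is the distance law between two uniform
  # points in a ball, F(t) = t^3 - (9/16) t^4 + (1/32) t^6 with t = y/R
  t <- pmin(ref$grid / 2, 2)
  analytic <- t^3 - 9 / 16 * t^4 + 1 / 32 * t^6
  expect_lt(max(abs(ref$mean - analytic)), 0.03)
})

test_that("signed maximum deviation has the closed form and antisymmetry", {
  n <- 4000
  df_lin <- nucspat:::distance_function("F", (1:n) / n) # F(y) ~ y
  df_sq <- nucspat:::distance_function("F", sqrt((1:n) / n)) # F(y) ~ y^2
  grid <- seq(0.0025, 1, by = 0.0025)
  ref_sq <- structure(list(kind = "F", grid = grid, mean = pmin(grid^2, 1)),
                      class = "reference_function")
  ref_lin <- structure(list(kind = "F", grid = grid, mean = pmin(grid, 1)),
                       class = "reference_function")
  d1 <- max_signed_deviation(df_lin, ref_sq)
  expect_equal(d1, 0.25, tolerance = 0.005) # attained at y = 0.5
  d2 <- max_signed_deviation(df_sq, ref_lin)
  expect_equal(d2, -d1, tolerance = 0.005)
  # identical observed and reference: deviation 0
  expect_equal(max_signed_deviation(df_lin, ref_lin), 0, tolerance = 0.001)
  expect_error(max_signed_deviation(g_function(
    point_pattern(rbind(c(0, 0, 0), c(1, 0, 0)))), ref_lin), "mismatched")
})

test_that("SDI flags clustering high and regularity low (F-function)", {
  m <- ball_mask(5, c(0.15, 0.15, 0.3))
  cen <- dim(m$data) / 2 * m$spacing
  cfg <- analysis_config(n_eval = 2000, p1 = 200, p2 = 200, seed = 17)
  # 44 points collapsed into a 0.1 um ball: strongly clustered
  collapsed <- point_pattern(matrix(cen, 44, 3, byrow = TRUE) +
                               matrix(runif(44 * 3, -0.05, 0.05), 44, 3))
  res_c <- sdi(collapsed, m, "F", cfg)
  expect_gte(res_c$sdi, 0.99)
  expect_lt(res_c$observed_deviation, 0)
  # tightly packed hardcore pattern: strongly regular
  set.seed(18)
  packed <- sample_crbpp(m, 15, radii = rep(1, 15))
  res_r <- sdi(point_pattern(packed$points), m, "F", cfg)
  expect_lte(res_r$sdi, 0.01)
  expect_gt(res_r$observed_deviation, 0)
  # the count convention: sdi = (#{D_i >= D_obs} + 1) / (p2 + 1)
  n_ge <- sum(res_r$reference_deviations >= res_r$observed_deviation)
  expect_equal(res_r$sdi, (n_ge + 1) / 201)
  expect_equal(res_r$sdi, 1 / 201) # larger than every simulated deviation
  res_lit <- sdi(point_pattern(packed$points), m, "F", cfg,
                 include_observed = FALSE)
  expect_equal(res_lit$sdi,
               sum(res_lit$reference_deviations >=
                     res_lit$observed_deviation) / 200)
})

test_that("SDI of a hardcore pattern against its own hardcore null is flat", {
  # radii carried by the pattern enter the reference simulations, so the
  # SDI must not flag the hardcore structure itself
  m <- ball_mask(4, c(0.2, 0.2, 0.3))
  cfg <- analysis_config(n_eval = 1000, p1 = 60, p2 = 60)
  set.seed(19)
  sdis <- replicate(15, {
    pat <- sample_crbpp(m, 8, radii = rep(0.6, 8))
    sdi(pat, m, "F", cfg)$sdi
  })
  expect_gt(min(sdis), 0.01)
  expect_lt(min(sdis), 0.9) # not all piled at 1 either
  expect_gt(suppressWarnings(ks.test(sdis, "punif"))$p.value, 0.01)
})

test_that("population uniformity test matches closed forms", {
  pt <- population_uniformity_test(rep(0.5, 12))
  expect_equal(pt$D, 0.5)
  n <- 19
  grid_sdis <- (1:n) / (n + 1)
  pt2 <- population_uniformity_test(grid_sdis)
  expect_equal(pt2$D, 1 / (n + 1), tolerance = 1e-9)
  expect_gt(pt2$p_value, 0.99)
  expect_error(population_uniformity_test(numeric(0)), "empty")
  expect_warning(population_uniformity_test(c(0.2, 0.4)), "fewer than 5")
})

test_that("Kendall correlation handles the worked examples", {
  expect_equal(flatness_correlation(1:8, (1:8)^2)$tau, 1)
  expect_equal(flatness_correlation(1:8, -(1:8))$tau, -1)
  ex <- flatness_correlation(c(1, 2, 3), c(2, 1, 3))
  expect_equal(ex$tau, 1 / 3, tolerance = 1e-9)
  expect_error(flatness_correlation(1:2, 1:2), "at least 3")
})

test_that("a fixed seed reproduces the SDI table bit for bit", {
  spec <- phantom_spec(shape = "ellipsoid", semi_axes = c(3, 2.5, 2),
                       spacing = c(0.15, 0.15, 0.3), k = 10)
  set.seed(20)
  masks <- replicate(3, make_mask(spec), simplify = FALSE)
  patterns <- lapply(masks, sample_crbpp, k = 10)
  cfg <- analysis_config(n_eval = 1000, p1 = 50, p2 = 50, seed = 99)
  t1 <- population_sdi(masks, patterns, "F", cfg)
  t2 <- population_sdi(masks, patterns, "F", cfg)
  expect_identical(t1, t2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_results_csv(t1, f1); write_results_csv(t2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
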
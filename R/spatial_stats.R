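# The statistical core: G- and F-functions on a bounded nucleus, conditional
# Monte-Carlo simulation of completely random binomial point patterns
# (with a hardcore variant for chromocenters), the signed maximum-amplitude
# deviation, the per-nucleus spatial distribution index (SDI), and the
# population-level tests.

#' Nearest-neighbor distance function (G)
#'
#' Empirical cumulative distribution of the distance from each pattern point
#' to its nearest neighboring point, in micrometres. No edge correction is
#' applied: the nucleus is the complete, bounded domain of the pattern, so
#' no point can be missing beyond a boundary.
#'
#' @param pattern a [point_pattern()] with at least 2 points.
#' @return A `distance_function` (see [df_eval()]).
#' @export
g_function <- function(pattern) {
  if (npoints(pattern) < 2) stop("G-function needs at least 2 points")
  d <- cpp_nn_dists(pattern$points)
  distance_function("G", d)
}

#' Empty-space distance function (F)
#'
#' `F(y)` is the fraction of the nuclear volume lying within distance `y` of
#' the pattern, estimated from `n_eval` uniform random evaluation points
#' sampled in the mask (subvoxel precision of both evaluation points and
#' pattern coordinates is respected).
#'
#' @param pattern a non-empty [point_pattern()].
#' @param mask the [nucleus_mask()] domain.
#' @param n_eval number of evaluation points.
#' @param eval_points optional pre-sampled evaluation points (n x 3 um).
#' @return A `distance_function`.
#' @export
f_function <- function(pattern, mask, n_eval = 10000L, eval_points = NULL) {
  if (npoints(pattern) < 1) stop("empty pattern")
  if (is.null(eval_points))
    eval_points <- sample_uniform_in_mask(mask, n_eval)
  d <- cpp_min_dists(eval_points, pattern$points)
  distance_function("F", d)
}

distance_function <- function(kind, distances) {
  structure(list(kind = kind, distances = sort(distances),
                 n = length(distances)),
            class = "distance_function")
}

#' Evaluate an empirical distance function
#'
#' Right-continuous step CDF: the fraction of the underlying distance sample
#' less than or equal to `r`.
#'
#' @param df a `distance_function` from [g_function()] or [f_function()].
#' @param r radii (um), any length.
#' @export
df_eval <- function(df, r) {
  findInterval(r, df$distances) / df$n
}

#' @export
print.distance_function <- function(x, ...) {
  cat(sprintf("<distance_function> kind %s, %d distances, median %.3f um\n",
              x$kind, x$n, stats::median(x$distances)))
  invisible(x)
}

#' Distance-map estimate of the F-function
#'
#' Alternative F estimator used as a cross-check of the Monte-Carlo route:
#' pattern points are rounded to voxel coordinates, the anisotropy-aware
#' Euclidean distance map from those voxels is computed, and F is the
#' normalized cumulative histogram of the map over the mask. Rounding to the
#' grid loses subvoxel precision, so the two estimators agree only up to
#' voxelization plus Monte-Carlo error.
#'
#' @inheritParams f_function
#' @export
f_function_edm_oracle <- function(pattern, mask) {
  if (npoints(pattern) < 1) stop("empty pattern")
  stopifnot_mask(mask)
  d <- dim(mask$data)
  idx <- sapply(1:3, function(a)
    pmin(pmax(round(pattern$points[, a] / mask$spacing[a] + 0.5), 1), d[a]))
  idx <- matrix(idx, ncol = 3)
  feat <- array(FALSE, d)
  feat[idx] <- TRUE
  edm <- edt_from_feature(feat, d, mask$spacing)
  distance_function("F", edm[mask$data])
}

#' Uniform random points inside a mask
#'
#' Exactly uniform over the voxelized domain: a foreground voxel is drawn
#' uniformly, then a uniform continuous offset within that voxel, giving
#' subvoxel precision.
#'
#' @param mask a [nucleus_mask()].
#' @param n number of points.
#' @return n x 3 matrix of micrometre coordinates.
#' @export
sample_uniform_in_mask <- function(mask, n) {
  fg <- fg_coords(mask)
  sample_uniform_fg(fg, mask$spacing, n)
}

sample_uniform_fg <- function(fg, spacing, n) {
  idx <- sample.int(nrow(fg), n, replace = TRUE)
  fg[idx, , drop = FALSE] +
    matrix(runif(3 * n) - 0.5, ncol = 3) %*% diag(spacing)
}

# trilinear interpolation of a 3D array sampled at voxel centers
interp3 <- function(arr, spacing, pts) {
  d <- dim(arr)
  out <- numeric(nrow(pts))
  g <- sapply(1:3, function(a) pts[, a] / spacing[a] + 0.5)
  g <- matrix(g, ncol = 3)
  f0 <- pmin(pmax(floor(g), 1), pmax(d - 1, 1))
  fr <- pmin(pmax(g - f0, 0), 1)
  f1 <- pmin(f0 + 1, d[col(f0)])
  val <- function(ix, iy, iz) arr[cbind(ix, iy, iz)]
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- (if (cx) fr[, 1] else 1 - fr[, 1]) *
         (if (cy) fr[, 2] else 1 - fr[, 2]) *
         (if (cz) fr[, 3] else 1 - fr[, 3])
    out <- out + w * val(if (cx) f1[, 1] else f0[, 1],
                         if (cy) f1[, 2] else f0[, 2],
                         if (cz) f1[, 3] else f0[, 3])
  }
  out
}

#' Simulate a (hardcore) completely random binomial pattern
#'
#' Without radii: `k` points drawn independently and uniformly in the mask.
#' With radii (the chromocenter case): the observed radii are randomly
#' permuted over the points and sequential rejection sampling enforces, for
#' each accepted point i, (a) a distance to the mask boundary of at least
#' `r_i` and (b) a hardcore separation from every previously accepted point
#' j of `r_i + r_j` (rule `"sum"`, non-overlapping spheres; default) or
#' `max(r_i, r_j)` (rule `"max"`, the literal single-radius exclusion).
#'
#' @param mask a [nucleus_mask()].
#' @param k number of points (>= 1).
#' @param radii `NULL`, or `k` hardcore radii in micrometres.
#' @param hardcore_rule `"sum"` or `"max"`.
#' @param max_attempts total rejection budget before giving up.
#' @return A [point_pattern()].
#' @export
sample_crbpp <- function(mask, k, radii = NULL,
                         hardcore_rule = c("sum", "max"),
                         max_attempts = 1e5) {
  hardcore_rule <- match.arg(hardcore_rule)
  if (k < 1) stop("k must be >= 1")
  fg <- fg_coords(mask)
  if (is.null(radii) || all(radii == 0)) {
    return(point_pattern(sample_uniform_fg(fg, mask$spacing, k), radii))
  }
  if (length(radii) != k) stop("need one radius per point")
  dmap <- distance_map(mask, inside = TRUE)
  sample_crbpp_hardcore(fg, mask$spacing, dmap, k, radii, hardcore_rule,
                        max_attempts)
}

sample_crbpp_hardcore <- function(fg, spacing, dmap, k, radii, rule,
                                  max_attempts) {
  r <- radii[sample.int(k)]
  pts <- matrix(0, k, 3)
  attempts <- 0L
  i <- 1L
  while (i <= k) {
    cand <- sample_uniform_fg(fg, spacing, 1L)
    ok <- interp3(dmap, spacing, cand) >= r[i]
    if (ok && i > 1L) {
      prev <- pts[seq_len(i - 1L), , drop = FALSE]
      dd <- sqrt(rowSums(sweep(prev, 2, as.numeric(cand))^2))
      minsep <- if (rule == "sum") r[seq_len(i - 1L)] + r[i]
                else pmax(r[seq_len(i - 1L)], r[i])
      ok <- all(dd >= minsep)
    }
    if (ok) {
      pts[i, ] <- cand
      i <- i + 1L
    } else {
      attempts <- attempts + 1L
      if (attempts > max_attempts) stop("hardcore packing failed")
    }
  }
  point_pattern(pts, r)
}

# common radius grid for reference/deviation comparisons
radius_grid <- function(mask, ngrid = 512L) {
  diag <- mask_bbox_diagonal(mask)
  dr <- diag / ngrid
  list(dr = dr, r = seq_len(ngrid) * dr)
}

#' Monte-Carlo reference distance function under the (hardcore) CRBPP
#'
#' Simulates `p1` completely random binomial patterns of `k` points in the
#' mask (honoring hardcore radii when given), evaluates each pattern's G- or
#' F-function on a common radius grid (512 radii spanning the mask bounding
#' box diagonal), and returns the pointwise mean together with 2.5%/97.5%
#' envelopes. F-functions of all replicates are evaluated against one shared
#' set of uniform evaluation points.
#'
#' @param mask a [nucleus_mask()].
#' @param k points per pattern.
#' @param radii optional hardcore radii (length k).
#' @param kind `"F"` or `"G"`.
#' @param p1 number of replicates.
#' @param n_eval evaluation points for F.
#' @param ngrid grid resolution.
#' @param hardcore_rule see [sample_crbpp()].
#' @return A `reference_function`: list with `kind`, `grid`, `mean`,
#'   `envelope_low`, `envelope_high`.
#' @export
reference_function <- function(mask, k, radii = NULL, kind = c("F", "G"),
                               p1 = 500L, n_eval = 10000L, ngrid = 512L,
                               hardcore_rule = "sum") {
  kind <- match.arg(kind)
  gr <- radius_grid(mask, ngrid)
  eval_pts <- if (kind == "F") sample_uniform_in_mask(mask, n_eval)
              else matrix(0, 0, 3)
  mat <- simulate_counts_matrix(mask, k, radii, kind, p1, eval_pts,
                                gr$dr, ngrid, hardcore_rule)
  denom <- if (kind == "F") nrow(eval_pts) else k
  mat <- mat / denom
  mu <- colMeans(mat)
  # empirical tail quantiles are clamped so the envelope always brackets
  # the mean (a raw 2.5% quantile can exceed the mean when almost every
  # replicate sits at 1 with rare low values)
  structure(list(kind = kind, grid = gr$r, mean = mu,
                 envelope_low = pmin(apply(mat, 2, quantile, 0.025,
                                           names = FALSE), mu),
                 envelope_high = pmax(apply(mat, 2, quantile, 0.975,
                                            names = FALSE), mu)),
            class = "reference_function")
}

# P x ngrid cumulative count matrix for P simulated patterns
simulate_counts_matrix <- function(mask, k, radii, kind, P, eval_pts, dr,
                                   ngrid, hardcore_rule) {
  kind_int <- if (kind == "F") 0L else 1L
  if (is.null(radii) || all(radii == 0)) {
    fg <- fg_coords(mask)
    cpp_gf_null_batch(fg, mask$spacing[1], mask$spacing[2], mask$spacing[3],
                      as.integer(k), as.integer(P), eval_pts, kind_int,
                      dr, as.integer(ngrid))
  } else {
    fg <- fg_coords(mask)
    dmap <- distance_map(mask, inside = TRUE)
    t(vapply(seq_len(P), function(p) {
      pat <- sample_crbpp_hardcore(fg, mask$spacing, dmap, k, radii,
                                   hardcore_rule, 1e5)
      as.numeric(cpp_gf_counts(pat$points, eval_pts, kind_int, dr,
                               as.integer(ngrid)))
    }, numeric(ngrid)))
  }
}

#' Signed maximum-amplitude deviation
#'
#' The deviation between an observed distance function and its Monte-Carlo
#' reference is the signed value of their difference at the radius where the
#' absolute difference is largest (ties resolved at the smallest radius).
#'
#' @param observed a `distance_function`.
#' @param reference a `reference_function` of the same kind.
#' @export
max_signed_deviation <- function(observed, reference) {
  if (observed$kind != reference$kind)
    stop("mismatched kinds: ", observed$kind, " vs ", reference$kind)
  diff <- df_eval(observed, reference$grid) - reference$mean
  diff[which.max(abs(diff))]
}

signed_max_rows <- function(mat, refmean) {
  am <- abs(sweep(mat, 2, refmean))
  j <- max.col(am, ties.method = "first")
  mat[cbind(seq_len(nrow(mat)), j)] - refmean[j]
}

#' Spatial distribution index of one nucleus
#'
#' Monte-Carlo p-value scoring the departure of the observed pattern from
#' the completely random binomial reference within its own nucleus. The
#' reference mean function is estimated from `p1` simulated patterns; the
#' null distribution of the signed maximum-amplitude deviation from a
#' second, independent set of `p2` patterns; the SDI is the proportion of
#' deviations at least as large as the observed one. With the default
#' convention the observed pattern is included in the pool,
#' `SDI = (#\{D_i >= D_obs\} + 1) / (p2 + 1)`, the standard exact
#' Monte-Carlo p-value, uniform on `\{1/(p2+1), ..., 1\}` under the null;
#' `include_observed = FALSE` gives the literal `#\{D_i >= D_obs\} / p2`.
#'
#' For the F-function, low SDI indicates regularity (observed F above the
#' reference) and high SDI clustering; the G-function concentrates the
#' opposite way.
#'
#' @param pattern the observed [point_pattern()] (radii, when present,
#'   are carried into the reference simulations as hardcore constraints).
#' @param mask the [nucleus_mask()].
#' @param kind `"F"` (default) or `"G"`.
#' @param config an [analysis_config()].
#' @param hardcore_rule see [sample_crbpp()].
#' @param include_observed include the observed deviation in the pool.
#' @param ngrid radius grid resolution.
#' @return An `sdi_result`: list with `sdi`, `observed_deviation`,
#'   `reference_deviations`, `kind`, `n_points`, `reference` (grid + mean).
#' @export
sdi <- function(pattern, mask, kind = c("F", "G"),
                config = analysis_config(), hardcore_rule = "sum",
                include_observed = TRUE, ngrid = 512L) {
  kind <- match.arg(kind)
  k <- npoints(pattern)
  if (kind == "G" && k < 2) stop("G-function SDI needs at least 2 points")
  if (k < 1) stop("empty pattern")
  if (!is.null(config$seed)) set.seed(config$seed)
  gr <- radius_grid(mask, ngrid)
  eval_pts <- if (kind == "F") sample_uniform_in_mask(mask, config$n_eval)
              else matrix(0, 0, 3)
  denom <- if (kind == "F") config$n_eval else k
  kind_int <- if (kind == "F") 0L else 1L

  refmat <- simulate_counts_matrix(mask, k, pattern$radii, kind, config$p1,
                                   eval_pts, gr$dr, ngrid, hardcore_rule)
  refmean <- colMeans(refmat) / denom
  devmat <- simulate_counts_matrix(mask, k, pattern$radii, kind, config$p2,
                                   eval_pts, gr$dr, ngrid, hardcore_rule)
  devs <- signed_max_rows(devmat / denom, refmean)
  obs <- as.numeric(cpp_gf_counts(pattern$points, eval_pts, kind_int,
                                  gr$dr, as.integer(ngrid))) / denom
  diff <- obs - refmean
  d_obs <- diff[which.max(abs(diff))]
  n_ge <- sum(devs >= d_obs)
  val <- if (include_observed) (n_ge + 1) / (config$p2 + 1) else n_ge / config$p2
  structure(list(sdi = val, observed_deviation = d_obs,
                 reference_deviations = devs, kind = kind, n_points = k,
                 reference = list(grid = gr$r, mean = refmean)),
            class = "sdi_result")
}

#' @export
print.sdi_result <- function(x, ...) {
  cat(sprintf("<sdi_result> %s-SDI = %.4f (D_obs = %+.4f, k = %d)\n",
              x$kind, x$sdi, x$observed_deviation, x$n_points))
  invisible(x)
}

#' Per-nucleus SDI table for a population
#'
#' Runs [sdi()] over matched lists of masks and patterns and returns a
#' data.frame with one row per nucleus. With `config$seed` set the whole
#' table is exactly reproducible.
#'
#' @param masks list of [nucleus_mask()].
#' @param patterns list of [point_pattern()] of the same length.
#' @param kind `"F"` or `"G"`.
#' @param config an [analysis_config()].
#' @param ... passed to [sdi()].
#' @export
population_sdi <- function(masks, patterns, kind = "F",
                           config = analysis_config(), ...) {
  stopifnot(length(masks) == length(patterns))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$seed <- NULL # one stream for the whole population
  rows <- lapply(seq_along(masks), function(i) {
    res <- sdi(patterns[[i]], masks[[i]], kind = kind, config = cfg, ...)
    data.frame(id = i, n_points = res$n_points, sdi = res$sdi,
               observed_deviation = res$observed_deviation)
  })
  do.call(rbind, rows)
}

#' Population-level test of SDI uniformity
#'
#' Under the completely random null the per-nucleus SDI is uniform on
#' (0, 1]; departure of a population is assessed with the two-sided
#' one-sample Kolmogorov-Smirnov test against Uniform(0,1). The asymptotic
#' p-value is used throughout (Monte-Carlo SDIs live on a discrete support,
#' so ties are expected).
#'
#' @param sdis numeric vector of per-nucleus SDI values.
#' @return List with `n`, `D` (KS statistic) and `p_value`.
#' @export
population_uniformity_test <- function(sdis) {
  if (length(sdis) == 0) stop("empty input")
  if (length(sdis) < 5)
    warning("fewer than 5 nuclei: the uniformity test has little power")
  ks <- suppressWarnings(ks.test(sdis, "punif", exact = FALSE))
  structure(list(n = length(sdis), D = unname(ks$statistic),
                 p_value = ks$p.value),
            class = "population_test")
}

#' @export
print.population_test <- function(x, ...) {
  cat(sprintf("<population_test> n = %d, KS D = %.3f, p = %.3g\n",
              x$n, x$D, x$p_value))
  invisible(x)
}

#' Rank correlation between nuclear flatness and SDI
#'
#' Kendall's tau (tie-corrected) with its two-sided p-value, used to check
#' whether pattern regularity merely reflects nuclear flattening. Intended
#' for the subset of nuclei whose minor axis is Z-oriented.
#'
#' @param flatness_values numeric vector.
#' @param sdis numeric vector of the same length.
#' @return List with `tau` and `p_value`.
#' @export
flatness_correlation <- function(flatness_values, sdis) {
  if (length(flatness_values) != length(sdis))
    stop("inputs must have the same length")
  if (length(sdis) < 3) stop("need at least 3 pairs")
  ct <- suppressWarnings(cor.test(flatness_values, sdis, method = "kendall"))
  list(tau = unname(ct$estimate), p_value = ct$p.value)
}
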
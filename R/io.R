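# Reading and writing calibrated stacks, point patterns, configurations and
# per-nucleus result tables.

#' Read a multi-page TIFF as a calibrated 3D stack
#'
#' Pages are stacked along z; within a page, TIFF rows map to the y axis and
#' columns to the x axis, so the returned array is indexed `[x, y, z]`.
#' Intensities are stored as 16-bit grayscale on disk and returned on the
#' 0..65535 integer scale, unmodified relative to what [write_stack()]
#' wrote. Voxel spacing is resolved in order of preference from the
#' `spacing` argument, OME-style metadata in the image description
#' (`PhysicalSizeX/Y/Z`, as written by many acquisition tools), or the
#' sidecar JSON written next to the stack by [write_stack()].
#'
#' @param path TIFF file path.
#' @param spacing optional numeric length-3 spacing (x, y, z) in micrometres;
#'   overrides any file metadata when given.
#' @return A [voxel_grid()].
#' @export
read_stack <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("not a 3D stack: file has fewer than 2 pages")
  if (is.null(spacing)) {
    desc <- attr(pages[[1]], "description")
    spacing <- parse_ome_spacing(desc)
  }
  if (is.null(spacing) && file.exists(paste0(path, ".json"))) {
    side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    spacing <- side$spacing
  }
  if (is.null(spacing))
    stop("no voxel spacing in metadata or sidecar; pass `spacing=`")
  arr <- vapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1] # drop extra channels
    t(p) # TIFF row-major (y, x) -> [x, y]
  }, matrix(0, ncol(pages[[1]]), nrow(pages[[1]])))
  voxel_grid(round(arr * 65535), spacing)
}

#' Write a calibrated 3D stack as multi-page 16-bit TIFF
#'
#' Intensities must lie in 0..65535; they are stored so that
#' [read_stack()] recovers them exactly. Spacing is recorded in a sidecar
#' JSON file (`<path>.json`) alongside the stack.
#'
#' @param grid a [voxel_grid()] or [nucleus_mask()] (masks are written 0/1).
#' @param path output path.
#' @export
write_stack <- function(grid, path) {
  data <- grid$data
  if (is.logical(data)) data <- data * 1
  if (min(data) < 0 || max(data) > 65535)
    stop("intensities must lie in 0..65535 for 16-bit storage")
  pages <- lapply(seq_len(dim(data)[3]),
                  function(k) t(data[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(spacing = grid$spacing), paste0(path, ".json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

parse_ome_spacing <- function(desc) {
  if (is.null(desc) || !nzchar(desc)) return(NULL)
  get1 <- function(axis) {
    m <- regmatches(desc, regexpr(
      sprintf('PhysicalSize%s="[0-9.eE+-]+"', axis), desc))
    if (length(m) == 0) return(NA_real_)
    as.numeric(sub('.*"([0-9.eE+-]+)"', "\\1", m))
  }
  s <- c(get1("X"), get1("Y"), get1("Z"))
  if (any(is.na(s))) NULL else s
}

#' Write a point pattern to CSV
#'
#' Columns are `x_um`, `y_um`, `z_um` and, when the pattern carries radii,
#' `radius_um`. Coordinates survive a round trip to at least 6 significant
#' digits.
#'
#' @param pattern a [point_pattern()].
#' @param path output CSV path.
#' @export
write_pattern_csv <- function(pattern, path) {
  df <- data.frame(x_um = pattern$points[, 1],
                   y_um = pattern$points[, 2],
                   z_um = pattern$points[, 3])
  if (!is.null(pattern$radii)) df$radius_um <- pattern$radii
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a point pattern from CSV
#'
#' @param path CSV with columns `x_um`, `y_um`, `z_um` and optionally
#'   `radius_um` (which must then be present for every point).
#' @return A [point_pattern()].
#' @export
read_pattern_csv <- function(path) {
  df <- read.csv(path)
  need <- c("x_um", "y_um", "z_um")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  radii <- NULL
  if ("radius_um" %in% names(df)) {
    radii <- df$radius_um
    if (any(is.na(radii)))
      stop("radius_um present for some points only")
    if (any(radii < 0)) stop("negative radius")
  }
  point_pattern(cbind(df$x_um, df$y_um, df$z_um), radii)
}

#' Write / read an analysis configuration as JSON
#' @param config an [analysis_config()].
#' @param path JSON path.
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  analysis_config(n_eval = x$n_eval, p1 = x$p1, p2 = x$p2,
                  seed = x$seed, alpha = x$alpha)
}

#' Write a per-nucleus results table
#'
#' One row per nucleus: id, point count, volume, compactness, flatness,
#' elongation, flattening axis and the F- and G-based spatial distribution
#' indexes. Any column may be NA when not computed.
#'
#' @param results data.frame with (a subset of) the columns above.
#' @param path output CSV path.
#' @export
write_results_csv <- function(results, path) {
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}
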
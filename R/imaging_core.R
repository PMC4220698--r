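## imaging_core: containers for 2D images / 3D stacks, line-profile
## sampling, top-k maximum projections, and the two confocal
## quantification procedures (developmental fluorescence series,
## colocalization line profiles).

#' 2D scalar image with a tagged physical pixel size
#'
#' @param pixels numeric matrix; rows index y, columns index x. The
#'   physical coordinate of pixel `[i, j]` is `((j-1)*pixel_size,
#'   (i-1)*pixel_size)` (0-based voxel-centre convention).
#' @param pixel_size physical side of a pixel.
#' @param unit `"nm"` or `"um"`.
#' @return An object of class `image2d`.
#' @export
image2d <- function(pixels, pixel_size, unit = c("nm", "um")) {
  unit <- match.arg(unit)
  check_that(is.matrix(pixels) && is.numeric(pixels) && all(dim(pixels) >= 2L),
             "`pixels` must be a numeric matrix with at least 2 rows and columns")
  check_number(pixel_size, "pixel_size", positive = TRUE)
  structure(list(pixels = pixels, pixel_size = pixel_size, unit = unit),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px, pixel %g %s\n",
              ncol(x$pixels), nrow(x$pixels), x$pixel_size, x$unit))
  invisible(x)
}

#' 3D image stack on an anisotropic voxel grid
#'
#' @param voxels numeric 3D array indexed `[x, y, z]`.
#' @param spacing physical voxel sides `c(x, y, z)`.
#' @param unit `"um"` or `"nm"`.
#' @param channel optional channel label.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, spacing, unit = c("um", "nm"), channel = NA_character_) {
  unit <- match.arg(unit)
  check_that(is.array(voxels) && length(dim(voxels)) == 3L && all(dim(voxels) >= 1L),
             "`voxels` must be a non-empty 3D array")
  check_that(is.numeric(spacing) && length(spacing) == 3L && all(spacing > 0),
             "`spacing` must be three positive physical voxel sides")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 unit = unit, channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d voxels, spacing (%g, %g, %g) %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$unit))
  invisible(x)
}

#' Straight sampling line in physical coordinates
#'
#' @param start,end length-2 physical coordinates `(x, y)`.
#' @param step sampling step along the line (same unit as the coordinates).
#' @param unit `"nm"` or `"um"`.
#' @return An object of class `line_anchor`.
#' @export
line_anchor <- function(start, end, step = 1, unit = c("nm", "um")) {
  unit <- match.arg(unit)
  check_that(is.numeric(start) && length(start) == 2L && all(is.finite(start)),
             "`start` must be a finite (x, y) pair")
  check_that(is.numeric(end) && length(end) == 2L && all(is.finite(end)),
             "`end` must be a finite (x, y) pair")
  check_number(step, "step", positive = TRUE)
  len <- sqrt(sum((end - start)^2))
  check_that(len > 0, "line anchor has zero length")
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 step = step, unit = unit, length = len),
            class = "line_anchor")
}

#' Ordered, equally spaced intensity samples along a line
#'
#' The substrate of the cleft-width estimator: electron-density (or
#' fluorescence) values at `step`-spaced positions, with `origin` the
#' physical position of sample 1 along the line.
#'
#' @param samples numeric vector, at least 3 values.
#' @param step spacing between consecutive samples.
#' @param origin physical position of the first sample (default 0).
#' @param unit `"nm"` or `"um"`.
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(samples, step, origin = 0, unit = c("nm", "um")) {
  unit <- match.arg(unit)
  check_that(is.numeric(samples) && length(samples) >= 3L && all(is.finite(samples)),
             "`samples` must be a finite numeric vector with >= 3 values")
  check_number(step, "step", positive = TRUE)
  structure(list(samples = as.numeric(samples), step = step,
                 origin = origin, unit = unit),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d samples, step %g %s\n",
              length(x$samples), x$step, x$unit))
  invisible(x)
}

#' Positions of the samples of an intensity profile
#' @param profile an [intensity_profile()].
#' @return numeric vector of physical positions.
#' @export
profile_positions <- function(profile) {
  profile$origin + (seq_along(profile$samples) - 1) * profile$step
}

## Bilinear interpolation at physical points (x, y); gx/gy are 0-based
## fractional pixel indices. Callers guarantee in-bounds.
bilinear_at <- function(pixels, gx, gy) {
  nx <- ncol(pixels); ny <- nrow(pixels)
  x0 <- pmin(pmax(floor(gx), 0), nx - 2L)
  y0 <- pmin(pmax(floor(gy), 0), ny - 2L)
  fx <- gx - x0
  fy <- gy - y0
  i <- y0 + 1L; j <- x0 + 1L
  v00 <- pixels[cbind(i, j)]
  v01 <- pixels[cbind(i, j + 1L)]
  v10 <- pixels[cbind(i + 1L, j)]
  v11 <- pixels[cbind(i + 1L, j + 1L)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

#' Sample an intensity profile along a straight line
#'
#' Values are obtained by bilinear interpolation at `floor(length/step) + 1`
#' equally spaced points from the anchor start towards its end.
#'
#' @param image an [image2d()].
#' @param anchor a [line_anchor()] in the same length unit as `image`.
#' @return An [intensity_profile()] (origin 0 at the anchor start).
#' @export
sample_line_profile <- function(image, anchor) {
  stopifnot(inherits(image, "image2d"), inherits(anchor, "line_anchor"))
  check_same_unit(image$unit, anchor$unit, "image and anchor")
  n <- floor(anchor$length / anchor$step + 1e-9) + 1L
  dir <- (anchor$end - anchor$start) / anchor$length
  t <- (seq_len(n) - 1) * anchor$step
  px <- anchor$start[1] + t * dir[1]
  py <- anchor$start[2] + t * dir[2]
  gx <- px / image$pixel_size
  gy <- py / image$pixel_size
  eps <- 1e-9
  inb <- gx >= -eps & gx <= ncol(image$pixels) - 1 + eps &
    gy >= -eps & gy <= nrow(image$pixels) - 1 + eps
  if (!all(inb)) {
    abort(sprintf("line anchor leaves the image (%d of %d samples out of bounds)",
                  sum(!inb), n),
          "synmorph_bounds_error")
  }
  intensity_profile(bilinear_at(image$pixels, gx, gy),
                    step = anchor$step, origin = 0, unit = anchor$unit)
}

#' Maximum-intensity projection over the brightest k slices
#'
#' Ranks z-slices by a summary score (mean intensity by default), keeps the
#' `k` highest-scoring slices and returns their per-pixel maximum. This is
#' the projection used before quantifying a developmental fluorescence
#' series, where dim out-of-focus or poorly penetrated slices would bias a
#' whole-stack projection.
#'
#' @param stack an [image_stack()].
#' @param k number of slices to keep (default 5).
#' @param score `"mean"` or `"sum"` slice score.
#' @return An [image2d()] (pixel size = xy spacing, which must be isotropic).
#' @export
max_project_top_k <- function(stack, k = 5, score = c("mean", "sum")) {
  stopifnot(inherits(stack, "image_stack"))
  score <- match.arg(score)
  nz <- dim(stack$voxels)[3]
  k <- check_count(k, "k")
  check_that(k >= 1 && k <= nz,
             sprintf("`k` must be between 1 and the number of slices (%d)", nz))
  check_that(isTRUE(all.equal(stack$spacing[1], stack$spacing[2])),
             "projection requires isotropic xy spacing")
  s <- apply(stack$voxels, 3, if (score == "mean") mean else sum)
  keep <- order(s, decreasing = TRUE)[seq_len(k)]
  proj <- apply(stack$voxels[, , keep, drop = FALSE], c(1, 2), max)
  ## voxels are [x, y]; image2d pixels are [y, x]
  image2d(t(proj), pixel_size = stack$spacing[1], unit = stack$unit)
}

#' Normalized mean fluorescence across a developmental series
#'
#' For each age, the region-of-interest mean of the top-k maximum
#' projection is divided by the same quantity at the reference age, so the
#' reference maps to 1.0. Mirrors per-layer expression quantification
#' normalized to the oldest time point.
#'
#' @param stacks_by_age named list of [image_stack()]s (names = ages).
#' @param roi logical matrix in projection (y, x) layout selecting the
#'   region of interest (e.g. a cell layer band).
#' @param reference_age name of the reference age; must be present.
#' @param k slices kept in the projection (default 5).
#' @return Named numeric vector of normalized means (reference = 1).
#' @export
quantify_expression_series <- function(stacks_by_age, roi, reference_age, k = 5) {
  check_that(is.list(stacks_by_age) && length(stacks_by_age) >= 1 &&
               !is.null(names(stacks_by_age)),
             "`stacks_by_age` must be a named list of image stacks")
  check_that(reference_age %in% names(stacks_by_age),
             sprintf("reference age '%s' absent from the series", reference_age))
  check_that(is.matrix(roi) && is.logical(roi), "`roi` must be a logical matrix")
  check_that(any(roi), "`roi` selects no pixels")
  roi_mean <- function(stack) {
    proj <- max_project_top_k(stack, k = min(k, dim(stack$voxels)[3]))
    check_that(all(dim(roi) == dim(proj$pixels)),
               "`roi` dimensions do not match the projection")
    mean(proj$pixels[roi])
  }
  vals <- vapply(stacks_by_age, roi_mean, numeric(1))
  ref <- vals[[reference_age]]
  check_that(ref != 0, "reference-age mean fluorescence is zero")
  vals / ref
}

#' Per-channel line profiles with a zero-lag overlap score
#'
#' Samples the same anchor in each aligned channel and reports the
#' pairwise normalized cross-correlation at zero lag (cosine similarity of
#' the two profiles). A channel with zero norm makes the score undefined;
#' it is returned as `NA` and flagged.
#'
#' @param channels list of [image2d()]s with identical geometry.
#' @param anchor a [line_anchor()].
#' @return list with `profiles` (one [intensity_profile()] per channel),
#'   `overlap` (symmetric score matrix) and `degenerate` (logical vector
#'   flagging zero-norm channels).
#' @export
channel_line_profiles <- function(channels, anchor) {
  check_that(is.list(channels) && length(channels) >= 2,
             "`channels` must be a list of at least two images")
  dims <- vapply(channels, function(im) dim(im$pixels), integer(2))
  check_that(all(dims == dims[, 1]), "channel image shapes differ")
  profiles <- lapply(channels, sample_line_profile, anchor = anchor)
  mat <- vapply(profiles, function(p) p$samples,
                numeric(length(profiles[[1]]$samples)))
  norms <- sqrt(colSums(mat^2))
  nch <- length(channels)
  overlap <- matrix(NA_real_, nch, nch)
  for (a in seq_len(nch)) {
    for (b in seq_len(nch)) {
      if (norms[a] > 0 && norms[b] > 0) {
        overlap[a, b] <- sum(mat[, a] * mat[, b]) / (norms[a] * norms[b])
      }
    }
  }
  if (!is.null(names(channels))) dimnames(overlap) <- list(names(channels), names(channels))
  list(profiles = profiles, overlap = overlap, degenerate = norms == 0)
}
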
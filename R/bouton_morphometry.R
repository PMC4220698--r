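## bouton_morphometry: detect boutons along a traced collateral by the
## twice-axonal-diameter rule and measure their volumes by counting
## fluorescent voxels (volume = count x voxel volume; 0.00004 um^3 per
## voxel at the default 0.01 x 0.01 x 0.4 um spacing).

#' Axon skeleton trace
#'
#' @param points n x 3 matrix of skeleton coordinates (x, y, z in um),
#'   ordered along the axon; consecutive points must be distinct.
#' @param terminal length-2 logical: is the first / last trace end an
#'   axon terminal (as opposed to a cut)?
#' @return An object of class `axon_trace` with an arc-length
#'   parameterization.
#' @export
axon_trace <- function(points, terminal = c(FALSE, TRUE)) {
  points <- as.matrix(points)
  check_that(is.numeric(points) && ncol(points) == 3L && nrow(points) >= 2L,
             "`points` must be an n x 3 numeric matrix with n >= 2")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  check_that(all(seg > 0), "trace arc length must be strictly increasing")
  check_that(is.logical(terminal) && length(terminal) == 2L,
             "`terminal` must be two logical flags")
  structure(list(points = unname(points), arc = c(0, cumsum(seg)),
                 terminal = terminal),
            class = "axon_trace")
}

#' @export
print.axon_trace <- function(x, ...) {
  cat(sprintf("<axon_trace> %d points, length %.2f um\n",
              nrow(x$points), max(x$arc)))
  invisible(x)
}

## Otsu threshold on raw intensities (EBImage works on [0, 1]).
otsu_threshold <- function(v) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  img <- EBImage::Image(matrix((v - rng[1]) / (rng[2] - rng[1]), ncol = 1))
  rng[1] + EBImage::otsu(img) * (rng[2] - rng[1])
}

resolve_threshold <- function(stack, threshold) {
  if (identical(threshold, "otsu")) otsu_threshold(as.vector(stack$voxels))
  else check_number(threshold, "threshold")
}

#' Median-filter every z-slice of a stack
#'
#' Applied before morphometry to suppress shot noise in confocal
#' projections; radius-1 window by default.
#'
#' @param stack an [image_stack()].
#' @param size filter radius in pixels.
#' @return A filtered [image_stack()].
#' @export
median_filter_stack <- function(stack, size = 1) {
  stopifnot(inherits(stack, "image_stack"))
  vox <- stack$voxels
  rng <- range(vox)
  for (z in seq_len(dim(vox)[3])) {
    sl <- vox[, , z]
    if (rng[2] > rng[1]) {
      norm <- (sl - rng[1]) / (rng[2] - rng[1])
      vox[, , z] <- rng[1] + (rng[2] - rng[1]) *
        as.matrix(EBImage::medianFilter(EBImage::Image(norm), size = size))
    }
  }
  image_stack(vox, spacing = stack$spacing, unit = stack$unit,
              channel = stack$channel)
}

#' Local axon diameter along a trace
#'
#' At each skeleton point the diameter is the extent of contiguous
#' foreground along the in-plane normal to the trace, measured on the
#' z-slice nearest the point. The baseline axonal diameter is the median
#' over positions that are not candidate dilations (those exceeding 1.5x
#' the global median are excluded before the final median).
#'
#' @param stack an [image_stack()].
#' @param trace an [axon_trace()] inside the stack.
#' @param threshold numeric foreground threshold, or `"otsu"` (default)
#'   for Otsu's method on the whole stack.
#' @param max_radius furthest search distance from the skeleton (um).
#' @return An object of class `diameter_profile`: arc positions, local
#'   diameters (um), the baseline diameter and the threshold used.
#' @export
local_diameter_profile <- function(stack, trace, threshold = "otsu",
                                   max_radius = 2) {
  stopifnot(inherits(stack, "image_stack"), inherits(trace, "axon_trace"))
  thr <- resolve_threshold(stack, threshold)
  sp <- stack$spacing
  dims <- dim(stack$voxels)
  pts <- trace$points
  lims <- (dims - 1) * sp
  if (any(pts[, 1] < 0 | pts[, 1] > lims[1] | pts[, 2] < 0 | pts[, 2] > lims[2] |
            pts[, 3] < 0 | pts[, 3] > lims[3])) {
    abort("trace leaves the stack", "synmorph_bounds_error")
  }
  mask <- stack$voxels > thr
  fg_at <- function(x, y, zi) {
    i <- round(x / sp[1]) + 1L
    j <- round(y / sp[2]) + 1L
    if (i < 1L || i > dims[1] || j < 1L || j > dims[2]) return(FALSE)
    mask[i, j, zi]
  }
  n <- nrow(pts)
  step <- sp[1]
  nmax <- ceiling(max_radius / step)
  diam <- numeric(n)
  for (k in seq_len(n)) {
    k0 <- max(1L, k - 1L); k1 <- min(n, k + 1L)
    tang <- pts[k1, 1:2] - pts[k0, 1:2]
    tl <- sqrt(sum(tang^2))
    tang <- if (tl > 0) tang / tl else c(1, 0)
    nrm <- c(-tang[2], tang[1])
    zi <- min(max(round(pts[k, 3] / sp[3]) + 1L, 1L), dims[3])
    if (!fg_at(pts[k, 1], pts[k, 2], zi)) {
      diam[k] <- 0
      next
    }
    ext <- function(sgn) {
      m <- 0L
      while (m < nmax) {
        p <- pts[k, 1:2] + sgn * (m + 1L) * step * nrm
        if (!fg_at(p[1], p[2], zi)) break
        m <- m + 1L
      }
      m
    }
    diam[k] <- (ext(1) + ext(-1) + 1L) * step
  }
  if (all(diam == 0)) {
    abort("no foreground along the trace: cannot estimate a baseline diameter",
          "synmorph_degenerate_baseline")
  }
  med <- stats::median(diam[diam > 0])
  keep <- diam > 0 & diam <= 1.5 * med
  baseline <- stats::median(diam[keep])
  structure(list(arc = trace$arc, diameter = diam, baseline = baseline,
                 threshold = thr, trace = trace),
            class = "diameter_profile")
}

#' @export
print.diameter_profile <- function(x, ...) {
  cat(sprintf("<diameter_profile> %d positions, baseline %.3f um\n",
              length(x$arc), x$baseline))
  invisible(x)
}

#' Detect bouton intervals by the twice-diameter rule
#'
#' Bouton boundaries are the points at which the local diameter crosses
#' `factor` times the baseline axonal diameter (crossing positions
#' interpolated linearly in arc length). A dilation still above
#' threshold at a trace end yields a terminal bouton extending from its
#' opening crossing to the trace end.
#'
#' @param profile a [diameter_profile()].
#' @param factor dilation factor (default 2).
#' @return data frame with columns `start_arc`, `end_arc`, `terminal`.
#' @export
detect_boutons <- function(profile, factor = 2.0) {
  stopifnot(inherits(profile, "diameter_profile"))
  check_number(factor, "factor", positive = TRUE)
  check_that(profile$baseline > 0, "baseline diameter must be positive")
  thr <- factor * profile$baseline
  a <- profile$arc
  d <- profile$diameter
  above <- d > thr
  n <- length(a)
  starts <- numeric(0); ends <- numeric(0); term <- logical(0)
  open_start <- if (above[1]) a[1] else NA_real_
  open_terminal <- above[1]
  for (k in seq_len(n - 1)) {
    if (!above[k] && above[k + 1]) {
      f <- (thr - d[k]) / (d[k + 1] - d[k])
      open_start <- a[k] + f * (a[k + 1] - a[k])
      open_terminal <- FALSE
    } else if (above[k] && !above[k + 1] && !is.na(open_start)) {
      f <- (thr - d[k]) / (d[k + 1] - d[k])
      starts <- c(starts, open_start)
      ends <- c(ends, a[k] + f * (a[k + 1] - a[k]))
      term <- c(term, open_terminal)
      open_start <- NA_real_
    }
  }
  if (!is.na(open_start)) {
    starts <- c(starts, open_start)
    ends <- c(ends, a[n])
    term <- c(term, TRUE)
  }
  data.frame(start_arc = starts, end_arc = ends, terminal = term)
}

## Arc-length position of the projection of points onto the trace
## polyline. `xyz` is m x 3; returns length-m arc positions.
project_arc <- function(trace, xyz) {
  pts <- trace$points
  nseg <- nrow(pts) - 1L
  best_d2 <- rep(Inf, nrow(xyz))
  best_arc <- rep(NA_real_, nrow(xyz))
  for (s in seq_len(nseg)) {
    a <- pts[s, ]; b <- pts[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((xyz[, 1] - a[1]) * ab[1] + (xyz[, 2] - a[2]) * ab[2] +
            (xyz[, 3] - a[3]) * ab[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- xyz[, 1] - (a[1] + t * ab[1])
    dy <- xyz[, 2] - (a[2] + t * ab[2])
    dz <- xyz[, 3] - (a[3] + t * ab[3])
    d2 <- dx^2 + dy^2 + dz^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- trace$arc[s] + t[upd] * sqrt(len2)
  }
  best_arc
}

#' Bouton volume by fluorescent-voxel counting
#'
#' Counts voxels above threshold whose arc-length projection onto the
#' trace falls inside `[start_arc, end_arc)` and multiplies by the voxel
#' volume (`prod(spacing)`; 0.00004 um^3 on the default grid).
#'
#' @param stack an [image_stack()].
#' @param trace an [axon_trace()].
#' @param interval one row of [detect_boutons()] output (or a list with
#'   `start_arc`, `end_arc`, optional `terminal`).
#' @param threshold numeric or `"otsu"`.
#' @param median_filter apply a radius-1 median filter to each slice
#'   before thresholding.
#' @return one-row data frame (a bouton record): `start_arc`, `end_arc`,
#'   `terminal`, `voxel_count`, `volume` (um^3), `centroid_x`,
#'   `centroid_y`, `layer` (unassigned).
#' @export
bouton_volume <- function(stack, trace, interval, threshold = "otsu",
                          median_filter = FALSE) {
  stopifnot(inherits(stack, "image_stack"), inherits(trace, "axon_trace"))
  if (median_filter) stack <- median_filter_stack(stack)
  thr <- resolve_threshold(stack, threshold)
  start_arc <- interval$start_arc
  end_arc <- interval$end_arc
  check_that(start_arc < end_arc, "interval must have start_arc < end_arc")
  check_that(start_arc >= min(trace$arc) - 1e-9 && end_arc <= max(trace$arc) + 1e-9,
             "interval outside the trace extent")
  sp <- stack$spacing
  fg <- which(stack$voxels > thr, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    warning("no fluorescent voxels above threshold; volume 0")
    rec <- data.frame(start_arc = start_arc, end_arc = end_arc,
                      terminal = isTRUE(interval$terminal), voxel_count = 0L,
                      volume = 0, centroid_x = NA_real_, centroid_y = NA_real_,
                      layer = "unassigned")
    return(rec)
  }
  xyz <- cbind((fg[, 1] - 1) * sp[1], (fg[, 2] - 1) * sp[2], (fg[, 3] - 1) * sp[3])
  arcs <- project_arc(trace, xyz)
  inside <- arcs >= start_arc & arcs < end_arc
  cnt <- sum(inside)
  if (cnt == 0) warning("no fluorescent voxels inside the bouton interval")
  data.frame(start_arc = start_arc, end_arc = end_arc,
             terminal = isTRUE(interval$terminal),
             voxel_count = cnt, volume = cnt * prod(sp),
             centroid_x = if (cnt) mean(xyz[inside, 1]) else NA_real_,
             centroid_y = if (cnt) mean(xyz[inside, 2]) else NA_real_,
             layer = "unassigned")
}

#' Full bouton pipeline for one stack
#'
#' Diameter profile, twice-diameter detection, then voxel volumetry for
#' each detected interval.
#'
#' @inheritParams local_diameter_profile
#' @inheritParams detect_boutons
#' @inheritParams bouton_volume
#' @return data frame of bouton records (possibly 0 rows).
#' @export
measure_boutons <- function(stack, trace, threshold = "otsu", factor = 2.0,
                            median_filter = FALSE, max_radius = 2) {
  if (median_filter) stack <- median_filter_stack(stack)
  prof <- local_diameter_profile(stack, trace, threshold = threshold,
                                 max_radius = max_radius)
  iv <- detect_boutons(prof, factor = factor)
  if (nrow(iv) == 0) {
    return(data.frame(start_arc = numeric(0), end_arc = numeric(0),
                      terminal = logical(0), voxel_count = integer(0),
                      volume = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), layer = character(0)))
  }
  do.call(rbind, lapply(seq_len(nrow(iv)), function(i) {
    bouton_volume(stack, trace, iv[i, ], threshold = prof$threshold)
  }))
}

#' Assign planar points to cortical layer bands
#'
#' Layers are horizontal bands: molecular layer above `ml_pcl`,
#' Purkinje-cell layer between the two boundaries, granule-cell layer
#' below `pcl_gcl`. A point exactly on a boundary belongs to the deeper
#' (lower-y) layer. Points outside an optional vertical `extent` are
#' labelled `"unassigned"` with a warning.
#'
#' @param points data frame with columns `x`, `y` (or `centroid_x`,
#'   `centroid_y`), optionally `cell_id` and `type` (e.g. `"bouton"`,
#'   `"branch"`).
#' @param ml_pcl,pcl_gcl band boundaries (y, um), `ml_pcl > pcl_gcl`.
#' @param extent optional `c(ymin, ymax)` valid range.
#' @return list with `points` (input plus a `layer` column) and `counts`
#'   (per-layer, and per `cell_id`/`type` when present).
#' @export
assign_layers <- function(points, ml_pcl, pcl_gcl, extent = NULL) {
  if (all(c("centroid_x", "centroid_y") %in% names(points)) &&
        !all(c("x", "y") %in% names(points))) {
    points$x <- points$centroid_x
    points$y <- points$centroid_y
  }
  check_that(all(c("x", "y") %in% names(points)),
             "`points` needs x/y (or centroid_x/centroid_y) columns")
  check_number(ml_pcl, "ml_pcl"); check_number(pcl_gcl, "pcl_gcl")
  check_that(ml_pcl > pcl_gcl, "`ml_pcl` must lie above `pcl_gcl`")
  y <- points$y
  layer <- ifelse(y > ml_pcl, "ML", ifelse(y > pcl_gcl, "PCL", "GCL"))
  if (!is.null(extent)) {
    outside <- y < extent[1] | y > extent[2]
    if (any(outside)) {
      warning(sprintf("%d point(s) outside the layer extent: unassigned",
                      sum(outside)))
      layer[outside] <- "unassigned"
    }
  }
  points$layer <- factor(layer, levels = c("ML", "PCL", "GCL", "unassigned"))
  by <- list(layer = points$layer)
  if ("type" %in% names(points)) by$type <- points$type
  if ("cell_id" %in% names(points)) by$cell_id <- points$cell_id
  counts <- as.data.frame(table(by))
  names(counts)[names(counts) == "Freq"] <- "n"
  list(points = points, counts = counts)
}
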
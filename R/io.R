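## File interfaces: TIFF images/stacks (via the tiff package) and
## delimited-text annotations. All writers store float32 data; intensity
## is linearly rescaled to [0, 1] on write and the scale recorded is the
## caller's responsibility (synthetic data already lives in [0, 1]).

#' Read and write single-plane TIFF images
#'
#' @param path file path.
#' @param pixel_size physical pixel side to attach on read.
#' @param unit `"nm"` or `"um"`.
#' @return `read_image2d()` returns an [image2d()]; `write_image2d()`
#'   returns `path` invisibly.
#' @export
read_image2d <- function(path, pixel_size, unit = c("nm", "um")) {
  unit <- match.arg(unit)
  px <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(px)) == 3L) px <- px[, , 1]  # drop extra channels
  image2d(px, pixel_size = pixel_size, unit = unit)
}

#' @rdname read_image2d
#' @param image an [image2d()] to write.
#' @export
write_image2d <- function(image, path) {
  stopifnot(inherits(image, "image2d"))
  px <- image$pixels
  rng <- range(px)
  if (rng[2] > 1 || rng[1] < 0) {
    px <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1]) else px * 0
  }
  tiff::writeTIFF(px, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read and write multi-page TIFF stacks
#'
#' Pages are z-slices; pixels in page layout (y, x) are mapped to the
#' internal `[x, y, z]` voxel array.
#'
#' @param path file path.
#' @param spacing physical voxel sides `c(x, y, z)`.
#' @param unit `"um"` or `"nm"`.
#' @return `read_stack_tiff()` returns an [image_stack()].
#' @export
read_stack_tiff <- function(path, spacing, unit = c("um", "nm")) {
  unit <- match.arg(unit)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  vox <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) vox[, , z] <- t(pages[[z]])
  image_stack(vox, spacing = spacing, unit = unit)
}

#' @rdname read_stack_tiff
#' @param stack an [image_stack()] to write.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  vox <- stack$voxels
  rng <- range(vox)
  if (rng[2] > 1 || rng[1] < 0) {
    vox <- if (rng[2] > rng[1]) (vox - rng[1]) / (rng[2] - rng[1]) else vox * 0
  }
  pages <- lapply(seq_len(dim(vox)[3]), function(z) t(vox[, , z]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read line anchors from a delimited text file
#'
#' Expected columns: `id, x1, y1, x2, y2, unit` (one straight line per
#' row, coordinates in the stated unit).
#'
#' @param path CSV path.
#' @param step sampling step to attach to each anchor.
#' @return named list of [line_anchor()]s.
#' @export
read_anchors_csv <- function(path, step = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x1", "y1", "x2", "y2", "unit")
  check_that(all(need %in% names(df)),
             paste("anchor CSV must have columns:", paste(need, collapse = ", ")))
  anchors <- lapply(seq_len(nrow(df)), function(i) {
    line_anchor(c(df$x1[i], df$y1[i]), c(df$x2[i], df$y2[i]),
                step = step, unit = df$unit[i])
  })
  names(anchors) <- df$id
  anchors
}
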
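## density_map: superimpose per-cell bouton point sets in a common frame
## (soma at the origin, main axon along a fixed direction) and bin them
## into 20-um squares to map bouton density (boutons/um^2) as a heat map.

#' Per-cell arbor annotation
#'
#' @param soma soma centre `(x, y)` in um.
#' @param axon_dir main-axon direction (towards the white matter); any
#'   nonzero vector.
#' @param boutons n x 2 matrix of bouton positions (um).
#' @param branches optional m x 2 matrix of branch-point positions.
#' @return An object of class `cell_arbor`.
#' @export
cell_arbor <- function(soma, axon_dir, boutons, branches = NULL) {
  check_that(is.numeric(soma) && length(soma) == 2L && all(is.finite(soma)),
             "`soma` must be a finite (x, y) pair")
  check_that(is.numeric(axon_dir) && length(axon_dir) == 2L &&
               sum(axon_dir^2) > 0,
             "`axon_dir` must be a nonzero direction")
  boutons <- as.matrix(boutons)
  if (length(boutons) == 0) boutons <- matrix(numeric(0), ncol = 2)
  check_that(ncol(boutons) == 2L, "`boutons` must be an n x 2 matrix")
  if (!is.null(branches)) {
    branches <- as.matrix(branches)
    check_that(ncol(branches) == 2L, "`branches` must be an m x 2 matrix")
  }
  structure(list(soma = as.numeric(soma),
                 axon_dir = axon_dir / sqrt(sum(axon_dir^2)),
                 boutons = boutons, branches = branches),
            class = "cell_arbor")
}

#' Superimpose arbors in a common soma-centred frame
#'
#' Applies to each cell the rigid transform (translation plus rotation,
#' never scaling or reflection) that moves its soma to the origin and
#' its main-axon direction onto `target` (default +x). Mirror-image
#' arbors are therefore not superposed: handedness is preserved.
#'
#' @param cells list of [cell_arbor()]s.
#' @param target unit direction the axon is rotated onto.
#' @return list of transformed [cell_arbor()]s (somata at the origin).
#' @export
align_arbors <- function(cells, target = c(1, 0)) {
  check_that(is.list(cells) && length(cells) >= 1 &&
               all(vapply(cells, inherits, logical(1), "cell_arbor")),
             "`cells` must be a list of cell_arbor objects")
  check_that(is.numeric(target) && length(target) == 2L && sum(target^2) > 0,
             "`target` must be a nonzero direction")
  target <- target / sqrt(sum(target^2))
  lapply(cells, function(cell) {
    d <- cell$axon_dir
    cosang <- d[1] * target[1] + d[2] * target[2]
    sinang <- d[1] * target[2] - d[2] * target[1]  # rotation d -> target
    R <- matrix(c(cosang, sinang, -sinang, cosang), 2, 2)
    tf <- function(p) {
      if (nrow(p) == 0) return(p)
      t(R %*% (t(p) - cell$soma))
    }
    cell_arbor(soma = c(0, 0), axon_dir = target,
               boutons = tf(cell$boutons),
               branches = if (is.null(cell$branches)) NULL else tf(cell$branches))
  })
}

#' Bin points into a square-lattice density matrix
#'
#' Half-open square bins `[k*s, (k+1)*s)` anchored at `origin` (the
#' common soma position after alignment, so the soma sits at a bin
#' corner). Density is count divided by bin area.
#'
#' @param points n x 2 matrix of positions (um), or a list of matrices
#'   (pooled).
#' @param bin_side bin side length (um, default 20).
#' @param origin lattice anchor.
#' @return An object of class `density_matrix`: `counts` (rows = y bins,
#'   increasing; cols = x bins), `density` (boutons/um^2), `bin_side`,
#'   `x_breaks`/`y_breaks` (lower bin edges).
#' @export
bin_density <- function(points, bin_side = 20, origin = c(0, 0)) {
  if (is.list(points) && !is.matrix(points)) points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (length(points) == 0) points <- matrix(numeric(0), ncol = 2)
  check_number(bin_side, "bin_side", positive = TRUE)
  if (nrow(points) == 0) {
    counts <- matrix(0L, 1, 1)
    out <- list(counts = counts, density = counts / bin_side^2,
                bin_side = bin_side, x_breaks = origin[1], y_breaks = origin[2])
    class(out) <- "density_matrix"
    return(out)
  }
  ix <- floor((points[, 1] - origin[1]) / bin_side)
  iy <- floor((points[, 2] - origin[2]) / bin_side)
  xr <- range(ix); yr <- range(iy)
  counts <- matrix(0L, yr[2] - yr[1] + 1L, xr[2] - xr[1] + 1L)
  for (k in seq_along(ix)) {
    r <- iy[k] - yr[1] + 1L
    c <- ix[k] - xr[1] + 1L
    counts[r, c] <- counts[r, c] + 1L
  }
  out <- list(counts = counts, density = counts / bin_side^2,
              bin_side = bin_side,
              x_breaks = (xr[1]:xr[2]) * bin_side + origin[1],
              y_breaks = (yr[1]:yr[2]) * bin_side + origin[2])
  class(out) <- "density_matrix"
  out
}

#' @export
print.density_matrix <- function(x, ...) {
  cat(sprintf("<density_matrix> %d x %d bins of %g um, %d points\n",
              nrow(x$counts), ncol(x$counts), x$bin_side, sum(x$counts)))
  invisible(x)
}

#' Render a bouton density matrix as a heat map
#'
#' Warmest colour marks the highest density; the colour bar is labelled
#' in boutons/um^2.
#'
#' @param matrix a `density_matrix` from [bin_density()].
#' @param file optional output path (PNG); when `NULL` the plot object is
#'   returned without writing.
#' @param width,height,dpi device geometry passed to [ggplot2::ggsave()].
#' @return A ggplot object, invisibly when written to file.
#' @export
render_heatmap <- function(matrix, file = NULL, width = 5, height = 5, dpi = 150) {
  stopifnot(inherits(matrix, "density_matrix"))
  df <- expand.grid(x = matrix$x_breaks + matrix$bin_side / 2,
                    y = matrix$y_breaks + matrix$bin_side / 2)
  df$density <- as.vector(t(matrix$density))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = density)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(
      colours = c("#00007F", "#007FFF", "#7FFF7F", "#FF7F00", "#7F0000"),
      name = expression("boutons/" * mu * m^2),
      limits = c(0, max(matrix$density, 1e-12))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(x ~ (mu * m)), y = expression(y ~ (mu * m))) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height, dpi = dpi)
    return(invisible(p))
  }
  p
}
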
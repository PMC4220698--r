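## vesicle_az: active-zone bookkeeping and geometric vesicle
## classification. The AZ is a straight membrane chord; the "vicinity"
## pool is the presynaptic half-disc whose diameter is the AZ length;
## "docked" vesicles have their membrane (centre distance minus radius)
## within 10 nm of the chord, within its lateral extent. Vesicle counts
## scale linearly with AZ length, summarized by an OLS regression.

#' Active-zone membrane chord
#'
#' @param p1,p2 chord endpoints `(x, y)` in nm.
#' @param presyn_side which side of the chord is presynaptic: the sign
#'   (+1 or -1) of the cross product `(p2 - p1) x (v - p1)` for
#'   presynaptic points `v`.
#' @return An object of class `az_segment` with the chord `length` (nm).
#' @export
az_segment <- function(p1, p2, presyn_side = 1) {
  check_that(is.numeric(p1) && length(p1) == 2L && all(is.finite(p1)),
             "`p1` must be a finite (x, y) pair")
  check_that(is.numeric(p2) && length(p2) == 2L && all(is.finite(p2)),
             "`p2` must be a finite (x, y) pair")
  check_that(presyn_side %in% c(-1, 1), "`presyn_side` must be +1 or -1")
  len <- sqrt(sum((p2 - p1)^2))
  check_that(len > 0, "degenerate active zone: endpoints coincide")
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2),
                 presyn_side = presyn_side, length = len),
            class = "az_segment")
}

#' @export
print.az_segment <- function(x, ...) {
  cat(sprintf("<az_segment> length %.1f nm\n", x$length))
  invisible(x)
}

#' Vesicle scene: an AZ chord plus vesicle centres
#'
#' @param az an [az_segment()].
#' @param centers n x 2 matrix of vesicle centres (nm).
#' @param radius vesicle radius (nm), shared or per-vesicle.
#' @return An object of class `vesicle_scene`.
#' @export
vesicle_scene <- function(az, centers, radius) {
  stopifnot(inherits(az, "az_segment"))
  centers <- as.matrix(centers)
  if (length(centers) == 0) centers <- matrix(numeric(0), ncol = 2)
  check_that(ncol(centers) == 2L, "`centers` must be an n x 2 matrix")
  check_that(is.numeric(radius) && all(radius > 0) &&
               length(radius) %in% c(1L, nrow(centers), max(1L, nrow(centers))),
             "`radius` must be positive (shared or per-vesicle)")
  structure(list(az = az, centers = centers, radius = radius),
            class = "vesicle_scene")
}

#' @export
print.vesicle_scene <- function(x, ...) {
  cat(sprintf("<vesicle_scene> %d vesicles, AZ %.1f nm\n",
              nrow(x$centers), x$az$length))
  invisible(x)
}

#' Classify vesicles into the AZ-vicinity and docked pools
#'
#' Vicinity: vesicle centre inside the presynaptic half-disc of diameter
#' equal to the AZ length, centred on the AZ midpoint. Docked: vesicle
#' membrane closer than `dock_dist` to the AZ chord
#' (perpendicular centre distance minus radius, or the centre distance
#' itself with `from = "center"`) and laterally within the chord;
#' docked vesicles always count in the vicinity pool
#' (`n_docked <= n_vicinity`).
#'
#' @param scene a [vesicle_scene()].
#' @param dock_dist docking distance (nm, default 10).
#' @param from measure docking from the `"membrane"` (centre distance
#'   minus radius, default) or from the `"center"`.
#' @return list of class `vesicle_counts`: `n_docked`, `n_vicinity`,
#'   `vicinity_area` (nm^2), `docked`/`vicinity` logical vectors.
#' @export
classify_vesicles <- function(scene, dock_dist = 10,
                              from = c("membrane", "center")) {
  stopifnot(inherits(scene, "vesicle_scene"))
  from <- match.arg(from)
  check_number(dock_dist, "dock_dist", positive = TRUE)
  az <- scene$az
  n <- nrow(scene$centers)
  radius <- rep(scene$radius, length.out = max(n, 1L))
  if (n == 0) {
    out <- list(n_docked = 0L, n_vicinity = 0L,
                vicinity_area = pi * (az$length / 2)^2 / 2,
                docked = logical(0), vicinity = logical(0),
                dock_dist = dock_dist, from = from)
    class(out) <- "vesicle_counts"
    return(out)
  }
  mid <- (az$p1 + az$p2) / 2
  u <- (az$p2 - az$p1) / az$length          # chord direction
  rel <- sweep(scene$centers, 2, mid)
  along <- rel[, 1] * u[1] + rel[, 2] * u[2]           # lateral position
  cross <- (rel[, 1] * (-u[2]) + rel[, 2] * u[1])       # signed offset
  side_ok <- az$presyn_side * (u[1] * rel[, 2] - u[2] * rel[, 1]) > 0
  r2 <- rel[, 1]^2 + rel[, 2]^2
  vicinity <- side_ok & r2 <= (az$length / 2)^2
  perp <- abs(cross)
  gap <- if (from == "membrane") perp - radius else perp
  docked <- side_ok & gap < dock_dist & abs(along) <= az$length / 2
  docked <- docked & vicinity                      # docked subset of vicinity
  out <- list(n_docked = sum(docked), n_vicinity = sum(vicinity),
              vicinity_area = pi * (az$length / 2)^2 / 2,
              docked = docked, vicinity = vicinity,
              dock_dist = dock_dist, from = from)
  class(out) <- "vesicle_counts"
  out
}

#' @export
print.vesicle_counts <- function(x, ...) {
  cat(sprintf("<vesicle_counts> %d docked / %d vicinity (area %.0f nm^2)\n",
              x$n_docked, x$n_vicinity, x$vicinity_area))
  invisible(x)
}

#' Vesicle density in the AZ vicinity
#'
#' Vicinity count divided by the half-disc area, expressed per
#' `area_unit` (default a (100 nm)^2 = 1e4 nm^2 patch). The unit is
#' explicit in the output: printed "per 100 nm^2" figures in the
#' literature are dimensionally ambiguous at half-disc scale, so no
#' silent unit is assumed.
#'
#' @param counts a `vesicle_counts` from [classify_vesicles()].
#' @param area_unit reference area (nm^2, default `100^2`).
#' @return list: `density` (vesicles per `area_unit`), `n`, `area`,
#'   `area_unit`.
#' @export
vesicle_density <- function(counts, area_unit = 100^2) {
  stopifnot(inherits(counts, "vesicle_counts"))
  check_number(area_unit, "area_unit", positive = TRUE)
  check_that(counts$vicinity_area > 0, "vicinity area must be positive")
  list(density = counts$n_vicinity / (counts$vicinity_area / area_unit),
       n = counts$n_vicinity, area = counts$vicinity_area,
       area_unit = area_unit)
}

#' Vesicle count versus AZ length regression
#'
#' Ordinary least squares of vesicle count on AZ length, with the
#' Pearson correlation and its two-tailed p value. Both `r` and `r2`
#' are reported: figure legends sometimes label the plain correlation
#' "coefficient of determination", so neither is left implicit.
#'
#' @param az_length AZ lengths (nm).
#' @param count vesicle counts (same length, >= 3 records).
#' @return list of class `vesicle_regression`: `slope` (vesicles/nm),
#'   `intercept`, `r`, `r2`, `p`, `n`.
#' @export
regress_vesicles_vs_az <- function(az_length, count) {
  check_that(is.numeric(az_length) && is.numeric(count) &&
               length(az_length) == length(count),
             "`az_length` and `count` must be numeric vectors of equal length")
  check_that(length(az_length) >= 3, "need at least 3 records")
  check_that(stats::var(az_length) > 0,
             "degenerate regression: AZ lengths are constant",
             class = "synmorph_degenerate_regression")
  fit <- stats::lm(count ~ az_length)
  ct <- suppressWarnings(stats::cor.test(az_length, count,
                                         alternative = "two.sided",
                                         method = "pearson"))
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
              p = ct$p.value, n = length(az_length))
  class(out) <- "vesicle_regression"
  out
}

#' @export
print.vesicle_regression <- function(x, ...) {
  cat(sprintf("<vesicle_regression> S = %.4f vesicles/nm, r = %.3f (r2 = %.3f), p = %.3g, n = %d\n",
              x$slope, x$r, x$r2, x$p, x$n))
  invisible(x)
}

#' Per-group active-zone summary
#'
#' Mean AZ count per bouton and mean AZ length, each with its SEM, per
#' group (e.g. genotype).
#'
#' @param az data frame with columns `bouton_id`, `az_length` and
#'   optionally `group` (single group assumed when absent).
#' @return data frame: one row per group with `n_boutons`,
#'   `mean_az_per_bouton`, `sem_az_per_bouton`, `mean_az_length`,
#'   `sem_az_length`.
#' @export
az_summary <- function(az) {
  check_that(is.data.frame(az) && nrow(az) >= 1 &&
               all(c("bouton_id", "az_length") %in% names(az)),
             "`az` must be a non-empty data frame with bouton_id and az_length")
  if (!"group" %in% names(az)) az$group <- "all"
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  do.call(rbind, lapply(split(az, az$group), function(g) {
    per_bouton <- as.numeric(table(g$bouton_id))
    data.frame(group = g$group[1],
               n_boutons = length(per_bouton),
               mean_az_per_bouton = mean(per_bouton),
               sem_az_per_bouton = sem(per_bouton),
               mean_az_length = mean(g$az_length),
               sem_az_length = sem(g$az_length),
               row.names = NULL)
  }))
}
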
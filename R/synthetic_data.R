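## synthetic_data: generators for every input the measurement stages
## consume, each returning its ground truth so recovery can be tested
## without any real micrograph.
##
## All generators are deterministic given their spec (which embeds a
## seed) and leave the caller's RNG state untouched. Noise is additive
## Gaussian, clipped at zero.

# ---------------------------------------------------------------------------
# EM cross-section density profiles

#' Specification of a synthetic cleft density profile
#'
#' Describes a 1D electron-density profile across a symmetric synapse:
#' two electron-dense membrane peaks of density `peak_density` separated
#' by `membrane_separation`, flanking a brighter cleft valley of density
#' `valley_density`, inside a window of `window_length`. Membrane
#' cross-sections are triangular ramps (half-width `membrane_width_param`)
#' or Gaussians (sigma `membrane_width_param`); Gaussian membranes
#' superpose additively, so their realized peak density can slightly
#' exceed `peak_density` when they overlap.
#'
#' @param membrane_separation true peak-to-peak distance (nm).
#' @param membrane_shape `"triangular"` or `"gaussian"`.
#' @param membrane_width_param ramp half-width or Gaussian sigma (nm).
#' @param peak_density,valley_density density levels (arbitrary units),
#'   `peak_density > valley_density`.
#' @param window_length profile window (nm, default 100); must cover the
#'   membranes: `window_length >= membrane_separation + 2 * membrane_width_param`.
#' @param step sampling step (nm, default 1).
#' @param noise_sd additive Gaussian noise SD (density units).
#' @param seed integer seed.
#' @return An object of class `cleft_profile_spec`.
#' @export
cleft_profile_spec <- function(membrane_separation,
                               membrane_shape = c("triangular", "gaussian"),
                               membrane_width_param = 10,
                               peak_density = 1, valley_density = 0,
                               window_length = 100, step = 1,
                               noise_sd = 0, seed = 1L) {
  membrane_shape <- match.arg(membrane_shape)
  check_number(membrane_separation, "membrane_separation", positive = TRUE)
  check_number(membrane_width_param, "membrane_width_param", positive = TRUE)
  check_number(window_length, "window_length", positive = TRUE)
  check_number(step, "step", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  check_number(peak_density, "peak_density")
  check_number(valley_density, "valley_density")
  check_that(peak_density > valley_density,
             "`peak_density` must exceed `valley_density`")
  check_that(window_length >= membrane_separation + 2 * membrane_width_param,
             "window too short: need window_length >= membrane_separation + 2 * membrane_width_param")
  structure(list(membrane_separation = membrane_separation,
                 membrane_shape = membrane_shape,
                 membrane_width_param = membrane_width_param,
                 peak_density = peak_density, valley_density = valley_density,
                 window_length = window_length, step = step,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cleft_profile_spec")
}

## Noise-free analytic density at positions x (nm). Membrane centres sit
## symmetrically about the window midpoint.
cleft_density_fun <- function(spec) {
  c1 <- spec$window_length / 2 - spec$membrane_separation / 2
  c2 <- spec$window_length / 2 + spec$membrane_separation / 2
  w <- spec$membrane_width_param
  amp <- spec$peak_density - spec$valley_density
  if (spec$membrane_shape == "triangular") {
    function(x) {
      s <- pmax(0, pmax(1 - abs(x - c1) / w, 1 - abs(x - c2) / w))
      spec$valley_density + amp * s
    }
  } else {
    function(x) {
      s <- exp(-(x - c1)^2 / (2 * w^2)) + exp(-(x - c2)^2 / (2 * w^2))
      spec$valley_density + amp * s
    }
  }
}

## Evaluate the 10%-drop rule on a fine grid of the analytic, noise-free
## profile. Independent of measure_cleft_width(): peaks are located as
## the argmax of each half-window, the valley as the argmin between
## them, and crossings by linear interpolation on the fine grid.
drop_rule_ground_truth <- function(spec, drop_fraction = 0.10, grid_step = 0.01) {
  f <- cleft_density_fun(spec)
  x <- seq(0, spec$window_length, by = grid_step)
  y <- f(x)
  mid <- which.min(abs(x - spec$window_length / 2))
  i_pre <- which.max(y[1:mid])
  i_post <- mid + which.max(y[(mid + 1):length(y)])
  iv <- i_pre + which.min(y[i_pre:i_post]) - 1L
  v <- y[iv]
  cross_from <- function(ip, iv) {
    thr <- y[ip] - drop_fraction * (y[ip] - v)
    dir <- sign(iv - ip)
    i <- ip
    while (i != iv) {
      j <- i + dir
      if (y[i] >= thr && y[j] < thr) {
        return(x[i] + dir * grid_step * (y[i] - thr) / (y[i] - y[j]))
      }
      i <- j
    }
    NA_real_
  }
  pre_b <- cross_from(i_pre, iv)
  post_b <- cross_from(i_post, iv)
  list(width = post_b - pre_b, pre_boundary = pre_b, post_boundary = post_b,
       pre_peak_pos = x[i_pre], post_peak_pos = x[i_post],
       peak_separation = x[i_post] - x[i_pre],
       valley_pos = x[iv], drop_fraction = drop_fraction)
}

#' Generate a synthetic cleft density profile with ground truth
#'
#' Samples the analytic two-membrane density at `step` spacing over the
#' window, adds clipped Gaussian noise, and returns alongside it the
#' noise-free ground-truth geometry: the width the 10%-drop rule yields
#' on a 0.01-nm grid of the analytic profile, the true peak positions and
#' boundaries.
#'
#' @param spec a [cleft_profile_spec()].
#' @param drop_fraction drop fraction used for the ground-truth width
#'   (default 0.10).
#' @return list with `profile` (an [intensity_profile()], electron-density
#'   polarity), `truth` (ground-truth geometry) and `spec`.
#' @export
gen_cleft_profile <- function(spec, drop_fraction = 0.10) {
  stopifnot(inherits(spec, "cleft_profile_spec"))
  f <- cleft_density_fun(spec)
  x <- seq(0, spec$window_length, by = spec$step)
  y <- f(x)
  if (spec$noise_sd > 0) {
    y <- with_seed(spec$seed, pmax(0, y + stats::rnorm(length(y), 0, spec$noise_sd)))
  }
  list(profile = intensity_profile(y, step = spec$step, origin = 0, unit = "nm"),
       truth = drop_rule_ground_truth(spec, drop_fraction = drop_fraction),
       spec = spec)
}

#' Generate a 2D synthetic EM patch with a membrane anchor
#'
#' Extrudes the analytic cleft density along the membrane tangent (image
#' y axis) into a patch, optionally bowing both membranes along a shared
#' circular arc of the given curvature. The returned [cleft_anchor()]
#' points across the cleft at the patch midline; sampling it with the
#' cleft-width module recovers the specified geometry.
#'
#' @param spec a [cleft_profile_spec()]; `step` doubles as the pixel size.
#' @param curvature membrane curvature (1/nm); 0 gives straight membranes.
#' @param patch_height patch extent along the membranes (nm, default 60,
#'   enough for five lines 10 nm apart with margin).
#' @return list with `image` (an [image2d()], nm pixels), `anchor`,
#'   `truth` (as in [gen_cleft_profile()]) and `spec`.
#' @export
gen_em_patch <- function(spec, curvature = 0, patch_height = 60) {
  stopifnot(inherits(spec, "cleft_profile_spec"))
  check_number(curvature, "curvature", nonneg = TRUE)
  check_number(patch_height, "patch_height", positive = TRUE)
  xs <- seq(0, spec$window_length, by = spec$step)
  ys <- seq(0, patch_height, by = spec$step)
  y0 <- patch_height / 2
  if (curvature > 0) {
    R <- 1 / curvature
    check_that(R >= max(abs(ys - y0)),
               "curvature too strong: membrane arc exits the patch",
             class = "synmorph_validation_error")
    shift <- R - sqrt(R^2 - (ys - y0)^2)
  } else {
    shift <- rep(0, length(ys))
  }
  outer_edge <- spec$window_length / 2 + spec$membrane_separation / 2 +
    spec$membrane_width_param
  check_that(outer_edge + max(shift) <= spec$window_length,
             "membranes exit the patch under this curvature",
             class = "synmorph_validation_error")
  f <- cleft_density_fun(spec)
  pixels <- t(vapply(seq_along(ys), function(i) f(xs - shift[i]),
                     numeric(length(xs))))  # rows = y, cols = x
  if (spec$noise_sd > 0) {
    pixels <- with_seed(spec$seed, {
      out <- pixels + matrix(stats::rnorm(length(pixels), 0, spec$noise_sd),
                             nrow = nrow(pixels))
      out[out < 0] <- 0
      out
    })
  }
  list(image = image2d(pixels, pixel_size = spec$step, unit = "nm"),
       anchor = cleft_anchor(c(spec$window_length / 2, y0), c(1, 0), unit = "nm"),
       truth = drop_rule_ground_truth(spec),
       spec = spec)
}

# ---------------------------------------------------------------------------
# Confocal bouton stacks

#' Specification of a synthetic bouton-bearing axon stack
#'
#' A straight tube (the axon collateral) of diameter `axon_diameter` runs
#' along the x axis at the field centre; spherical bouton dilations of
#' the given radii are centred on the axis at the given arc positions.
#' The voxel grid is anisotropic, defaulting to 0.01 x 0.01 x 0.4 um.
#'
#' @param voxel_spacing `(x, y, z)` voxel sides (um).
#' @param extent field extent `(x, y, z)` in um.
#' @param axon_diameter tube diameter (um); 0 suppresses the tube.
#' @param bouton_centers arc (x) positions of bouton centres (um).
#' @param bouton_radii bouton radii (um); each must exceed the tube
#'   radius.
#' @param background_level,foreground_level voxel intensities.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed.
#' @return An object of class `bouton_stack_spec`.
#' @export
bouton_stack_spec <- function(voxel_spacing = c(0.01, 0.01, 0.4),
                              extent = c(8, 3, 2.4),
                              axon_diameter = 0.5,
                              bouton_centers = numeric(0),
                              bouton_radii = numeric(0),
                              background_level = 0, foreground_level = 1,
                              noise_sd = 0, seed = 1L) {
  check_that(is.numeric(voxel_spacing) && length(voxel_spacing) == 3L &&
               all(voxel_spacing > 0), "`voxel_spacing` must be 3 positive sides")
  check_that(is.numeric(extent) && length(extent) == 3L && all(extent > 0),
             "`extent` must be 3 positive lengths")
  check_number(axon_diameter, "axon_diameter", nonneg = TRUE)
  check_that(length(bouton_centers) == length(bouton_radii),
             "`bouton_centers` and `bouton_radii` lengths differ")
  check_that(all(bouton_radii > axon_diameter / 2),
             "every bouton radius must exceed the axon radius")
  check_number(background_level, "background_level")
  check_number(foreground_level, "foreground_level")
  check_that(foreground_level > background_level,
             "`foreground_level` must exceed `background_level`")
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  if (length(bouton_centers)) {
    inside <- bouton_centers - bouton_radii >= 0 &
      bouton_centers + bouton_radii <= extent[1] &
      bouton_radii <= extent[2] / 2 & bouton_radii <= extent[3] / 2
    check_that(all(inside), "a bouton extends outside the field")
  }
  structure(list(voxel_spacing = as.numeric(voxel_spacing),
                 extent = as.numeric(extent),
                 axon_diameter = axon_diameter,
                 bouton_centers = as.numeric(bouton_centers),
                 bouton_radii = as.numeric(bouton_radii),
                 background_level = background_level,
                 foreground_level = foreground_level,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "bouton_stack_spec")
}

## Sphere/tube overlap volume by numerical integration on a transverse
## grid 10x finer than the in-plane voxel grid (the chord through the
## sphere is exact along the tube axis; the tube cross-section is
## discretized isotropically so the coarse z spacing does not limit the
## ground-truth accuracy).
sphere_tube_overlap <- function(radius, tube_radius, spacing) {
  if (tube_radius <= 0) return(0)
  a <- min(tube_radius, radius)
  dy <- min(spacing[1:2]) / 10
  dz <- dy
  ys <- seq(-a, a, by = dy)
  zs <- seq(-a, a, by = dz)
  rho2 <- outer(ys^2, zs^2, "+")
  inside <- rho2 <= tube_radius^2 & rho2 <= radius^2
  chord <- 2 * sqrt(pmax(0, radius^2 - rho2))
  sum(chord[inside]) * dy * dz
}

#' Generate a synthetic bouton stack with analytic ground truth
#'
#' Rasterizes the tube-plus-spheres geometry onto the anisotropic voxel
#' grid (voxel-centre inclusion), adds clipped Gaussian noise, and
#' returns the axon skeleton as an [axon_trace()] plus per-bouton ground
#' truth: the analytic sphere volume, the sphere/tube overlap (numerical,
#' 10x finer transverse grid) and the volume the bouton adds beyond the
#' tube.
#'
#' @param spec a [bouton_stack_spec()].
#' @param trace_step skeleton sampling step along the axon (um).
#' @return list with `stack` (an [image_stack()]), `trace`, `truth`
#'   (data frame: centre, radius, vol_sphere, vol_overlap, vol_added) and
#'   `spec`.
#' @export
gen_bouton_stack <- function(spec, trace_step = 0.05) {
  stopifnot(inherits(spec, "bouton_stack_spec"))
  sp <- spec$voxel_spacing
  xs <- seq(0, spec$extent[1], by = sp[1])
  ys <- seq(0, spec$extent[2], by = sp[2])
  zs <- seq(0, spec$extent[3], by = sp[3])
  y0 <- spec$extent[2] / 2; z0 <- spec$extent[3] / 2
  rho2 <- outer((ys - y0)^2, (zs - z0)^2, "+")     # [ny, nz]
  vox <- array(spec$background_level, dim = c(length(xs), length(ys), length(zs)))
  amp <- spec$foreground_level - spec$background_level
  if (spec$axon_diameter > 0) {
    tube <- rho2 <= (spec$axon_diameter / 2)^2
    if (any(tube)) {
      idx <- which(tube, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        vox[, idx[r, 1], idx[r, 2]] <- spec$foreground_level
      }
    }
  }
  for (b in seq_along(spec$bouton_centers)) {
    cb <- spec$bouton_centers[b]; rb <- spec$bouton_radii[b]
    xi <- which(abs(xs - cb) <= rb)
    for (i in xi) {
      inside <- rho2 <= rb^2 - (xs[i] - cb)^2
      if (any(inside)) {
        slice <- vox[i, , ]
        slice[inside] <- spec$foreground_level
        vox[i, , ] <- slice
      }
    }
  }
  if (spec$noise_sd > 0) {
    vox <- with_seed(spec$seed, {
      out <- vox + array(stats::rnorm(length(vox), 0, spec$noise_sd), dim = dim(vox))
      out[out < 0] <- 0
      out
    })
  }
  truth <- data.frame(
    center = spec$bouton_centers,
    radius = spec$bouton_radii,
    vol_sphere = 4 / 3 * pi * spec$bouton_radii^3,
    vol_overlap = vapply(spec$bouton_radii, sphere_tube_overlap,
                         numeric(1), tube_radius = spec$axon_diameter / 2,
                         spacing = sp)
  )
  truth$vol_added <- truth$vol_sphere - truth$vol_overlap
  tx <- seq(0, spec$extent[1], by = trace_step)
  trace <- axon_trace(cbind(tx, y0, z0))
  list(stack = image_stack(vox, spacing = sp, unit = "um", channel = "biocytin"),
       trace = trace, truth = truth, spec = spec)
}

# ---------------------------------------------------------------------------
# Vesicle scenes around an active zone

#' Specification of a synthetic vesicle scene
#'
#' Places vesicles of a common radius around a straight active-zone (AZ)
#' chord of length `az_length` lying on the x axis with the presynaptic
#' side at y > 0: `n_docked` vesicles whose membrane lies closer than
#' `dock_dist` to the AZ chord (and within its lateral extent),
#' `n_vicinity` further vesicles inside the presynaptic half-disc of
#' diameter `az_length`, and `n_outside` vesicles outside that half-disc.
#'
#' @param az_length AZ chord length (nm).
#' @param n_docked,n_vicinity,n_outside vesicle counts.
#' @param vesicle_radius vesicle radius (nm, default 20).
#' @param dock_dist docking distance (nm, default 10).
#' @param seed integer seed.
#' @return An object of class `vesicle_scene_spec`.
#' @export
vesicle_scene_spec <- function(az_length, n_docked = 0, n_vicinity = 0,
                               n_outside = 0, vesicle_radius = 20,
                               dock_dist = 10, seed = 1L) {
  check_number(az_length, "az_length", positive = TRUE)
  n_docked <- check_count(n_docked, "n_docked")
  n_vicinity <- check_count(n_vicinity, "n_vicinity")
  n_outside <- check_count(n_outside, "n_outside")
  check_number(vesicle_radius, "vesicle_radius", positive = TRUE)
  check_number(dock_dist, "dock_dist", positive = TRUE)
  if (n_docked + n_vicinity > 0) {
    check_that(az_length / 2 > vesicle_radius + dock_dist,
               "AZ too short to hold vesicles of this radius inside its half-disc")
  }
  structure(list(az_length = az_length, n_docked = n_docked,
                 n_vicinity = n_vicinity, n_outside = n_outside,
                 vesicle_radius = vesicle_radius, dock_dist = dock_dist,
                 seed = as.integer(seed)),
            class = "vesicle_scene_spec")
}

#' Generate a labelled vesicle scene
#'
#' Docked vesicles satisfy the membrane-distance rule by construction
#' (centre height sampled in `[radius, radius + dock_dist)` over the
#' chord); vicinity vesicles fall inside the half-disc but fail the
#' docking rule; outside vesicles fall on a ring beyond the half-disc.
#'
#' @param spec a [vesicle_scene_spec()].
#' @return list with `scene` (a [vesicle_scene()]), `labels`
#'   (`"docked"`, `"vicinity"` or `"outside"` per vesicle) and `truth`
#'   (`n_docked`, and `n_vicinity` counting docked vesicles as the
#'   classifier does) and `spec`.
#' @export
gen_vesicle_scene <- function(spec) {
  stopifnot(inherits(spec, "vesicle_scene_spec"))
  L <- spec$az_length; r <- spec$vesicle_radius; dd <- spec$dock_dist
  half_r <- L / 2
  pts <- with_seed(spec$seed, {
    out <- matrix(numeric(0), ncol = 2)
    if (spec$n_docked > 0) {
      y <- stats::runif(spec$n_docked, r + 0.02 * dd, r + 0.95 * dd)
      xmax <- pmin(sqrt(pmax(0, (0.99 * half_r)^2 - y^2)), 0.99 * half_r)
      x <- stats::runif(spec$n_docked, -xmax, xmax)
      out <- rbind(out, cbind(x, y))
    }
    if (spec$n_vicinity > 0) {
      got <- 0
      acc <- matrix(0, spec$n_vicinity, 2)
      ymin <- r + 1.05 * dd
      while (got < spec$n_vicinity) {
        rho <- 0.98 * half_r * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, pi)
        x <- rho * cos(th); y <- rho * sin(th)
        docked <- (y - r) < dd && abs(x) <= half_r
        if (y >= ymin && !docked) {
          got <- got + 1
          acc[got, ] <- c(x, y)
        }
      }
      out <- rbind(out, acc)
    }
    if (spec$n_outside > 0) {
      rho <- stats::runif(spec$n_outside, 1.1 * half_r, 1.6 * half_r)
      th <- stats::runif(spec$n_outside, -pi, pi)
      out <- rbind(out, cbind(rho * cos(th), rho * sin(th)))
    }
    out
  })
  labels <- rep(c("docked", "vicinity", "outside"),
                c(spec$n_docked, spec$n_vicinity, spec$n_outside))
  az <- az_segment(c(-half_r, 0), c(half_r, 0), presyn_side = 1)
  scene <- vesicle_scene(az, pts, radius = spec$vesicle_radius)
  list(scene = scene, labels = labels,
       truth = list(n_docked = spec$n_docked,
                    n_vicinity = spec$n_docked + spec$n_vicinity),
       spec = spec)
}

# ---------------------------------------------------------------------------
# Planar bouton point patterns

#' Specification of a layered synthetic bouton point pattern
#'
#' Each simulated cell contributes a homogeneous Poisson bouton pattern
#' per cortical layer band (molecular, Purkinje-cell and granule-cell
#' layers as horizontal bands in the cell's canonical frame, soma at the
#' origin, main axon pointing towards negative y / the white matter).
#' Cells are then placed at random positions and orientations so that
#' arbor alignment can be exercised.
#'
#' @param n_cells number of cells.
#' @param rates named bouton intensities (boutons/um^2) for bands
#'   `ML`, `PCL`, `GCL`.
#' @param field_width band width in x (um).
#' @param bands named list of `c(ymin, ymax)` per layer in the canonical
#'   frame.
#' @param seed integer seed.
#' @return An object of class `point_pattern_spec`.
#' @export
point_pattern_spec <- function(n_cells = 10,
                               rates = c(ML = 0.001, PCL = 0.005, GCL = 0.002),
                               field_width = 300,
                               bands = list(ML = c(0, 150), PCL = c(-20, 0),
                                            GCL = c(-140, -20)),
                               seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells")
  check_that(n_cells >= 1, "`n_cells` must be >= 1")
  check_that(is.numeric(rates) && all(rates >= 0) && !is.null(names(rates)),
             "`rates` must be named non-negative intensities")
  check_that(all(names(rates) %in% names(bands)),
             "every rate needs a matching band")
  check_number(field_width, "field_width", positive = TRUE)
  structure(list(n_cells = n_cells, rates = rates,
                 field_width = field_width, bands = bands,
                 seed = as.integer(seed)),
            class = "point_pattern_spec")
}

#' Generate per-cell bouton point patterns with layer ground truth
#'
#' @param spec a [point_pattern_spec()].
#' @return list with `cells` (list of [cell_arbor()]s in world
#'   coordinates), `canonical` (per-cell bouton matrices in the common
#'   frame), `truth` (per-cell per-layer counts and per-layer expected
#'   counts `rate * area`) and `spec`.
#' @export
gen_point_pattern <- function(spec) {
  stopifnot(inherits(spec, "point_pattern_spec"))
  W <- spec$field_width
  layer_names <- names(spec$rates)
  areas <- vapply(layer_names, function(l) W * diff(spec$bands[[l]]), numeric(1))
  with_seed(spec$seed, {
    canonical <- vector("list", spec$n_cells)
    cells <- vector("list", spec$n_cells)
    counts <- matrix(0L, spec$n_cells, length(layer_names),
                     dimnames = list(NULL, layer_names))
    for (ci in seq_len(spec$n_cells)) {
      pts <- matrix(numeric(0), ncol = 2)
      for (l in layer_names) {
        n <- stats::rpois(1, spec$rates[[l]] * areas[[l]])
        counts[ci, l] <- n
        if (n > 0) {
          band <- spec$bands[[l]]
          pts <- rbind(pts, cbind(stats::runif(n, -W / 2, W / 2),
                                  stats::runif(n, band[1], band[2])))
        }
      }
      canonical[[ci]] <- pts
      ## random rigid placement; canonical axon direction is (0, -1)
      theta <- stats::runif(1, -pi, pi)
      soma <- stats::runif(2, -100, 100)
      R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      world <- if (nrow(pts)) t(R %*% t(pts)) + rep(soma, each = nrow(pts)) else pts
      cells[[ci]] <- cell_arbor(soma = soma, axon_dir = as.numeric(R %*% c(0, -1)),
                                boutons = world)
    }
    list(cells = cells, canonical = canonical,
         truth = list(counts = counts,
                      expected = spec$rates * areas),
         spec = spec)
  })
}
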
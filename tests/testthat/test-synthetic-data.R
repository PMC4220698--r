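test_that("triangular cleft profiles carry the closed-form drop-rule width", {
  ## peaks at 30 and 70 nm, ramps 10 nm: boundaries sit 10% of the ramp
  ## inside each peak, so width = 40 - 2 * 0.1 * 10 = 38 nm
  spec <- cleft_profile_spec(40, "triangular", 10, peak_density = 1,
                             valley_density = 0, step = 1, noise_sd = 0)
  g <- gen_cleft_profile(spec)
  expect_equal(g$truth$width, 38, tolerance = 1e-3)
  expect_equal(g$truth$peak_separation, 40, tolerance = 1e-3)
  expect_length(g$profile$samples, 101)
})

test_that("gaussian ground truth matches an independent root-finding oracle", {
  for (sep in c(22, 28, 34)) {
    spec <- cleft_profile_spec(sep, "gaussian", 5, noise_sd = 0)
    g <- gen_cleft_profile(spec)
    oracle <- drop_rule_oracle(sep, "gaussian", 5)
    expect_equal(g$truth$width, oracle$width, tolerance = 0.02)
  }
})

test_that("profile generation is deterministic in the seed", {
  spec <- cleft_profile_spec(25, "gaussian", 5, noise_sd = 0.1, seed = 11)
  expect_identical(gen_cleft_profile(spec)$profile$samples,
                   gen_cleft_profile(spec)$profile$samples)
  spec2 <- cleft_profile_spec(25, "gaussian", 5, noise_sd = 0.1, seed = 12)
  expect_false(identical(gen_cleft_profile(spec)$profile$samples,
                         gen_cleft_profile(spec2)$profile$samples))
})

test_that("cleft profile spec invariants are enforced", {
  expect_error(cleft_profile_spec(-5, "triangular", 10), "must be > 0")
  expect_error(cleft_profile_spec(40, "triangular", 10, window_length = -50),
               "must be > 0")
  expect_error(cleft_profile_spec(90, "triangular", 10, window_length = 100),
               "window too short")
  expect_error(cleft_profile_spec(40, "triangular", 10, peak_density = 0,
                                  valley_density = 0.5), "must exceed")
})

test_that("flat EM patches reproduce the 1D profile row by row", {
  spec <- cleft_profile_spec(30, "triangular", 8, noise_sd = 0)
  patch <- gen_em_patch(spec, curvature = 0)
  prof <- gen_cleft_profile(spec)$profile$samples
  for (row in c(1, 20, nrow(patch$image$pixels))) {
    expect_equal(unname(patch$image$pixels[row, ]), prof, tolerance = 1e-12)
  }
})

test_that("the estimator recovers a constructed 22-nm separation patch", {
  spec <- cleft_profile_spec(22, "gaussian", 4, noise_sd = 0)
  patch <- gen_em_patch(spec, curvature = 0)
  m <- measure_synapse(patch$image, patch$anchor, method = "manual")
  expect_equal(m$width, 22, tolerance = spec$step)
})

test_that("too-strong curvature pushes membranes out of the patch", {
  spec <- cleft_profile_spec(40, "triangular", 10, window_length = 100)
  expect_error(gen_em_patch(spec, curvature = 0.2),
               class = "synmorph_validation_error")
})

test_that("bouton-free stacks yield no detections", {
  g <- gen_bouton_stack(bouton_stack_spec(extent = c(3, 1.5, 2.4),
                                          axon_diameter = 0.4))
  recs <- measure_boutons(g$stack, g$trace, threshold = 0.5)
  expect_equal(nrow(recs), 0)
})

test_that("an isolated unit sphere has the closed-form volume as ground truth", {
  g <- gen_bouton_stack(bouton_stack_spec(extent = c(4, 3, 2.4),
                                          axon_diameter = 0,
                                          bouton_centers = 2, bouton_radii = 1))
  expect_equal(g$truth$vol_sphere, 4 / 3 * pi, tolerance = 1e-12)
  expect_equal(g$truth$vol_overlap, 0)
})

test_that("rasterized sphere voxel count matches an exhaustive inclusion oracle", {
  r <- 0.997  # off-lattice radius: no voxel centre sits exactly on the boundary
  spec <- bouton_stack_spec(extent = c(3, 2.4, 2.4), axon_diameter = 0,
                            bouton_centers = 1.5, bouton_radii = r)
  g <- gen_bouton_stack(spec)
  ## oracle: voxel-centre inclusion test on the full grid
  sp <- spec$voxel_spacing
  xs <- seq(0, spec$extent[1], by = sp[1])
  ys <- seq(0, spec$extent[2], by = sp[2])
  zs <- seq(0, spec$extent[3], by = sp[3])
  cnt <- 0L
  for (k in seq_along(zs)) {
    dz2 <- (zs[k] - spec$extent[3] / 2)^2
    if (dz2 > r^2) next
    dy2 <- (ys - spec$extent[2] / 2)^2
    for (j in which(dy2 + dz2 <= r^2)) {
      cnt <- cnt + sum((xs - 1.5)^2 <= r^2 - dy2[j] - dz2)
    }
  }
  expect_equal(sum(g$stack$voxels > 0.5), cnt)
  expect_equal(cnt * prod(sp), 4 / 3 * pi * r^3, tolerance = 0.05)
})

test_that("sphere/tube overlap integration matches the closed form", {
  ## axis through the sphere centre: V = 4pi/3 (R^3 - (R^2 - a^2)^(3/2))
  for (geom in list(c(0.7, 0.25), c(0.6, 0.1), c(1, 0.3))) {
    R <- geom[1]; a <- geom[2]
    got <- synmorph:::sphere_tube_overlap(R, a, c(0.01, 0.01, 0.4))
    expect_equal(got, 4 * pi / 3 * (R^3 - (R^2 - a^2)^1.5), tolerance = 0.02)
  }
})

test_that("boutons outside the field are rejected", {
  expect_error(bouton_stack_spec(extent = c(4, 3, 2.4), bouton_centers = 3.8,
                                 bouton_radii = 0.5), "outside the field")
})

test_that("generated vesicle scenes classify exactly as specified", {
  g <- gen_vesicle_scene(vesicle_scene_spec(300, n_docked = 2, n_vicinity = 5,
                                            n_outside = 3, seed = 4))
  counts <- classify_vesicles(g$scene)
  expect_identical(counts$n_docked, g$truth$n_docked)
  expect_identical(counts$n_vicinity, g$truth$n_vicinity)
  ## and per-vesicle labels agree with the classifier
  expect_identical(unname(counts$docked), g$labels == "docked")
  expect_identical(unname(counts$vicinity), g$labels != "outside")
})

test_that("empty scenes and identical seeds behave as contracts state", {
  g0 <- gen_vesicle_scene(vesicle_scene_spec(200))
  c0 <- classify_vesicles(g0$scene)
  expect_identical(c(c0$n_docked, c0$n_vicinity), c(0L, 0L))
  s <- vesicle_scene_spec(250, 3, 4, 2, seed = 9)
  expect_identical(gen_vesicle_scene(s)$scene$centers,
                   gen_vesicle_scene(s)$scene$centers)
})

test_that("geometrically impossible vesicle counts are rejected", {
  expect_error(vesicle_scene_spec(50, n_docked = 1, vesicle_radius = 20),
               "AZ too short")
  expect_error(vesicle_scene_spec(0, n_docked = 1), "must be > 0")
})

test_that("zero-rate point patterns are empty", {
  spec <- point_pattern_spec(n_cells = 3,
                             rates = c(ML = 0, PCL = 0, GCL = 0), seed = 2)
  g <- gen_point_pattern(spec)
  expect_true(all(vapply(g$canonical, nrow, integer(1)) == 0))
})

test_that("realized pattern counts follow the requested Poisson intensities", {
  ## homogeneous rate: mean total count over 200 seeds within 3 SE of
  ## lambda * A
  lam <- 0.003; W <- 200
  bands <- list(ML = c(0, 50), PCL = c(-50, 0), GCL = c(-100, -50))
  area <- W * 150
  totals <- vapply(1:200, function(s) {
    g <- gen_point_pattern(point_pattern_spec(
      n_cells = 1, rates = c(ML = lam, PCL = lam, GCL = lam),
      field_width = W, bands = bands, seed = s))
    nrow(g$canonical[[1]])
  }, numeric(1))
  mu <- lam * area
  se <- sqrt(mu / 200)
  expect_lt(abs(mean(totals) - mu), 3 * se)
})

test_that("a dominant Purkinje-layer rate dominates the binned heat map", {
  g <- gen_point_pattern(point_pattern_spec(
    n_cells = 4, rates = c(ML = 0.0005, PCL = 0.05, GCL = 0.0005),
    field_width = 200, seed = 5))
  aligned <- align_arbors(g$cells, target = c(0, -1))
  dm <- bin_density(lapply(aligned, `[[`, "boutons"))
  ## rows covering the PCL band (-20 <= y < 0) must hold most points
  pcl_rows <- which(dm$y_breaks >= -20 & dm$y_breaks < 0)
  expect_gt(sum(dm$counts[pcl_rows, ]), 0.6 * sum(dm$counts))
})
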
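## Shared small fixture: tube of diameter 0.5 um with one bouton.
tube_fixture <- function(centers = numeric(0), radii = numeric(0),
                         extent = c(5, 2, 2.4)) {
  gen_bouton_stack(bouton_stack_spec(extent = extent, axon_diameter = 0.5,
                                     bouton_centers = centers,
                                     bouton_radii = radii))
}

test_that("a plain tube has a flat diameter profile at its true diameter", {
  g <- tube_fixture()
  prof <- local_diameter_profile(g$stack, g$trace, threshold = 0.5)
  interior <- prof$arc > 0.5 & prof$arc < 4.5
  expect_true(all(abs(prof$diameter[interior] - 0.5) <= 0.02))
  expect_equal(prof$baseline, 0.5, tolerance = 0.05)
})

test_that("an empty stack yields zero diameters and a baseline error", {
  empty <- image_stack(array(0, dim = c(50, 30, 3)),
                       spacing = c(0.01, 0.01, 0.4), unit = "um")
  trace <- axon_trace(cbind(seq(0, 0.4, 0.05), 0.14, 0.4))
  expect_error(local_diameter_profile(empty, trace, threshold = 0.5),
               class = "synmorph_degenerate_baseline")
})

test_that("a spheroid bulge doubles the local diameter at its centre", {
  g <- tube_fixture(centers = 2.5, radii = 0.65)
  prof <- local_diameter_profile(g$stack, g$trace, threshold = 0.5)
  at_centre <- which.min(abs(prof$arc - 2.5))
  expect_equal(prof$diameter[at_centre], 1.3, tolerance = 0.05)
  expect_equal(prof$baseline, 0.5, tolerance = 0.05)
})

test_that("constant profiles yield no boutons", {
  g <- tube_fixture()
  prof <- local_diameter_profile(g$stack, g$trace, threshold = 0.5)
  expect_equal(nrow(detect_boutons(prof)), 0)
})

test_that("detected interval endpoints match a dense-grid crossing search", {
  ## analytic diameter profile: bulge peaking at 2.6x baseline
  base <- 0.5
  darc <- function(s) base + (2.6 - 1) * base * exp(-(s - 3)^2 / 0.18)
  arc <- seq(0, 6, by = 0.05)
  prof <- structure(list(arc = arc, diameter = darc(arc), baseline = base,
                         threshold = 0.5), class = "diameter_profile")
  iv <- detect_boutons(prof, factor = 2)
  expect_equal(nrow(iv), 1)
  ## oracle: brute-force crossing search on a 1e-5 grid
  fine <- seq(0, 6, by = 1e-5)
  above <- darc(fine) > 2 * base
  expect_equal(iv$start_arc, fine[which(above)[1]], tolerance = 1e-3)
  expect_equal(iv$end_arc, fine[rev(which(above))[1]], tolerance = 1e-3)
  expect_false(iv$terminal)
})

test_that("a dilation reaching the trace end is a terminal bouton", {
  base <- 0.5
  arc <- seq(0, 4, by = 0.05)
  d <- base + (2.6 - 1) * base * exp(-(arc - 4)^2 / 0.4)
  prof <- structure(list(arc = arc, diameter = d, baseline = base,
                         threshold = 0.5), class = "diameter_profile")
  iv <- detect_boutons(prof, factor = 2)
  expect_equal(nrow(iv), 1)
  expect_true(iv$terminal)
  expect_equal(iv$end_arc, 4)
})

test_that("volume is the voxel count times the voxel volume", {
  stk <- one_voxel_stack(3, 3, 2)
  trace <- axon_trace(cbind(c(0, 0.04), 0.02, 0.4))
  rec <- bouton_volume(stk, trace, list(start_arc = 0, end_arc = 0.04),
                       threshold = 0.5)
  expect_identical(rec$voxel_count, 1L)
  expect_equal(rec$volume, 0.00004, tolerance = 1e-12)

  none <- image_stack(array(0, dim = c(5, 5, 3)),
                      spacing = c(0.01, 0.01, 0.4), unit = "um")
  expect_warning(rec0 <- bouton_volume(none, trace,
                                       list(start_arc = 0, end_arc = 0.04),
                                       threshold = 0.5),
                 "volume 0")
  expect_equal(rec0$volume, 0)
})

test_that("a rasterized unit sphere recovers its analytic volume within 5%", {
  g <- gen_bouton_stack(bouton_stack_spec(extent = c(4, 3, 2.4),
                                          axon_diameter = 0,
                                          bouton_centers = 2, bouton_radii = 1))
  rec <- bouton_volume(g$stack, g$trace, list(start_arc = 1, end_arc = 3),
                       threshold = 0.5)
  expect_equal(rec$volume, 4 / 3 * pi, tolerance = 0.05)
})

test_that("voxel counts are additive over disjoint arc intervals", {
  g <- tube_fixture(centers = 2.5, radii = 0.7)
  v1 <- bouton_volume(g$stack, g$trace, list(start_arc = 0.5, end_arc = 2.5),
                      threshold = 0.5)
  v2 <- bouton_volume(g$stack, g$trace, list(start_arc = 2.5, end_arc = 4.5),
                      threshold = 0.5)
  vu <- bouton_volume(g$stack, g$trace, list(start_arc = 0.5, end_arc = 4.5),
                      threshold = 0.5)
  expect_identical(v1$voxel_count + v2$voxel_count, vu$voxel_count)
})

test_that("doubling the voxel spacing scales volumes by 8 exactly", {
  g <- tube_fixture(centers = 2.5, radii = 0.7)
  rec1 <- bouton_volume(g$stack, g$trace, list(start_arc = 1.5, end_arc = 3.5),
                        threshold = 0.5)
  big <- image_stack(g$stack$voxels, spacing = g$stack$spacing * 2, unit = "um")
  tr2 <- axon_trace(g$trace$points * 2)
  rec2 <- bouton_volume(big, tr2, list(start_arc = 3, end_arc = 7),
                        threshold = 0.5)
  expect_identical(rec1$voxel_count, rec2$voxel_count)
  expect_equal(rec2$volume, 8 * rec1$volume, tolerance = 1e-12)
})

test_that("generator stacks with clear bulges are fully recovered", {
  g <- tube_fixture(centers = c(1.5, 3.6), radii = c(0.6, 0.7),
                    extent = c(5, 2, 2.4))
  recs <- measure_boutons(g$stack, g$trace, threshold = 0.5)
  expect_equal(nrow(recs), 2)
  expect_true(all(abs(sort(recs$centroid_x) - c(1.5, 3.6)) < 0.1))
})

test_that("the otsu default separates synthetic fore- and background", {
  g <- gen_bouton_stack(bouton_stack_spec(extent = c(3, 1.5, 2.4),
                                          axon_diameter = 0.5,
                                          background_level = 0.1,
                                          foreground_level = 0.9,
                                          noise_sd = 0.05, seed = 5))
  prof <- local_diameter_profile(g$stack, g$trace)  # threshold = "otsu"
  expect_gt(prof$threshold, 0.2)
  expect_lt(prof$threshold, 0.8)
  expect_equal(prof$baseline, 0.5, tolerance = 0.05)
})

test_that("layer assignment follows the deeper-at-boundary convention", {
  pts <- data.frame(x = c(0, 0, 0, 0, 0),
                    y = c(25, 10, 0, -5, -40))
  out <- assign_layers(pts, ml_pcl = 20, pcl_gcl = -20)
  expect_equal(as.character(out$points$layer),
               c("ML", "PCL", "PCL", "PCL", "GCL"))
  ## exactly on a boundary -> deeper layer
  onb <- assign_layers(data.frame(x = 0, y = 20), ml_pcl = 20, pcl_gcl = -20)
  expect_equal(as.character(onb$points$layer), "PCL")
  onb2 <- assign_layers(data.frame(x = 0, y = -20), ml_pcl = 20, pcl_gcl = -20)
  expect_equal(as.character(onb2$points$layer), "GCL")
})

test_that("layer counts equal a brute-force point-in-band test", {
  set.seed(11)
  pts <- data.frame(x = runif(300, -50, 50), y = runif(300, -100, 100),
                    cell_id = sample(1:3, 300, replace = TRUE))
  out <- assign_layers(pts, ml_pcl = 30, pcl_gcl = -10)
  brute <- ifelse(pts$y > 30, "ML", ifelse(pts$y > -10, "PCL", "GCL"))
  expect_equal(as.character(out$points$layer), brute)
  tab <- table(brute)
  for (l in names(tab)) {
    expect_equal(sum(out$counts$n[out$counts$layer == l]), unname(tab[[l]]))
  }
})

test_that("points outside the declared extent are flagged unassigned", {
  pts <- data.frame(x = 0, y = c(10, 500))
  expect_warning(out <- assign_layers(pts, 20, -20, extent = c(-100, 100)),
                 "unassigned")
  expect_equal(as.character(out$points$layer), c("PCL", "unassigned"))
})
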
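test_that("flat patches give five identical measurement lines", {
  spec <- cleft_profile_spec(30, "gaussian", 6, noise_sd = 0)
  patch <- gen_em_patch(spec, curvature = 0)
  profs <- sample_cleft_lines(patch$image, patch$anchor)
  expect_length(profs, 5)
  for (p in profs[-1]) expect_equal(p$samples, profs[[1]]$samples, tolerance = 1e-10)
})

test_that("lines leaving the image raise a bounds error naming the line", {
  spec <- cleft_profile_spec(30, "gaussian", 6, noise_sd = 0)
  patch <- gen_em_patch(spec, curvature = 0, patch_height = 60)
  near_edge <- cleft_anchor(c(50, 15), c(1, 0))  # offset -20 leaves the patch
  expect_error(sample_cleft_lines(patch$image, near_edge),
               "measurement line", class = "synmorph_bounds_error")
})

test_that("curved patches still recover the generator ground truth", {
  spec <- cleft_profile_spec(26, "gaussian", 5, noise_sd = 0)
  patch <- gen_em_patch(spec, curvature = 0.003)
  m <- measure_synapse(patch$image, patch$anchor)
  expect_equal(m$width, patch$truth$width, tolerance = 2 * spec$step)
})

test_that("profile averaging is the pointwise mean", {
  p <- intensity_profile(c(0, 1, 2, 3), step = 1)
  q <- intensity_profile(c(0, -1, -2, -3), step = 1)
  expect_equal(average_profiles(list(p, p, p))$samples, p$samples)
  expect_equal(average_profiles(list(p, q))$samples, rep(0, 4))
  r <- intensity_profile(c(0, 1, 2), step = 1)
  expect_error(average_profiles(list(p, r)), "different lengths")
  s <- intensity_profile(c(0, 1, 2, 3), step = 2)
  expect_error(average_profiles(list(p, s)), "different steps")
})

test_that("averaging n noisy profiles shrinks the variance like 1/n", {
  ## variance of a fixed sample position across 500 seeds
  sd0 <- 0.2
  mid_single <- mid_avg <- numeric(500)
  for (s in 1:500) {
    reps <- lapply(1:5, function(j) {
      gen_cleft_profile(cleft_profile_spec(24, "gaussian", 5, noise_sd = sd0,
                                           seed = s * 10 + j))$profile
    })
    mid_single[s] <- reps[[1]]$samples[15]   # far from the clip at 0
    mid_avg[s] <- average_profiles(reps)$samples[15]
  }
  ratio <- stats::var(mid_avg) / stats::var(mid_single)
  expect_gt(ratio, 1 / 5 * 0.7)
  expect_lt(ratio, 1 / 5 * 1.4)
})

test_that("the triangular profile yields the closed-form widths", {
  g <- gen_cleft_profile(cleft_profile_spec(40, "triangular", 10, noise_sd = 0))
  std <- measure_cleft_width(g$profile)
  man <- measure_cleft_manual(g$profile)
  expect_equal(std$width, 38, tolerance = 1e-9)
  expect_equal(man$width, 40, tolerance = 1e-9)
  expect_equal(std$pre_boundary, 31, tolerance = 1e-9)
  expect_equal(std$post_boundary, 69, tolerance = 1e-9)
  expect_s3_class(std, "cleft_measurement")
})

test_that("degenerate and ambiguous profiles raise classed errors", {
  flat <- intensity_profile(rep(1, 50), step = 1)
  expect_error(measure_cleft_width(flat), class = "synmorph_degenerate_profile")
  one_bump <- intensity_profile(exp(-(0:100 - 50)^2 / 50), step = 1)
  expect_error(measure_cleft_width(one_bump),
               class = "synmorph_ambiguous_synapse")
  expect_error(measure_cleft_manual(one_bump),
               class = "synmorph_ambiguous_synapse")
})

test_that("gaussian-membrane widths match the fine-grid oracle", {
  for (sep in c(20, 25, 30)) {
    g <- gen_cleft_profile(cleft_profile_spec(sep, "gaussian", 5, noise_sd = 0,
                                              step = 1))
    m <- measure_cleft_width(g$profile)
    oracle <- drop_rule_oracle(sep, "gaussian", 5)
    expect_equal(m$width, oracle$width, tolerance = 1)  # one sampling step
  }
})

test_that("width is invariant under profile mirroring", {
  for (sep in c(22, 31)) {
    g <- gen_cleft_profile(cleft_profile_spec(sep, "gaussian", 5,
                                              noise_sd = 0.05, seed = sep))
    m1 <- measure_cleft_width(g$profile)
    mirrored <- intensity_profile(rev(g$profile$samples), step = g$profile$step)
    m2 <- measure_cleft_width(mirrored)
    expect_equal(m1$width, m2$width, tolerance = 1e-9)
  }
})

test_that("increasing the drop fraction never increases the width", {
  g <- gen_cleft_profile(cleft_profile_spec(28, "gaussian", 6, noise_sd = 0))
  widths <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.5),
                   function(d) measure_cleft_width(g$profile, drop_fraction = d)$width,
                   numeric(1))
  expect_true(all(diff(widths) <= 1e-12))
})

test_that("noise-free recovery is within one sampling step across shapes", {
  set.seed(100)
  for (i in 1:50) {
    shape <- if (i %% 2) "triangular" else "gaussian"
    sep <- runif(1, 18, 36)
    g <- gen_cleft_profile(cleft_profile_spec(sep, shape,
                                              membrane_width_param = if (shape == "triangular") 10 else 5,
                                              noise_sd = 0, seed = i))
    m <- measure_cleft_width(g$profile)
    expect_lt(abs(m$width - g$truth$width), g$profile$step)
  }
})

test_that("manual peak-to-peak width never falls below the standardized width", {
  set.seed(200)
  for (i in 1:40) {
    g <- gen_cleft_profile(cleft_profile_spec(runif(1, 20, 34), "gaussian", 5,
                                              noise_sd = 0.08, seed = 300 + i))
    expect_gte(measure_cleft_manual(g$profile)$width,
               measure_cleft_width(g$profile)$width)
  }
})

test_that("the absolute drop interpretation is available and distinct", {
  g <- gen_cleft_profile(cleft_profile_spec(30, "gaussian", 5,
                                            valley_density = 0.4, noise_sd = 0))
  m_range <- measure_cleft_width(g$profile, drop_mode = "range")
  m_abs <- measure_cleft_width(g$profile, drop_mode = "absolute")
  ## with an elevated valley, 10% of the absolute peak is a bigger drop
  ## than 10% of the peak-to-valley range: boundaries move inwards
  expect_lt(m_abs$width, m_range$width)
})

test_that("inverted (bright-membrane) profiles measure identically via invert", {
  g <- gen_cleft_profile(cleft_profile_spec(27, "gaussian", 5, noise_sd = 0))
  bright <- intensity_profile(max(g$profile$samples) - g$profile$samples,
                              step = g$profile$step)
  expect_equal(measure_cleft_width(bright, invert = TRUE)$width,
               measure_cleft_width(g$profile)$width, tolerance = 1e-9)
})
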
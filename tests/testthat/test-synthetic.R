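test_that("generation is bit-identical for the same spec and seed", {
  spec <- synthetic_spec(radius_px = 70, field_px = c(180, 180),
                         model = model_punctate(4, 8), boundary_roughness = 0.1,
                         seed = 99)
  g1 <- generate_section(spec)
  g2 <- generate_section(spec)
  expect_identical(g1$section$channels, g2$section$channels)
  expect_identical(g1$truth$shell_percent, g2$truth$shell_percent)
})

test_that("spec validation rejects impossible parameterizations", {
  expect_error(synthetic_spec(radius_px = 300, field_px = c(256, 256)),
               "does not fit")
  expect_error(synthetic_spec(model = model_exponential(400), radius_px = 300),
               "exceeds the organoid radius")
  expect_error(synthetic_spec(boundary_roughness = 0.7), "0.5")
  expect_error(synthetic_spec(signal_amplitude = 0), "positive")
})

test_that("uniform-disk ground truth reproduces the annulus areas", {
  gen <- generate_section(synthetic_spec(radius_px = 100, field_px = c(230, 230),
                                         model = model_uniform(), seed = 1))
  expect_equal(unname(gen$truth$region_percent), c(36, 28, 20, 12, 4),
               tolerance = 1.5 / 4)
  expect_equal(sum(gen$truth$region_percent), 100, tolerance = 1e-6)
  expect_equal(sum(gen$truth$shell_percent), 100, tolerance = 1e-6)
})

test_that("a thin crust places all expected signal in R1", {
  gen <- generate_section(synthetic_spec(radius_px = 100, field_px = c(230, 230),
                                         model = model_crust(10), seed = 2))
  expect_equal(unname(gen$truth$region_percent[1]), 100)
})

test_that("closed-form expected shells match the analytic annulus integral", {
  spec <- synthetic_spec(radius_px = 300, model = model_uniform(),
                         field_px = c(640, 640))
  pct <- expected_profile(spec, 25)
  expect_equal(pct[1], 100 * (300^2 - 275^2) / 300^2, tolerance = 1e-9)
  expect_equal(sum(pct), 100, tolerance = 1e-9)
  # exponential short-decay limit: everything in the first shell
  spec2 <- synthetic_spec(radius_px = 300, model = model_exponential(1),
                          field_px = c(640, 640))
  expect_gt(expected_profile(spec2, 25)[1], 99.9)
})

test_that("closed-form and supersampled numeric profiles agree", {
  spec <- synthetic_spec(radius_px = 120, model = model_exponential(40),
                         field_px = c(280, 280), seed = 3)
  closed <- expected_profile(spec, 25)
  numeric <- radialorg:::supersampled_truth(spec, 25, 6)$shell_percent
  expect_equal(numeric, closed, tolerance = 0.2 / max(closed))
  closed_r <- expected_regions(spec)
  numeric_r <- radialorg:::supersampled_truth(spec, 25, 6)$region_percent
  expect_equal(unname(numeric_r), unname(closed_r), tolerance = 0.2 / max(closed_r))
})

test_that("longer decay lengths move expected signal deeper", {
  lambdas <- seq(10, 100, by = 15)
  mean_depth <- vapply(lambdas, function(l) {
    spec <- synthetic_spec(radius_px = 300, model = model_exponential(l),
                           field_px = c(640, 640))
    pct <- expected_profile(spec, 25)
    mids <- (seq_along(pct) - 0.5) * 25
    sum(pct * pmin(mids, 300)) / 100
  }, 0)
  expect_true(all(diff(mean_depth) > 0))
})

test_that("the closed loop generator -> pipeline stays within 2 points per region", {
  models <- list(model_uniform(), model_crust(30), model_exponential(30),
                 model_channels(3, 8, 80), model_punctate())
  for (i in seq_along(models)) {
    gen <- generate_section(synthetic_spec(radius_px = 100, field_px = c(230, 230),
                                           model = models[[i]], seed = 30 + i))
    q <- quantify_section(gen$section, min_area_px = 1000)
    expect_true(max(abs(q$regions$percents - gen$truth$region_percent)) < 2,
                label = sprintf("model %s region deviation < 2", models[[i]]$type))
  }
})

test_that("TUNEL fixtures honour their truth parameters", {
  fx <- generate_tunel_fixture(20, positive_fraction = 0.25, seed = 8)
  expect_identical(fx$truth$n_positive, 5L)
  expect_identical(nrow(fx$truth$centers), 20L)
  # all pairwise center distances respect the non-overlap guarantee
  d <- as.matrix(dist(fx$truth$centers))
  diag(d) <- Inf
  expect_true(min(d) >= 2 * 6 + 8)
  # zero positive fraction leaves no high-amplitude TUNEL signal
  fx0 <- generate_tunel_fixture(20, positive_fraction = 0, seed = 9)
  expect_lt(max(fx0$section$channels$tunel), 3 * 50)
  expect_error(generate_tunel_fixture(500, field_px = c(96, 96), seed = 1),
               "capacity")
})

test_that("simulated region datasets are balanced compositional tables", {
  d <- simulate_region_dataset(6, seed = 11)
  expect_identical(nrow(d), 60L)
  sums <- tapply(d$percent, d$organoid_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_silent(res <- region_time_anova(d))
  # a strong shift is detected
  d2 <- simulate_region_dataset(6, mean_percents = c(96, 2, 1, 0.7, 0.3),
                                mean_percents_2 = c(45, 25, 15, 10, 5),
                                seed = 12)
  res2 <- region_time_anova(d2)
  expect_lt(res2$comparisons$p_adj[1], 0.0001)
})
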
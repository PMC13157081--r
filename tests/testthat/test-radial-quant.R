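test_that("depth maps match trivial hand-derived cases", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  dm <- compute_depth_map(m)
  expect_equal(dm$depth[3, 3], 1)
  expect_equal(dm$radius_px, 1)
  m2 <- matrix(FALSE, 7, 7); m2[3:5, 3:5] <- TRUE
  dm2 <- compute_depth_map(m2)
  expect_equal(dm2$depth[4, 4], 2)
  expect_true(all(dm2$depth[3:5, 3:5][-5] == 1))
  expect_true(all(dm2$depth[!m2] == 0))
})

test_that("depth maps equal the exhaustive nearest-background search", {
  for (seed in 1:5) {
    m <- random_blob(40, seed)
    dm <- compute_depth_map(m)
    expect_equal(dm$depth, brute_force_edt(m), tolerance = 1e-12)
    expect_equal(dm$radius_px, max(dm$depth))
  }
})

test_that("shell intervals follow the ceiling(radius/width) layout", {
  dm <- structure(list(depth = matrix(0, 1, 1), radius_px = 100),
                  class = "depth_map")
  s <- build_shells(dm, 25)
  expect_identical(s$n_shells, 4L)
  expect_equal(s$depth_lo_px, c(0, 25, 50, 75))
  expect_equal(s$depth_hi_px, c(25, 50, 75, 100))
  dm$radius_px <- 60
  s2 <- build_shells(dm, 25)
  expect_identical(s2$n_shells, 3L)
  expect_equal(s2$depth_hi_px, c(25, 50, 60))
  expect_error(build_shells(dm, 0), "positive")
})

test_that("shell labels partition the mask and agree with direct binning", {
  m <- random_blob(48, 9)
  dm <- compute_depth_map(m)
  s <- build_shells(dm, 3)
  expect_true(all((s$shell_labels > 0) == m))
  d <- dm$depth[m]
  direct <- pmin(floor(d / 3) + 1, s$n_shells)
  expect_identical(as.integer(s$shell_labels[m]), as.integer(direct))
})

test_that("uniform disks give the analytic annulus percentages", {
  n <- 640
  mask <- disk_mask(n, 300)
  dm <- compute_depth_map(mask)
  shells <- build_shells(dm, 25)
  prof <- measure_profile(matrix(1, n, n), shells)
  expect_equal(prof$percent[1], 100 * (300^2 - 275^2) / 300^2, tolerance = 0.5 / 16)
  rs <- summarize_regions(matrix(1, n, n), dm)
  expect_equal(unname(rs$percents), c(36, 28, 20, 12, 4), tolerance = 1.5 / 4)
  expect_equal(sum(rs$percents), 100, tolerance = 1e-6)
})

test_that("signal concentrated at a known depth lands in the right shell and region", {
  mask <- disk_mask(256, 100)
  dm <- compute_depth_map(mask)
  shells <- build_shells(dm, 25)
  sig <- matrix(0, 256, 256)
  sig[dm$depth >= 30 & dm$depth < 31] <- 5
  prof <- measure_profile(sig, shells)
  expect_equal(prof$percent[2], 100)
  expect_equal(sum(prof$percent), 100, tolerance = 1e-6)
  shallow <- matrix(0, 256, 256)
  shallow[dm$depth > 0 & dm$depth < 0.1 * dm$radius_px] <- 2
  rs <- summarize_regions(shallow, dm)
  expect_equal(unname(rs$percents[1]), 100)
})

test_that("profiles and summaries match an independent per-pixel accumulation", {
  gen <- generate_section(synthetic_spec(radius_px = 90, field_px = c(240, 240),
                                         model = model_exponential(30), seed = 21))
  sig <- gen$section$channels$signal
  mask <- gen$truth$mask
  dm <- compute_depth_map(mask)
  shells <- build_shells(dm, 25)
  prof <- measure_profile(sig, shells)
  # oracle: direct accumulation over depth bins
  d <- dm$depth[mask]; v <- sig[mask]
  K <- shells$n_shells
  idx <- pmin(floor(d / 25) + 1, K)
  o_shell <- vapply(seq_len(K), function(i) sum(v[idx == i]), 0)
  expect_equal(prof$intden, o_shell, tolerance = 1e-9)
  expect_equal(prof$percent, 100 * o_shell / sum(v), tolerance = 1e-9)
  rs <- summarize_regions(sig, dm)
  rdx <- findInterval(d / dm$radius_px, c(.2, .4, .6, .8)) + 1
  o_reg <- vapply(1:5, function(i) sum(v[rdx == i]), 0)
  expect_equal(unname(rs$percents), 100 * o_reg / sum(v), tolerance = 1e-9)
})

test_that("a 90-degree rotation moves region percents by less than 0.1 points", {
  gen <- generate_section(synthetic_spec(radius_px = 90, field_px = c(240, 240),
                                         model = model_exponential(30), seed = 5))
  q1 <- quantify_section(gen$section, min_area_px = 1000)
  rot <- section_image(lapply(gen$section$channels, rot90), meta = gen$section$meta)
  q2 <- quantify_section(rot, min_area_px = 1000)
  expect_true(max(abs(q1$regions$percents - q2$regions$percents)) < 0.1)
})

test_that("organoids without signal are excluded with a 'no signal' error", {
  mask <- disk_mask(128, 50)
  dm <- compute_depth_map(mask)
  shells <- build_shells(dm, 25)
  expect_error(measure_profile(matrix(0, 128, 128), shells), "no signal")
  expect_error(summarize_regions(matrix(0, 128, 128), dm), "no signal")
})

test_that("rescaling to the largest organoid only changes plotting positions", {
  mk <- function(r, n) {
    mask <- disk_mask(n, r)
    dm <- compute_depth_map(mask)
    measure_profile(matrix(1, n, n), build_shells(dm, 25))
  }
  p_small <- mk(100, 256)
  p_big <- mk(200, 450)
  resc <- rescale_to_largest(list(p_small, p_big))
  ref <- p_big$own_radius_px
  expect_equal(resc[[1]]$reference_radius_px, ref)
  # a mid-shell of the small organoid lands at mid_depth / largest radius
  i <- which(p_small$mid_depth_px == 37.5)
  expect_equal(resc[[1]]$relative_position[i], 37.5 / ref)
  expect_true(all(resc[[2]]$relative_position <= 1))
  # percentages untouched
  expect_identical(resc[[1]]$percent, p_small$percent)
  # single profile: reference is its own radius
  single <- rescale_to_largest(list(p_small))
  expect_equal(single[[1]]$reference_radius_px, p_small$own_radius_px)
  expect_error(rescale_to_largest(list()), "non-empty")
})

test_that("the exponential penetration fit recovers the decay length", {
  gen <- generate_section(synthetic_spec(radius_px = 120, field_px = c(300, 300),
                                         model = model_exponential(30), seed = 13))
  q <- quantify_section(gen$section, min_area_px = 1000)
  f <- fit_penetration(q$profile, q$depth)
  expect_lt(abs(coef(f)[["lambda_px"]] - 30) / 30, 0.1)
  f2 <- fit_penetration(q$profile)
  expect_lt(abs(coef(f2)[["lambda_px"]] - 30) / 30, 0.2)
  expect_equal(sum(fitted(f)), 100, tolerance = 1e-6)
})
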
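test_that("the D'Agostino-Pearson omnibus matches an independent reference", {
  # reference values computed with scipy.stats.normaltest / shapiro
  x <- c(2.1, 3.4, 1.9, 5.6, 4.4, 2.2, 7.8, 3.3, 2.9, 4.1,
         3.7, 6.2, 1.4, 3.9, 4.8, 2.6, 3.1, 5.1, 2.8, 3.5)
  nt <- normality_tests(x)
  expect_equal(nt$dagostino_stat, 4.41495316054848, tolerance = 1e-10)
  expect_equal(nt$dagostino_p, 0.10997781885738123, tolerance = 1e-10)
  expect_equal(nt$shapiro_stat, 0.9503518603450843, tolerance = 1e-7)
  expect_equal(nt$shapiro_p, 0.3724623087983064, tolerance = 1e-6)
})

test_that("sample-size contracts for the normality pre-tests hold", {
  nt <- normality_tests(c(1.2, 3.1, 2.2, 4.4, 0.9))
  expect_true(is.na(nt$dagostino_stat))
  expect_false(is.na(nt$shapiro_p))
  expect_error(normality_tests(c(1, 2)), "at least 3")
})

test_that("normality tests are calibrated under the null and powered under skew", {
  null_ok <- 0; skew_hit <- 0
  for (seed in 1:100) {
    set.seed(seed)
    g <- rnorm(500)
    nt <- normality_tests(g)
    if (nt$dagostino_p > 0.05 && nt$shapiro_p > 0.05) null_ok <- null_ok + 1
    set.seed(seed + 1000)
    e <- rexp(500)
    if (normality_tests(e)$shapiro_p < 0.01) skew_hit <- skew_hit + 1
  }
  expect_gte(null_ok, 90)
  expect_gte(skew_hit, 95)
})

test_that("Sidak adjustment matches its closed form and is monotone", {
  expect_equal(sidak_adjust(0.01, 5), 1 - 0.99^5, tolerance = 1e-12)
  expect_equal(sidak_adjust(0.3, 1), 0.3)
  p <- seq(0.001, 0.5, length.out = 50)
  adj <- sidak_adjust(p, 5)
  expect_true(all(diff(adj) > 0))
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1 & adj >= 0))
})

test_that("significance stars follow the 0.05/0.01/0.005/0.0001 ladder", {
  expect_identical(p_stars(c(0.2, 0.04, 0.009, 0.004, 5e-5)),
                   c("", "*", "**", "***", "****"))
})

test_that("the two-way ANOVA equals a textbook sum-of-squares decomposition", {
  d <- toy_region_dataset()
  res <- region_time_anova(d)
  o <- oracle_twoway(d$region, d$timepoint_weeks, d$percent)
  an <- res$anova
  expect_equal(an$sumsq[an$term == "region"], o$ssA, tolerance = 1e-10)
  expect_equal(an$sumsq[an$term == "timepoint"], o$ssB, tolerance = 1e-10)
  expect_equal(an$sumsq[an$term == "region:timepoint"], o$ssAB, tolerance = 1e-10)
  expect_equal(an$sumsq[an$term == "residuals"], o$ssE, tolerance = 1e-10)
  expect_equal(sum(an$sumsq), o$ssT, tolerance = 1e-8)
  expect_equal(an$F[an$term == "region"], o$FA, tolerance = 1e-10)
  expect_equal(an$p[an$term == "timepoint"], o$pB, tolerance = 1e-10)
  expect_equal(an$F[an$term == "region:timepoint"], o$FAB, tolerance = 1e-10)
  # per-region comparison from the pooled residual mean square
  n <- 2
  for (rg in paste0("R", 1:5)) {
    v1 <- d$percent[d$region == rg & d$timepoint_weeks == 1]
    v2 <- d$percent[d$region == rg & d$timepoint_weeks == 4]
    tval <- (mean(v2) - mean(v1)) / sqrt(o$msE * 2 / n)
    p_raw <- 2 * pt(-abs(tval), o$dfE)
    row <- res$comparisons[res$comparisons$region == rg, ]
    expect_equal(row$t, tval, tolerance = 1e-10)
    expect_equal(row$p_adj, 1 - (1 - p_raw)^5, tolerance = 1e-10)
    expect_identical(row$stars, p_stars(row$p_adj))
  }
})

test_that("the logit option transforms the response but keeps the design checks", {
  d <- toy_region_dataset()
  res <- region_time_anova(d, logit = TRUE)
  expect_true(all(is.finite(res$comparisons$p_adj)))
  # means are reported on the logit scale
  expect_equal(res$comparisons$mean_t1[1], mean(qlogis(c(40, 38) / 100)),
               tolerance = 1e-10)
})

test_that("design violations are reported as errors", {
  d <- toy_region_dataset()
  expect_error(region_time_anova(d[-1, ]), "design error")
  d2 <- d; d2$percent[1] <- d2$percent[1] + 5
  expect_error(region_time_anova(d2), "sum to 100")
  # zero residual variance: both organoids in each cell identical
  d3 <- d
  d3$percent[d3$organoid_id == "w1_org2"] <- d3$percent[d3$organoid_id == "w1_org1"]
  d3$percent[d3$organoid_id == "w4_org2"] <- d3$percent[d3$organoid_id == "w4_org1"]
  expect_error(region_time_anova(d3), "degenerate")
})

test_that("one-way comparisons against control behave at both extremes", {
  set.seed(42)
  ctrl <- 10 + rnorm(6, sd = 0.5)
  # identical group values: zero mean difference, p exactly 1
  r0 <- one_way_vs_control(list(control = ctrl, treated = ctrl), "control")
  expect_equal(r0$comparisons$p_adj, 1)
  # exact mean 0 / sd 1 draws: pooled t = 5 / sqrt(2/6) = 8.66, df = 10
  z <- as.numeric(scale(rnorm(6)))
  r1 <- one_way_vs_control(list(control = z, treated = 5 + z), "control")
  expect_lt(r1$comparisons$p_adj, 0.0001)
  expect_identical(r1$comparisons$stars, "****")
  expect_error(one_way_vs_control(list(a = 1:3), "a"), "at least two")
  expect_error(one_way_vs_control(list(a = 1:3, b = 1:3), "zzz"), "not found")
})
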
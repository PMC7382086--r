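test_that("piecewise-Weibull CDF and quantile are consistent and continuous", {
  sh <- c(1, 2, 0.7)
  sc <- c(5, 8, 3)
  br <- c(2, 6)
  p <- seq(0.01, 0.99, by = 0.02)
  q <- qpwweib(p, sh, sc, br)
  expect_true(all(diff(q) > 0))
  expect_equal(ppwweib(q, sh, sc, br), p, tolerance = 1e-12)
  # continuity at the breakpoints
  eps <- 1e-9
  expect_equal(ppwweib(br - eps, sh, sc, br), ppwweib(br + eps, sh, sc, br),
               tolerance = 1e-6)
  # single segment with shape 1 is the exponential distribution
  expect_equal(ppwweib(c(1, 3, 7), 1, 4), pexp(c(1, 3, 7), 1 / 4),
               tolerance = 1e-12)
  expect_equal(qpwweib(0.5, 1, 4), qexp(0.5, 1 / 4), tolerance = 1e-12)
  expect_error(ppwweib(1, c(1, 2), 5), "lengths differ")
  expect_error(qpwweib(0.5, c(1, 1), c(2, 2), breaks = -1), "increasing")
})

test_that("sampled draws follow the configured mixture", {
  set.seed(71)
  cfg <- scenario_config("A", 100, 100)
  g <- sample_group(cfg, 1, n = 1e5)
  # cause allocation is Bernoulli(p1) with p1 = 0.7
  expect_equal(mean(g$status == 1), 0.7, tolerance = 0.005)
  # conditional cause-1 times follow the closed-form CDF
  pw <- cfg$g1$cause1
  t1 <- g$time[g$status == 1]
  ks <- suppressWarnings(ks.test(t1, function(q)
    ppwweib(q, pw$shape, pw$scale, pw$breaks)))
  expect_gt(ks$p.value, 0.01)
  # p1 = 1 yields only events of interest
  cfg1 <- cfg
  cfg1$g1$p1 <- 1
  expect_true(all(sample_group(cfg1, 1, n = 500)$status == 1L))
})

test_that("censoring calibration hits its target and is monotone", {
  cfg <- scenario_config("A", 100, 100)
  expect_null(calibrate_censoring(cfg, 0))
  set.seed(73)
  b45 <- calibrate_censoring(cfg, 0.45)
  b15 <- calibrate_censoring(cfg, 0.15)
  expect_lt(b45, b15)   # heavier censoring needs a tighter bound
  cfg$censor_upper <- b45
  g <- sample_group(cfg, 1, n = 2e4)
  expect_equal(mean(g$status == 0), 0.45, tolerance = 0.01)
  expect_error(calibrate_censoring(cfg, 0.95), "\\[0, 0.9\\]")
})

test_that("a fixed seed reproduces samples and rejection tables exactly", {
  cfg <- scenario_config("B", 40, 40)
  set.seed(99)
  s1 <- simulate_cr_study(cfg)
  set.seed(99)
  s2 <- simulate_cr_study(cfg)
  expect_identical(s1, s2)
  r1 <- rejection_study(cfg, reps = 50, seed = 7)
  r2 <- rejection_study(cfg, reps = 50, seed = 7)
  expect_identical(r1$results, r2$results)
})

test_that("rejection machinery behaves at the edges and with sample size", {
  cfg <- scenario_config("A", 50, 50)
  r <- rejection_study(cfg, reps = 60, alpha = 1, seed = 5)
  expect_true(all(r$results$rate == 1))
  expect_equal(r$results$se, c(0, 0))
  expect_error(rejection_study(cfg, methods = "gray"), "arg")
  # power grows with n under an ordered alternative
  pw <- vapply(c(50, 100, 150), function(n) {
    rejection_study(scenario_config("B", n, n), methods = "diff",
                    reps = 400, seed = 1000 + n)$results$rate
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
  # under the null, observed "power" stays near alpha
  p0 <- observed_power_at_n(scenario_config("A", 50, 50), "diff",
                            n_total = 200, reps = 400, alpha = 0.05,
                            seed = 83)
  expect_lt(abs(p0 - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.02)
})
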
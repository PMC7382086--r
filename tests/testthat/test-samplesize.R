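test_that("closed-form total sample size matches direct arithmetic", {
  ss <- samplesize_diff(delta = 1, var1 = 4, var2 = 4)
  n_raw <- 2 * (qnorm(0.8) + qnorm(0.975))^2 * 8
  expect_equal(ss$n_raw, n_raw, tolerance = 1e-12)   # ~125.58
  expect_equal(ss$n_total, 126)
  expect_equal(ss$n1, 63)
  # doubling the effect quarters the raw size
  expect_equal(samplesize_diff(2, 4, 4)$n_raw, n_raw / 4, tolerance = 1e-12)
  # unequal allocation: per-group ceilings of the allocated raw sizes
  ss2 <- samplesize_diff(1, 4, 4, r = 2)
  expect_equal(ss2$n1, ceiling(ss2$n_raw / 3))
  expect_equal(ss2$n2, ceiling(2 * ss2$n_raw / 3))
  expect_error(samplesize_diff(0, 4, 4), "nonzero")
  expect_error(samplesize_diff(1, -1, 4), "positive")
})

test_that("required n moves the right way with every design parameter", {
  base <- samplesize_diff(1, 4, 4)$n_raw
  expect_gt(samplesize_diff(1, 6, 4)$n_raw, base)
  expect_gt(samplesize_diff(1, 4, 6)$n_raw, base)
  expect_gt(samplesize_diff(1, 4, 4, power = 0.9)$n_raw, base)
  expect_gt(samplesize_diff(1, 4, 4, alpha = 0.01)$n_raw, base)
  expect_lt(samplesize_diff(1.5, 4, 4)$n_raw, base)
  powers <- c(0.5, 0.8, 0.9, 0.99)
  ns <- vapply(powers, function(p) samplesize_diff(1, 4, 4, power = p)$n_raw,
               numeric(1))
  expect_true(all(diff(ns) > 0))
})

test_that("drift equation solution satisfies its defining properties", {
  sol <- solve_eta(0.05, 0.8)
  expect_equal(sol$eta_tilde, qnorm(0.975) + qnorm(0.8), tolerance = 1e-12)
  V <- sol$V
  Y <- function(x) pnorm(V - x, lower.tail = FALSE) +
    exp(2 * V * x) * pnorm(V + x, lower.tail = FALSE)
  expect_equal(Y(sol$eta), 0.8, tolerance = 1e-8)
  # analytic derivative agrees with a numerical one
  Yp <- function(x) dnorm(V - x) +
    2 * V * exp(2 * V * x) * pnorm(V + x, lower.tail = FALSE) -
    exp(2 * V * x) * dnorm(V + x)
  h <- 1e-6
  for (x in c(2.0, 2.8, 3.5))
    expect_equal(Yp(x), (Y(x + h) - Y(x - h)) / (2 * h), tolerance = 1e-6)
  # the supremum test always needs more drift than the fixed-time test
  for (al in c(0.01, 0.05, 0.2)) {
    for (pw in c(0.5, 0.8, 0.95)) {
      s <- solve_eta(al, pw)
      expect_gt(s$eta, s$eta_tilde)
    }
  }
})

test_that("inflation factor depends only on alpha and power, and n scales", {
  s1 <- samplesize_sdiff(1, 4, 4)
  s2 <- samplesize_sdiff(-2.5, 11, 3)
  s3 <- samplesize_sdiff(0.1, 0.02, 0.05)
  expect_equal(s1$xi, s2$xi, tolerance = 1e-10)
  expect_equal(s1$xi, s3$xi, tolerance = 1e-10)
  expect_gte(s1$xi, 1)
  expect_lte(s1$xi, 1.15)
  expect_equal(s1$n_raw, s1$xi * samplesize_diff(1, 4, 4)$n_raw,
               tolerance = 1e-12)
  expect_gte(s1$n_total, samplesize_diff(1, 4, 4)$n_total)
  for (al in c(0.01, 0.05)) {
    for (pw in c(0.8, 0.9)) {
      expect_gte(samplesize_sdiff(1, 4, 4, alpha = al, power = pw)$xi, 1)
    }
  }
})

test_that("pilot estimation feeds the formulas and is scale invariant", {
  set.seed(61)
  cfg <- scenario_config("B", 150, 150)
  s <- simulate_cr_study(cfg)
  pd <- pilot_design(s)
  expect_gt(pd$delta, 0)
  ss <- samplesize_diff(pd$delta, pd$var1, pd$var2)
  # rescaling time units leaves the calculated size unchanged
  s2 <- cr_sample(s$time * 12, s$status, group = s$group)
  pd2 <- pilot_design(s2, tau = pd$tau * 12)
  expect_equal(pd2$delta, 12 * pd$delta, tolerance = 1e-10)
  expect_equal(pd2$var1, 144 * pd$var1, tolerance = 1e-8)
  ss2 <- samplesize_diff(pd2$delta, pd2$var1, pd2$var2)
  expect_equal(ss2$n_raw, ss$n_raw, tolerance = 1e-10)
  # identical pilot groups carry no effect size
  a <- toy_sample()
  expect_error(pilot_design(bind_groups(a, a), tau = 3), "identical")
})
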
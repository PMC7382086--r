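test_that("identical groups give zero statistics and p-values of one", {
  a <- toy_sample()
  s <- bind_groups(a, a)
  d <- rmtl_diff_test(s, tau = 3)
  expect_equal(d$delta, 0)
  expect_equal(d$statistic, 0)
  expect_equal(d$p.value, 1)
  sd <- rmtl_sdiff_test(s, tau = 3)
  expect_equal(sd$statistic, 0)
  expect_equal(sd$p.value, 1)
  expect_true(all(sdiff_cumdiff(s, tau = 3)$delta == 0))
})

test_that("swapping groups negates Z and leaves both p-values unchanged", {
  set.seed(31)
  a <- random_sample(60)
  b <- random_sample(50)
  s1 <- bind_groups(a, b, labels = c("a", "b"))
  s2 <- bind_groups(b, a, labels = c("a", "b"))  # same labels, swapped data
  tau <- default_tau(s1)$value
  d1 <- rmtl_diff_test(s1, tau)
  d2 <- rmtl_diff_test(s2, tau)
  expect_equal(d2$statistic, -d1$statistic, tolerance = 1e-12)
  expect_equal(d2$p.value, d1$p.value, tolerance = 1e-12)
  q1 <- rmtl_sdiff_test(s1, tau)
  q2 <- rmtl_sdiff_test(s2, tau)
  expect_equal(q2$statistic, q1$statistic, tolerance = 1e-12)
  expect_equal(q2$p.value, q1$p.value, tolerance = 1e-12)
})

test_that("cumulative difference matches a naive grid evaluation and the
           fixed-tau effect", {
  set.seed(37)
  for (rep in 1:4) {
    a <- random_sample(40, cens = 0.2)
    b <- random_sample(35, cens = 0.2)
    s <- bind_groups(a, b)
    tau <- default_tau(s)$value
    cd <- sdiff_cumdiff(s, tau)
    oracle <- naive_cumdiff(a, b, tau)
    expect_equal(cd$delta, oracle$delta, tolerance = 1e-12)
    d <- rmtl_diff_test(s, tau)
    expect_equal(cd$delta[nrow(cd)], d$delta, tolerance = 1e-12)
    # the supremum dominates the endpoint on every sample
    expect_gte(max(abs(cd$delta)) + 1e-12, abs(d$delta))
  }
})

test_that("sigma matches the naive double sum and its special cases", {
  set.seed(41)
  a <- random_sample(30)
  b <- random_sample(30)
  s <- bind_groups(a, b)
  tau <- default_tau(s)$value
  for (rho in c(0, 0.5, 1)) {
    expect_equal(sdiff_sigma(s, tau, rho = rho),
                 naive_sigma(a, b, tau, rho), tolerance = 1e-12)
  }
  # rho = 0 keeps only the diagonal
  m <- rmtlcr:::.sdiff_machinery(a, b, tau)
  expect_equal(sdiff_sigma(s, tau, rho = 0),
               sqrt(sum(m$width^2 * m$vsum)), tolerance = 1e-12)
  expect_error(sdiff_sigma(s, tau, rho = 2), "rho")
})

test_that("event-free windows are refused rather than returning NaN", {
  a <- cr_sample(c(5, 6, 9), c(0, 0, 1))
  b <- cr_sample(c(5.5, 7, 8), c(0, 0, 1))
  s <- bind_groups(a, b)
  expect_error(rmtl_diff_test(s, tau = 4), "degenerate|no events")
  expect_error(rmtl_sdiff_test(s, tau = 4), "no events")
})

test_that("null p-values of the basic test are approximately uniform", {
  set.seed(53)
  cfg <- scenario_config("A", 200, 200)
  rs <- rejection_study(cfg, methods = "diff", reps = 5000, seed = 53,
                        store_p = TRUE)
  p <- rs$p_values[, "diff"]
  p <- p[!is.na(p)]
  ks <- max(abs(sort(p) - seq_along(p) / length(p)))
  expect_lt(ks, 0.03)
})
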
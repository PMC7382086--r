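test_that("product-limit and cumulative incidence match hand computation", {
  s <- toy_sample()
  sv <- allcause_survival(s)
  expect_equal(curve_at(sv, c(1, 2, 3)), c(0.75, 0.50, 0.25),
               tolerance = 1e-12)
  expect_equal(curve_at(sv, 0.5), 1)       # value 1 before the first event
  c1 <- cif(s, 1)
  c2 <- cif(s, 2)
  expect_equal(curve_at(c1, c(1, 3)), c(0.25, 0.50), tolerance = 1e-12)
  expect_equal(curve_at(c2, 2), 0.25, tolerance = 1e-12)
  expect_equal(curve_at(c1, 0.99), 0)
})

test_that("degenerate inputs follow the step-function conventions", {
  allcens <- cr_sample(c(2, 5, 7), c(0, 0, 0))
  expect_equal(curve_at(allcause_survival(allcens), c(1, 6, 10)),
               c(1, 1, 1))
  one <- cr_sample(5, 1)
  expect_equal(curve_at(allcause_survival(one), c(4.99, 5)), c(1, 0))
  nocause2 <- cif(cr_sample(c(1, 2), c(1, 1)), cause = 2)
  expect_equal(curve_at(nocause2, c(1, 2)), c(0, 0))
  expect_equal(cif_var_at(nocause2, c(1, 2)), c(0, 0))
  expect_error(cif(toy_sample(), cause = 0), "positive")
  expect_error(cr_sample(numeric(0), integer(0)), "empty")
})

test_that("causes conserve mass and CIFs are monotone on random samples", {
  set.seed(11)
  for (cens in c(0, 0.3)) {
    for (rep in 1:5) {
      s <- random_sample(80, cens = cens)
      c1 <- cif(s, 1)
      c2 <- cif(s, 2)
      sv <- allcause_survival(s)
      tt <- sv$time
      expect_true(all(diff(c1$cif) >= 0) && all(c1$cif <= 1 + 1e-12))
      expect_true(all(diff(c2$cif) >= 0))
      expect_true(all(c1$var >= 0))
      # exact identity at every event time, censored or not
      expect_equal(curve_at(c1, tt) + curve_at(c2, tt) + curve_at(sv, tt),
                   rep(1, length(tt)), tolerance = 1e-12)
    }
  }
})

test_that("single event type reduces the CIF to one minus Kaplan-Meier", {
  set.seed(3)
  tt <- rexp(60, 0.2)
  s <- cr_sample(tt, rep(1L, 60))
  c1 <- cif(s, 1)
  expect_equal(c1$cif, 1 - allcause_survival(s)$surv, tolerance = 1e-12)
  # no censoring, single cause: empirical CDF
  expect_equal(curve_at(c1, sort(tt)), seq_len(60) / 60, tolerance = 1e-12)
})

test_that("estimates and Aalen variance agree with independent references", {
  skip_if_not_installed("survival")
  skip_if_not_installed("cmprsk")
  set.seed(21)
  s <- random_sample(400, cens = 0.25)
  c1 <- cif(s, 1)
  sf <- survival::survfit(
    survival::Surv(time, factor(status, 0:2)) ~ 1,
    data = data.frame(time = s$time, status = s$status))
  expect_equal(curve_at(c1, sf$time), sf$pstate[, 2], tolerance = 1e-12)
  ci <- cmprsk::cuminc(s$time, s$status, cencode = 0)
  grid <- quantile(s$time[s$status == 1], c(0.2, 0.5, 0.8))
  tp <- cmprsk::timepoints(ci, grid)
  expect_equal(unname(curve_at(c1, grid)), unname(tp$est[1, ]),
               tolerance = 1e-10)
  expect_equal(unname(cif_var_at(c1, grid)), unname(tp$var[1, ]),
               tolerance = 0.02)
})
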
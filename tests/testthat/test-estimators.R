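ws <- function(w, T = 1) work_sample(w, temperature_T = T, units = "reduced")

test_that("the plain average and its degenerate single-sample case", {
  expect_equal(average_work(ws(c(1, 2, 3)))$estimate, 2)
  expect_warning(one <- average_work(ws(7)), "N_s = 1")
  expect_identical(one$estimate, 7)
  expect_identical(one$se, 0)
  expect_error(work_sample(numeric()), "empty")
})

test_that("the Jarzynski estimator reproduces closed-form values", {
  # N_s = 1: Wx equals Wa equals the single work value
  expect_warning(wx1 <- jarzynski_work(ws(5)), "N_s = 1")
  expect_identical(wx1$estimate, 5)
  # constant sample
  expect_equal(jarzynski_work(ws(rep(2.5, 8)))$estimate, 2.5,
               tolerance = 1e-12)
  # frozen high-precision arithmetic: -ln[(e^-1 + e^-2)/2] = 1.3798854930
  expect_equal(jarzynski_work(ws(c(1, 2)))$estimate, 1.3798854930,
               tolerance = 1e-9)
})

test_that("log-sum-exp shift makes huge works safe and exactly covariant", {
  big <- jarzynski_work(ws(c(1e4, 1e4 + 1)))$estimate
  expect_true(is.finite(big))
  # shift covariance: adding c shifts Wa and Wx by exactly c
  expect_equal(big, 1.3798854930 + 9999, tolerance = 1e-9)
  set.seed(3)
  w <- stats::rnorm(20, 10, 2)
  for (c_ in c(-5, 1e3)) {
    expect_equal(jarzynski_work(ws(w + c_))$estimate,
                 jarzynski_work(ws(w))$estimate + c_, tolerance = 1e-9)
    expect_equal(average_work(ws(w + c_))$estimate,
                 average_work(ws(w))$estimate + c_, tolerance = 1e-9)
  }
})

test_that("Jensen: Wx <= Wa for every sample, equality only when constant", {
  set.seed(21)
  for (i in 1:40) {
    w <- switch(1 + i %% 4,
                stats::rnorm(15, 10, 3),
                stats::rexp(10, 0.2),
                stats::runif(25, -5, 50),
                stats::rcauchy(12)^2)
    wa <- average_work(ws(w))$estimate
    wx <- jarzynski_work(ws(w))$estimate
    expect_lte(wx, wa + 1e-12 * max(1, abs(wa)))
    if (stats::var(w) > 1e-12) expect_lt(wx, wa)
  }
  expect_equal(jarzynski_work(ws(rep(3, 5)))$estimate,
               average_work(ws(rep(3, 5)))$estimate, tolerance = 1e-12)
})

test_that("mean Wx is non-increasing in N_s toward the free energy", {
  # Gaussian works N(10, 2^2), kBT = 1: ensemble Jarzynski value is 8; the
  # finite-sampling estimator decreases in expectation from <W> = 10 toward 8
  set.seed(99)
  mean_wx <- vapply(c(1, 3, 10, 30, 100), function(n) {
    mean(vapply(seq_len(200), function(r) {
      w <- stats::rnorm(n, 10, 2)
      suppressWarnings(jarzynski_work(ws(w))$estimate)
    }, numeric(1)))
  }, numeric(1))
  # allow sampling slack of 0.15 kBT per step (SE of each mean ~0.05-0.14)
  expect_true(all(diff(mean_wx) < 0.15))
  expect_lt(mean_wx[5], mean_wx[1] - 1)
})

test_that("bootstrap errors: degenerate cases and the exhaustive {1,2} oracle", {
  expect_identical(bootstrap_se(ws(rep(4, 6)), "Wa", B = 200, seed = 1), 0)
  expect_error(bootstrap_se(ws(5), "Wa"), "N_s = 1")
  expect_error(bootstrap_se(ws(c(1, 2)), "Wa", B = 10), "B must be")
  # n = 2 has 4 equally likely resamples; exhaustive SDs (population, over
  # resamples) are 0.3535533906 for Wa and 0.3586180053 for Wx
  expect_equal(bootstrap_se(ws(c(1, 2)), "Wa", B = 4000, seed = 8),
               0.3535533906, tolerance = 0.05)
  expect_equal(bootstrap_se(ws(c(1, 2)), "Wx", B = 4000, seed = 8),
               0.3586180053, tolerance = 0.05)
  # seeded: reproducible
  expect_identical(bootstrap_se(ws(c(1, 2, 4)), "Wx", B = 500, seed = 3),
                   bootstrap_se(ws(c(1, 2, 4)), "Wx", B = 500, seed = 3))
})

test_that("bootstrap SE of the mean tracks the closed form sigma/sqrt(n)", {
  set.seed(17)
  ses <- vapply(seq_len(50), function(r) {
    bootstrap_se(ws(stats::rnorm(30, 10, 2)), "Wa", B = 400, seed = r)
  }, numeric(1))
  expect_equal(mean(ses), 2 / sqrt(30), tolerance = 0.3)
})

test_that("estimate_work bundles both estimators with bootstrap errors", {
  set.seed(5)
  s <- ws(stats::rnorm(30, 12, 3))
  e <- estimate_work(s, B = 500, seed = 2, label = "bound")
  expect_s3_class(e, "estimator_result")
  expect_lte(e$Wx, e$Wa)
  expect_gt(e$se_Wa, 0)
  expect_gt(e$se_Wx, 0)
  expect_identical(e$N_s, 30L)
  expect_error(estimator_result(Wa = 1, Wx = 2), "Jensen")
})

test_that("ordering report computes margins in kBT and flags violations", {
  ok <- ordering_check(8, estimator_result(Wa = 10, Wx = 9))
  expect_true(ok$pass)
  expect_equal(ok$margin_dg_kbt, 1)
  expect_equal(ok$margin_jensen_kbt, 1)
  bad <- ordering_check(9.5, estimator_result(Wa = 10, Wx = 9))
  expect_false(bad$pass)
  expect_false(bad$dg_below_wx)
  expect_true(bad$wx_below_wa)
})

test_that("viscous correction subtracts, propagates in quadrature, rounds for display", {
  bound <- estimator_result(Wa = 5.0e-19, Wx = 4.0e-19, se_Wa = 0.6e-19,
                            se_Wx = 0.6e-19, N_s = 30L, temperature_T = 300,
                            units = "si")
  visc <- estimator_result(Wa = 0.8e-19, Wx = 0.4e-19, se_Wa = 0.2e-19,
                           se_Wx = 0.2e-19, N_s = 30L, temperature_T = 300,
                           units = "si", label = "viscous")
  corr <- viscous_correction(bound, visc)
  expect_equal(corr$Wx, 3.6e-19, tolerance = 1e-12)
  expect_equal(corr$se_Wx, sqrt(0.36 + 0.04) * 1e-19, tolerance = 1e-9)
  expect_equal(corr$display_Wx, 3.6e-19, tolerance = 1e-12)
  expect_equal(corr$display_se_Wx, 0.6e-19, tolerance = 1e-12)
  expect_identical(corr$label, "corrected")

  zero <- estimator_result(Wa = 0, Wx = 0, se_Wa = 0, se_Wx = 0,
                           temperature_T = 300, units = "si")
  expect_equal(viscous_correction(bound, zero)$Wx, bound$Wx)
  expect_equal(viscous_correction(bound, bound)$Wx, 0)
  visc_bad <- estimator_result(Wa = 1e-19, Wx = 0.5e-19, temperature_T = 310,
                               units = "si")
  expect_error(viscous_correction(bound, visc_bad), "temperature")
})

test_that("affinity constant to free energy and back", {
  dg <- delta_g_from_ka(18.79e3, 300)
  # printed value 4.07e-20 J, agreement within one unit of its last digit
  expect_lt(abs(dg - 4.07e-20), 0.01e-20)
  expect_identical(delta_g_from_ka(1, 300), 0)
  expect_error(delta_g_from_ka(-2, 300), "Ka")
  expect_equal(ka_from_delta_g(dg, 300), 18.79e3, tolerance = 1e-10)
})
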
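test_that("sinusoid evaluation matches the closed form and its edge cases", {
  # zero amplitude: constant forcing
  f0 <- seasonal_forcing(27.3, 0)
  expect_equal(eval_forcing(f0, c(0, 17, 359.5, 1000)), rep(27.3, 4))

  # frozen value computed independently: 27 + 2.5*sin(2*pi*225/360 - 5*pi/6)
  # = 27 + 2.5*sin(75 deg) = 29.41481456572267
  f <- seasonal_forcing(27, 2.5, phase_for_peak(240))
  expect_equal(f$phase, -5 * pi / 6)
  expect_equal(eval_forcing(f, 225), 29.41481456572267, tolerance = 1e-12)

  # the peak day carries the maximum
  expect_equal(eval_forcing(f, 240), 27 + 2.5, tolerance = 1e-12)

  # invalid construction
  expect_error(seasonal_forcing(27, -1), "amplitude")
  expect_error(seasonal_forcing(27, 1, period_days = 0), "period_days")
})

test_that("baseline forcing is periodic with the 360-day year", {
  f <- seasonal_forcing(5.8, 0.5, phase_for_peak(172))
  set.seed(99)
  t <- stats::runif(1000, 0, 3600)
  expect_equal(eval_forcing(f, t), eval_forcing(f, t + 360), tolerance = 1e-9)
})

test_that("the model calendar maps days to 30-day months and 360-day years", {
  expect_equal(month_of_day(c(0, 1, 30, 31, 181, 210, 211, 240, 241, 270, 360, 361)),
               c(1, 1, 1, 2, 7, 7, 8, 8, 9, 9, 12, 1))
  expect_equal(year_of_day(c(0, 1, 360, 361, 3600)), c(1, 1, 1, 2, 10))
})

test_that("anomaly overlay adds the scheduled offsets in the right months", {
  f <- site_forcings("lee_stocking")$sst
  sched <- warming_schedule()

  # +1.5 degC anywhere in August, +1 in July and September
  expect_equal(eval_sst(f, 225, sched) - eval_forcing(f, 225), 1.5)
  expect_equal(eval_sst(f, 185, sched) - eval_forcing(f, 185), 1.0)
  expect_equal(eval_sst(f, 265, sched) - eval_forcing(f, 265), 1.0)
  # December (and any unscheduled month): no offset
  expect_equal(eval_sst(f, 345, sched), eval_forcing(f, 345))

  # warming dominance: never below baseline, equal exactly outside Jul-Sep
  set.seed(4)
  t <- stats::runif(1000, 0, 3600)
  delta <- eval_sst(f, t, sched) - eval_forcing(f, t)
  expect_true(all(delta >= 0))
  in_window <- month_of_day(t) %in% 7:9
  expect_true(all(delta[!in_window] == 0))
  expect_true(all(delta[in_window] > 0))

  expect_error(anomaly_schedule(13, 1), "1..12")
  expect_error(anomaly_schedule(c(7, 7), c(1, 1)), "unique")
})

test_that("random-years mode selects years reproducibly with probability prob", {
  s_all <- warming_schedule(mode = "random_years", prob = 1)
  s_none <- warming_schedule(mode = "random_years", prob = 0)
  expect_true(all(select_anomaly_years(s_all, 10, seed = 3)))
  expect_false(any(select_anomaly_years(s_none, 10, seed = 3)))

  s_half <- warming_schedule(mode = "random_years", prob = 0.5)
  a <- select_anomaly_years(s_half, 50, seed = 7)
  expect_identical(a, select_anomaly_years(s_half, 50, seed = 7))
  expect_true(any(a) && !all(a))

  # unselected years get no offset
  ya <- c(TRUE, FALSE)
  sched <- warming_schedule()
  expect_equal(anomaly_delta(sched, 225, years_active = ya), 1.5)
  expect_equal(anomaly_delta(sched, 360 + 225, years_active = ya), 0)
})

test_that("seasonal fit recovers generating coefficients", {
  truth <- seasonal_forcing(26.5, 2.5, phase_for_peak(240))
  clim <- tibble::tibble(month = 1:12,
                         sst_c = eval_forcing(truth, (1:12 - 0.5) * 30))
  fit <- fit_seasonal_forcing(clim, "sst_c", driver = "sst")
  expect_equal(fit$mean_level, truth$mean_level, tolerance = 1e-9)
  expect_equal(fit$amplitude, truth$amplitude, tolerance = 1e-9)
  expect_equal(fit$phase, truth$phase, tolerance = 1e-9)
  expect_lt(glance(fit)$rss, 1e-18)

  # round trip through the evaluated curve
  expect_equal(eval_forcing(fit, 0:360), eval_forcing(truth, 0:360),
               tolerance = 1e-9)

  # degenerate inputs
  expect_error(fit_seasonal_forcing(clim[1:3, ], "sst_c"), "at least 4")
  const <- tibble::tibble(month = 1:12, sst_c = rep(27, 12))
  expect_warning(cfit <- fit_seasonal_forcing(const, "sst_c"), "constant")
  expect_equal(cfit$amplitude, 0)
  expect_equal(cfit$mean_level, 27)
})

test_that("noisy seasonal fits are unbiased within Monte-Carlo error", {
  truth <- seasonal_forcing(27, 2, phase_for_peak(240))
  t_mid <- (1:12 - 0.5) * 30
  base <- eval_forcing(truth, t_mid)
  sigma <- 0.1
  n_seeds <- 100
  est <- t(vapply(seq_len(n_seeds), function(s) {
    set.seed(s)
    clim <- tibble::tibble(month = 1:12, sst_c = base + stats::rnorm(12, 0, sigma))
    fit <- fit_seasonal_forcing(clim, "sst_c")
    c(fit$mean_level, fit$amplitude)
  }, numeric(2)))
  # mean of the estimates within 3 MC standard errors of the truth
  for (j in 1:2) {
    se <- stats::sd(est[, j]) / sqrt(n_seeds)
    expect_lt(abs(mean(est[, j]) - c(27, 2)[j]), 3 * se + 1e-12)
  }
})

test_that("tidy and glance expose forcing coefficients broom-style", {
  f <- seasonal_forcing(5.8, 0.5, phase_for_peak(172), driver = "si")
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate[td$term == "amplitude"], 0.5)
  expect_true(is.na(glance(f)$rss))
})
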
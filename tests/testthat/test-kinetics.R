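test_that("enhancement and concentration arithmetic match the HU anchors", {
  expect_equal(enhancement(-1000), 0)
  expect_equal(enhancement(-750), 250)
  expect_equal(enhancement(-875), 125)

  plateau <- tibble::tibble(roi = "nasal_left", time_s = seq(0, 67.5, 1.5),
                            hu = -1000 + 250 * pmin(seq(0, 67.5, 1.5) / 20, 1))
  e100 <- reference_enhancement(plateau)
  expect_equal(as.numeric(e100), 250)
  expect_true(attr(e100, "valid"))

  flat_air <- tibble::tibble(roi = "n", time_s = 0:10, hu = rep(-1000, 11))
  expect_warning(e0 <- reference_enhancement(flat_air), "not a valid")
  expect_equal(as.numeric(e0), 0)
  expect_false(attr(e0, "valid"))

  curve <- tibble::tibble(roi = "m", time_s = c(0, 1, 2),
                          hu = c(-1000, -875, -750))
  conc <- to_concentration(curve, 250)
  expect_equal(conc$c, c(0, 0.5, 1))
  expect_equal(attr(conc, "e100_hu"), 250)
  expect_error(to_concentration(curve, 0), "positive")
  expect_error(to_concentration(curve, -5), "positive")

  # noisy readings above the reference are capped at 1.1 before fitting
  hot <- tibble::tibble(roi = "m", time_s = c(0, 1, 2),
                        hu = c(-1000, -700, -650))
  expect_equal(max(to_concentration(hot, 250)$c), 1.1)
})

test_that("noisy reference is biased no lower than the clean maximum", {
  # max of noisy enhancements is an order statistic >= noise-free in expectation
  tt <- seq(0, 67.5, 1.5)
  clean <- -1000 + 250 * (1 - exp(-pmax(tt - 10.5, 0) / 2.5))
  refs <- vapply(1:200, function(i) {
    withr::with_seed(i, {
      noisy <- tibble::tibble(roi = "n", time_s = tt,
                              hu = clean + stats::rnorm(length(tt), sd = 2))
      as.numeric(reference_enhancement(noisy))
    })
  }, numeric(1))
  expect_gt(mean(refs), max(clean + 1000))
})

test_that("wash-in fitting recovers generator time constants exactly", {
  for (tau in c(7, 18)) {
    fit <- fit_washin(model_washin_curve(tau), c(34.5, 52.5), t0 = 34.5)
    expect_true(fit$converged)
    expect_equal(fit$tau_s, tau, tolerance = 1e-4)
    expect_equal(fit$level, 1, tolerance = 1e-3)
    expect_lt(fit$rmse, 1e-6)
    expect_equal(fit$n_points, 13L)
  }

  flat <- model_washin_curve(7)
  flat$c <- rep(0.4, nrow(flat))
  ffit <- fit_washin(flat, c(34.5, 52.5), t0 = 34.5)
  expect_false(ffit$converged)
  expect_true(is.na(ffit$tau_s))

  expect_error(fit_washin(model_washin_curve(7), c(100, 110), 100),
               "outside the curve")
  expect_error(fit_washin(model_washin_curve(7), c(34.5, 36.5), 34.5),
               "fewer than 3")
  expect_error(fit_washin(model_washin_curve(7), c(34.5, 52.5), 40),
               "must not exceed")
})

test_that("wash-out fitting recovers fast and slow decays", {
  fit6 <- fit_washout(model_washout_curve(6), c(63, 69), t0 = 63)
  expect_true(fit6$converged)
  expect_equal(fit6$tau_s, 6, tolerance = 1e-4)

  # slow laminar decay, longer window sampled every 1.5 s
  slow <- model_washout_curve(60, times = seq(52.5, 63, 1.5), t0 = 52.5)
  fit60 <- fit_washout(slow, c(52.5, 63), t0 = 52.5)
  expect_true(fit60$converged)
  expect_equal(fit60$tau_s, 60, tolerance = 0.05)

  zero <- model_washout_curve(6)
  zero$c <- 0
  expect_false(fit_washout(zero, c(63, 69), 63)$converged)
})

test_that("fit error shrinks with the noise level", {
  taus <- sapply(c(0, 2, 5), function(sigma) {
    est <- vapply(1:30, function(i) {
      curve <- model_washin_curve(7)
      withr::with_seed(7000 + i * 10 + sigma, {
        curve$c <- curve$c + stats::rnorm(nrow(curve), sd = sigma / 250)
      })
      f <- fit_washin(curve, c(34.5, 52.5), 34.5)
      c(f$tau_s, f$rmse)
    }, numeric(2))
    c(err = mean(abs(est[1, ] - 7)), rmse = mean(est[2, ]))
  })
  expect_lt(taus["err", 1], 1e-4)
  expect_lt(taus["rmse", 1], 1e-6)
  expect_true(all(diff(taus["err", ]) > 0))   # error grows with sigma
  expect_true(all(diff(taus["rmse", ]) > 0))
  expect_lt(taus["err", 3] / 7, 0.15)         # still informative at 5 HU
})

test_that("fitted plateau stays within the data envelope for plateauing data", {
  # meaningful when the curve approaches its plateau inside the window;
  # for very slow kinetics c_ss is an extrapolation beyond the data by design
  for (tau in c(2, 3, 4)) {
    curve <- model_washin_curve(tau, css = 0.85)
    f <- fit_washin(curve, c(34.5, 52.5), 34.5)
    expect_true(f$level >= min(curve$c) - 1e-9)
    expect_true(f$level <= max(curve$c) + 3 * f$rmse + 0.02)
  }
  curve <- model_washin_curve(4, css = 0.85)
  withr::with_seed(99, {
    curve$c <- pmax(curve$c + stats::rnorm(nrow(curve), sd = 0.01), 0)
  })
  f <- fit_washin(curve, c(34.5, 52.5), 34.5)
  expect_true(f$level >= min(curve$c) - 1e-9)
  expect_true(f$level <= max(curve$c) + 3 * f$rmse)
})

test_that("summary collates fits with series-wide peaks", {
  fx <- pre_noisefree()
  res <- analyze_experiment(fx$series, fx$rois, default_config("pre_fess"),
                            fx$protocol)
  summ <- res$summary
  expect_setequal(unique(summ$roi), sinus_regions())
  expect_equal(nrow(summ), 12)  # 6 wash-in + 6 wash-out rows
  frontal <- summ[summ$roi == "frontal_L" & summ$direction == "wash_in", ]
  expect_equal(frontal$peak_c, 0.10, tolerance = 0.02)

  empty <- summarize_kinetics(list(), list())
  expect_equal(nrow(empty), 0)

  f1 <- fit_washin(model_washin_curve(7), c(34.5, 52.5), 34.5)
  f2 <- fit_washin(model_washin_curve(9), c(34.5, 52.5), 34.5)
  expect_warning(
    dup <- summarize_kinetics(list(f1, f2), model_washin_curve(9)),
    "keeping the last"
  )
  expect_equal(nrow(dup), 1)
  expect_equal(dup$tau_s, 9, tolerance = 1e-3)

  # broom-style accessors
  td <- tidy(f1)
  expect_equal(td$tau_s, 7, tolerance = 1e-4)
  expect_true(glance(f1)$converged)
})
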
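test_that("component regression recovers exact linear relations", {
  te <- seq(-30, 30, by = 2)
  f1 <- fit_component_regression(te, te)
  expect_equal(c(f1$gain, f1$bias, f1$r2), c(1, 0, 1))
  f2 <- fit_component_regression(0.8 * te + 2, te)
  expect_equal(c(f2$gain, f2$bias, f2$r2), c(0.8, 2, 1))
  withr::with_seed(8, dg <- te + rnorm(length(te), 0, 0.1))
  expect_gt(fit_component_regression(dg, te)$r2, 0.99)
  # noisy gain recovery at n = 500
  withr::with_seed(44, {
    te5 <- runif(500, -30, 30)
    dg5 <- te5 + rnorm(500, 0, 3)
  })
  expect_true(abs(fit_component_regression(dg5, te5)$gain - 1) < 0.1)
  # degenerate regressor flagged
  expect_true(fit_component_regression(c(1, 2, 3), c(5, 5, 5))$degenerate)
})

test_that("ideal predictions collapse where models coincide", {
  rec <- simulate_records(200, params_noise_free(model = "DFB"),
                          seed = 2, noise = FALSE)
  sta <- rec[rec$klass == "static", ]
  expect_gt(nrow(sta), 10)
  expect_equal(predict_ideal(sta, "SFB"), predict_ideal(sta, "DFB"))
  # generator loop: DFB data regressed on the DFB prediction is exact
  dyn <- rec[rec$klass == "dynamic", ]
  pr <- predict_ideal(dyn, "DFB")
  f <- fit_component_regression(dyn$dg2_az, pr$pred_az)
  expect_lt(abs(f$gain - 1), 1e-9)
  expect_lt(abs(f$bias), 1e-9)
  expect_gt(f$r2, 1 - 1e-9)
})

test_that("noise-free MLR returns the generative coefficients exactly", {
  rec <- simulate_records(400, params_noise_free(model = "DFB"),
                          seed = 6, noise = FALSE)
  dyn <- rec[rec$klass == "dynamic", ]
  f <- fit_updating_mlr(dyn, "DFB")
  expect_lt(abs(f$alpha - 1), 1e-9)
  expect_lt(abs(f$beta + 1), 1e-9)
  expect_lt(abs(f$bias), 1e-9)
  expect_gt(f$r2, 1 - 1e-9)
  # no-updating data fitted with the visual regression: alpha 1, beta 0
  rec_nc <- simulate_records(400, params_noise_free(model = "NC"),
                             seed = 6, noise = FALSE)
  f_nc <- fit_updating_mlr(rec_nc[rec_nc$klass != "excluded", ], "NC")
  expect_lt(abs(f_nc$alpha - 1), 1e-9)
  expect_lt(abs(f_nc$beta), 1e-9)
})

test_that("noisy MLR recovers coefficients within sampling error", {
  p <- sim_params(model = "DFB", endpoint_sd = 3)
  rec <- simulate_records(2500, p, seed = 14)
  dyn <- rec[rec$klass == "dynamic", ]
  expect_gte(nrow(dyn), 500)
  f <- fit_updating_mlr(dyn[1:500, ], "DFB")
  dyn <- dyn[1:500, ]
  expect_true(f$alpha > 0.9 && f$alpha < 1.1)
  expect_true(f$beta > -1.1 && f$beta < -0.9)
  expect_error(fit_updating_mlr(dyn[1:5, ], "DFB"), "10")
})

test_that("the single 2 SD outlier pass removes only true outliers", {
  p <- sim_params(model = "DFB", endpoint_sd = 2)
  rec <- simulate_records(1200, p, seed = 25)
  dyn <- head(rec[rec$klass == "dynamic", ], 200)
  expect_equal(nrow(dyn), 200)
  expect_equal(nrow(drop_fit_outliers(dyn, "DFB")), 200 -
                 sum(abs(residuals(lm(dg2_az ~ t2e_az + gme1_az, dyn))) >
                       2 * sd(residuals(lm(dg2_az ~ t2e_az + gme1_az, dyn)))))
  # plant one gross outlier
  bad <- dyn[1, ]
  bad$dg2_az <- bad$dg2_az + 30
  bad$trial_id <- -1
  planted <- dplyr::bind_rows(dyn[-1, ], bad)
  kept <- drop_fit_outliers(planted, "DFB")
  expect_false(-1 %in% kept$trial_id)
  # on clean Gaussian residuals about 4.6 percent get trimmed
  withr::with_seed(33, {
    n <- 20000
    fake <- tibble::tibble(t2e_az = runif(n, -30, 30),
                           gme1_az = runif(n, -20, 20))
    fake$dg2_az <- fake$t2e_az - fake$gme1_az + rnorm(n, 0, 3)
  })
  frac <- 1 - nrow(drop_fit_outliers(fake, "DFB")) / n
  expect_lt(abs(frac - 0.046), 0.01)
})

test_that("bootstrap SDs are calibrated and reproducible", {
  withr::with_seed(10, {
    x <- rnorm(500, 0, 8)
    y <- x + rnorm(500, 0, 3)
  })
  fit <- lm(y ~ x)
  se <- summary(fit)$coefficients["x", 2]
  X <- cbind(bias = 1, alpha = x)
  b1 <- bootstrap_mlr(y, X, n_boot = 1000, seed = 11)
  expect_lt(abs(sd(b1$alpha) - se) / se, 0.2)
  b2 <- bootstrap_mlr(y, X, n_boot = 1000, seed = 11)
  expect_identical(b1, b2)
})

test_that("bootstrap SDs shrink like one over root n", {
  p <- sim_params(model = "DFB", endpoint_sd = 3)
  rec <- simulate_records(7000, p, seed = 71)
  dyn <- rec[rec$klass == "dynamic", ]
  expect_gte(nrow(dyn), 1600)
  ns <- c(100, 400, 1600)
  sds <- vapply(ns, function(n) {
    f <- fit_updating_mlr(dyn[seq_len(n), ], "DFB", n_boot = 300, seed = n)
    f$boot_sd_beta
  }, 0)
  slope <- coef(lm(log(sds) ~ log(ns)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("model comparison selects the generating model", {
  for (truth in c("VU", "SFB", "DFB")) {
    p <- sim_params(model = truth, endpoint_sd = 4)
    rec <- simulate_records(1500, p, seed = 300 + match(truth, c("VU", "SFB", "DFB")))
    dyn <- rec[rec$klass == "dynamic", ]
    cmp <- compare_updating_models(dyn)
    expect_equal(cmp$best, truth)
  }
  # SFB-generated data still put the generating model clearly on top
  p <- sim_params(model = "SFB", endpoint_sd = 4)
  rec <- simulate_records(1500, p, seed = 302)
  dyn <- rec[rec$klass == "dynamic", ]
  cmp <- compare_updating_models(dyn)
  expect_equal(cmp$ranking[1], "SFB")
  expect_gt(cmp$fits$r2[cmp$fits$model == "SFB"],
            max(cmp$fits$r2[cmp$fits$model != "SFB"]) + 0.01)
})

test_that("static-only record sets make the motor-feedback models tie", {
  rec <- simulate_records(400, sim_params(model = "DFB"), seed = 5,
                          t2_timing = "static")
  sta <- rec[rec$klass == "static", ]
  cmp <- compare_updating_models(sta, models = c("SFB", "DFB"))
  fits <- cmp$fits
  expect_lt(abs(fits$r2[1] - fits$r2[2]), 1e-9)
  expect_lt(abs(fits$alpha[1] - fits$alpha[2]), 1e-9)
  expect_lt(abs(fits$beta[1] - fits$beta[2]), 1e-9)
})

test_that("r2 ordering is invariant to affine rescaling of positions", {
  p <- sim_params(model = "DFB", endpoint_sd = 4)
  rec <- simulate_records(800, p, seed = 45)
  dyn <- rec[rec$klass == "dynamic", ]
  cmp1 <- compare_updating_models(dyn)
  scaled <- dyn
  for (cl in grep("_az$|_el$", names(scaled), value = TRUE)) {
    scaled[[cl]] <- scaled[[cl]] * 3.7
  }
  cmp2 <- compare_updating_models(scaled)
  expect_equal(cmp2$ranking, cmp1$ranking)
  expect_equal(cmp2$fits$r2, cmp1$fits$r2, tolerance = 1e-9)
})

test_that("paired bootstrap t-tests separate the models on DFB data", {
  p <- sim_params(model = "DFB", endpoint_sd = 4)
  rec <- simulate_records(1500, p, seed = 52)
  dyn <- rec[rec$klass == "dynamic", ]
  cmp <- compare_updating_models(dyn, n_boot = 300, seed = 52)
  expect_equal(cmp$best, "DFB")
  pw <- cmp$pairwise
  dfb_rows <- pw[pw$model_a == "DFB" | pw$model_b == "DFB", ]
  expect_true(all(dfb_rows$significant))
})

test_that("the head regression attributes head movements correctly", {
  p <- sim_params(head_gain_hme = 0.25)
  rec <- simulate_records(800, p, seed = 61)
  kept <- rec[rec$klass != "excluded", ][1:500, ]
  hf <- fit_head_mlr(kept, n_boot = 500, seed = 61)
  expect_lt(abs(hf$beta - 0.25), 0.05)
  expect_true(hf$alpha_ci[1] <= 0 && hf$alpha_ci[2] >= 0)
  # head at rest: all coefficients zero
  still <- kept
  still$dh2_az <- 0
  h0 <- fit_head_mlr(still, n_boot = 0)
  expect_equal(c(h0$alpha, h0$beta, h0$bias), c(0, 0, 0))
  # symmetric recovery when the head is driven by gaze motor error instead
  flipped <- kept
  withr::with_seed(62,
    flipped$dh2_az <- 0.25 * flipped$gme2_az + rnorm(nrow(flipped), 0, 1))
  hg <- fit_head_mlr(flipped, n_boot = 500, seed = 62)
  expect_lt(abs(hg$alpha - 0.25), 0.05)
  expect_lt(abs(hg$beta), 0.05)
})

test_that("perisaccadic delay curves are flat for dynamic-feedback data", {
  # a 95% CI misses zero for 1 in 20 true nulls, so check over replicates
  p <- sim_params(model = "DFB", endpoint_sd = 3)
  contains0 <- vapply(1:6, function(r) {
    rec <- simulate_records(1500, p, seed = 100 + r)
    dyn <- rec[rec$klass == "dynamic", ]
    tr <- perisaccadic_by_delay(dyn)$trend_delay
    tr$lower <= 0 && tr$upper >= 0
  }, TRUE)
  expect_gte(sum(contains0), 4)
  rec <- simulate_records(1500, p, seed = 101)
  dyn <- rec[rec$klass == "dynamic", ]
  pa <- perisaccadic_by_delay(dyn)
  expect_gt(nrow(pa$curve), 3)
  # zero noise: the error curves are identically zero
  rec0 <- simulate_records(800, params_noise_free(model = "DFB"),
                           seed = 102, noise = FALSE)
  dyn0 <- rec0[rec0$klass == "dynamic", ]
  pa0 <- perisaccadic_by_delay(dyn0)
  expect_lt(max(abs(pa0$curve$parallel_mean)), 1e-9)
  expect_lt(max(abs(pa0$curve$perpendicular_mean)), 1e-9)
  expect_error(perisaccadic_by_delay(dyn[1:10, ]), "20")
})

test_that("static-feedback data show the overcompensation signature", {
  p <- sim_params(model = "SFB", endpoint_sd = 3)
  rec <- simulate_records(1500, p, seed = 103)
  dyn <- rec[rec$klass == "dynamic", ]
  pa <- perisaccadic_by_delay(dyn)
  # parallel error tracks minus the pre-flash displacement
  expect_lt(pa$trend_preflash$upper, 0)
  expect_lt(abs(pa$trend_preflash$slope + 1), 0.15)
})

test_that("flash-duration analysis finds planted effects and nulls", {
  p <- sim_params(model = "DFB", endpoint_sd = 3)
  rec <- simulate_records(1200, p, seed = 104)
  dyn <- rec[rec$klass != "excluded", ]
  pd <- perisaccadic_by_duration(dyn)
  expect_true(pd$trend_az$lower <= 0 && pd$trend_az$upper >= 0)
  # plant a duration-dependent error and detect it
  planted <- dyn
  planted$dg2_az <- planted$dg2_az + 0.3 * planted$flash_dur_ms
  pp <- perisaccadic_by_duration(planted)
  expect_gt(pp$trend_az$lower, 0)
  # single duration: trend undefined and flagged
  one <- dyn[dyn$flash_dur_ms == dyn$flash_dur_ms[1], ]
  po <- perisaccadic_by_duration(one)
  expect_false(po$trend_az$defined)
  expect_equal(nrow(po$by_duration), 1)
})

test_that("the KS test behaves on identical and separated samples", {
  x <- rnorm(50)
  expect_equal(ks_two_sample(x, x)$statistic, 0)
  withr::with_seed(7, {
    a <- rnorm(200)
    b <- rnorm(200, 3)
  })
  expect_lt(ks_two_sample(a, b)$p_value, 1e-10)
  expect_error(ks_two_sample(1:3, 1:10), "at least 5")
})

test_that("tidiers return well-formed tibbles", {
  p <- sim_params(model = "DFB", endpoint_sd = 3)
  rec <- simulate_records(800, p, seed = 105)
  dyn <- rec[rec$klass == "dynamic", ]
  f <- fit_updating_mlr(dyn, "DFB", n_boot = 100, seed = 1)
  td <- generics::tidy(f)
  expect_equal(td$term, c("alpha", "beta", "bias"))
  expect_true(all(td$boot_sd > 0))
  gl <- generics::glance(f)
  expect_equal(gl$model, "DFB")
  cmp <- compare_updating_models(dyn, n_boot = 50, seed = 1)
  expect_equal(generics::glance(cmp)$best, "DFB")
  hf <- fit_head_mlr(dyn, n_boot = 50, seed = 1)
  expect_equal(nrow(generics::tidy(hf)), 3)
})
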
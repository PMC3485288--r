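test_that("trial timing draws stay inside the paradigm's ranges", {
  withr::with_seed(3, tm <- sample_trial_timing(10000))
  expect_true(all(tm$fixation_dur_ms >= 600 & tm$fixation_dur_ms <= 1100))
  expect_true(all(tm$gap1_ms >= 10 & tm$gap1_ms <= 70))
  expect_true(all(tm$gap2_ms >= 90 & tm$gap2_ms <= 140))
  expect_true(all(tm$t1_dur_ms %in% 10:30))
  expect_true(all(tm$t2_dur_ms %in% 10:30))
  expect_true(all(tm == floor(tm)))
  # same seed, same sequence
  a <- withr::with_seed(7, sample_trial_timing(50))
  b <- withr::with_seed(7, sample_trial_timing(50))
  expect_identical(a, b)
})

test_that("the target web has 85 LEDs on 7 rings and 12 spokes", {
  web <- make_target_web()
  expect_equal(nrow(web), 85)
  expect_equal(sum(web$r == 0), 1)
  expect_true(any(web$r == 43 & web$phi == 330))
  expect_setequal(unique(web$r), c(0, 5, 9, 14, 20, 27, 35, 43))
})

test_that("the default double-step set has 144 unique configurations", {
  ds <- make_double_step_set()
  expect_equal(nrow(ds), 144)
  expect_equal(nrow(dplyr::distinct(ds)), 144)
  small <- make_double_step_set(
    t1 = tibble::tibble(azimuth = c(10, -10), elevation = 0),
    t2 = tibble::tibble(azimuth = c(0, 5, 9), elevation = 1))
  expect_equal(nrow(small), 6)
  expect_error(make_double_step_set(t1 = tibble::tibble(azimuth = numeric(),
                                                        elevation = numeric())),
               "empty")
})

test_that("a simulated gaze shift lands on goal and obeys the VOR contract", {
  p <- params_noise_free(first_gain = 1)
  # goal == start: flat traces, no events
  gs0 <- simulate_gaze_shift(5, -3, 5, -3, p, noise = FALSE)
  expect_null(gs0$events)
  expect_lt(max(abs(gs0$gaze$azimuth - 5)), 1e-12)
  gs <- simulate_gaze_shift(0, 0, 20, 0, p, noise = FALSE)
  n <- nrow(gs$gaze)
  expect_lt(abs(gs$gaze$azimuth[n] - 20), 1e-6)
  # gaze = eye-in-head + head at all samples (linearized)
  eye <- gs$gaze$azimuth - gs$head$azimuth
  expect_equal(gs$gaze$azimuth, eye + gs$head$azimuth)
  # after gaze offset, gaze holds while the head still moves
  post <- gs$gaze$time_ms > gs$events$gaze_offset
  expect_lt(max(abs(gs$gaze$azimuth[post] - 20)), 1e-9)
  head_post <- gs$head$azimuth[post]
  expect_gt(max(head_post) - min(head_post), 0.1)
  expect_error(simulate_gaze_shift(0, 0, 95, 0, p, noise = FALSE), "90")
})

test_that("the raised-cosine profile has the analytic peak speed", {
  p <- params_noise_free(first_gain = 1)
  gs <- simulate_gaze_shift(0, 0, 20, 0, p, noise = FALSE)
  d <- differentiate(gs$gaze)
  analytic <- profile_peak_speed(20, p$ms_intercept + p$ms_slope * 20)
  expect_lt(abs(max(d$speed) - analytic) / analytic, 0.02)
})

test_that("second responses follow the selected updating model", {
  p <- sim_params()
  # NC without noise returns the raw retinal error
  nc <- generate_second_response("NC", 12, -3, params = p, noise = FALSE)
  expect_equal(unlist(nc), c(dg2_az = 12, dg2_el = -3))
  # on a static trial (GME1 = dG1) SFB and DFB coincide
  sfb <- generate_second_response("SFB", 12, -3, dg1_az = 18, dg1_el = 2,
                                  params = p, noise = FALSE)
  dfb <- generate_second_response("DFB", 12, -3, gme1_az = 18, gme1_el = 2,
                                  params = p, noise = FALSE)
  expect_identical(sfb, dfb)
  expect_error(generate_second_response("XX", 1, 1), "arg")
})

test_that("gaze-position and motor-error dynamic feedback are equivalent", {
  # DFB computed as T2E - GME1 equals (T2E + G1) - G2 because GME1 = G2 - G1
  withr::with_seed(17, {
    t2e <- matrix(rnorm(2000), ncol = 2)
    g1 <- matrix(rnorm(2000, 0, 10), ncol = 2)
    g2 <- matrix(rnorm(2000, 0, 10), ncol = 2)
  })
  via_gme <- generate_second_response("DFB", t2e[, 1], t2e[, 2],
                                      gme1_az = g2[, 1] - g1[, 1],
                                      gme1_el = g2[, 2] - g1[, 2],
                                      noise = FALSE)
  via_pos_az <- (t2e[, 1] + g1[, 1]) - g2[, 1]
  via_pos_el <- (t2e[, 2] + g1[, 2]) - g2[, 2]
  expect_lt(max(abs(via_gme$dg2_az - via_pos_az)), 1e-12)
  expect_lt(max(abs(via_gme$dg2_el - via_pos_el)), 1e-12)
})

test_that("head responses are driven by head motor error alone", {
  p <- sim_params(head_gain_hme = 0.25)
  h <- generate_head_response(20, 0, p, noise = FALSE)
  expect_equal(unlist(h), c(dh2_az = 5, dh2_el = 0))
  p0 <- sim_params(head_gain_hme = 0)
  h0 <- generate_head_response(20, 0, p0, noise = FALSE)
  expect_equal(unlist(h0), c(dh2_az = 0, dh2_el = 0))
})

test_that("record simulation is reproducible and mixes static and dynamic", {
  a <- simulate_records(300, sim_params(), seed = 11)
  b <- simulate_records(300, sim_params(), seed = 11)
  expect_identical(a, b)
  expect_gt(sum(a$klass == "static"), 0)
  expect_gt(sum(a$klass == "dynamic"), 0)
  expect_true(all(a$streak[a$klass == "static"] < 0.5))
  expect_true(all(a$streak[a$klass == "dynamic"] > 5))
  # every excluded row carries a reason
  expect_true(all(!is.na(a$exclusion_reason[a$klass == "excluded"])))
})

test_that("first-saccade endpoint scatter matches the configured SD", {
  p <- sim_params(first_scatter_sd = 3, fixation_jitter_sd = 0)
  rec <- simulate_records(1000, p, seed = 23)
  scatter <- rec$dg1_az - p$first_gain * rec$t1e_az
  expect_lt(abs(sd(scatter) - 3) / 3, 0.15)
})

test_that("sessions interleave single and double steps at the stated mix", {
  sess <- simulate_session(400, sim_params(), seed = 31)
  n_single <- sum(sess$trial_table$kind == "single")
  # 56% single steps, within binomial error
  expect_lt(abs(n_single / 400 - 0.56), 3 * sqrt(0.56 * 0.44 / 400))
  # byte-identical trial table under the same seed
  sess2 <- simulate_session(400, sim_params(), seed = 31)
  expect_identical(sess$trial_table, sess2$trial_table)
  # T2 onset respects the flash/gap chain
  dbl <- sess$trial_table[sess$trial_table$kind == "double", ]
  expect_true(all(dbl$t2_on_ms >= dbl$t1_on_ms + dbl$t1_dur_ms + dbl$gap2_ms - 1e-9))
})
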
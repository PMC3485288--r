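test_that("polar to double-pole matches convention and the 3D oracle", {
  expect_equal(polar_to_double_pole(20, 0),
               tibble::tibble(azimuth = 20, elevation = 0))
  expect_equal(polar_to_double_pole(0, 217),
               tibble::tibble(azimuth = 0, elevation = 0))
  # oracle agreement over a grid of eccentricities and directions
  grid <- tidyr::expand_grid(r = c(5, 9, 14, 20, 27, 35, 43, 60, 89),
                             phi = seq(0, 345, by = 15))
  got <- polar_to_double_pole(grid$r, grid$phi)
  want <- t(mapply(oracle_double_pole, grid$r, grid$phi))
  expect_lt(max(abs(got$azimuth - want[, "azimuth"])), 1e-9)
  expect_lt(max(abs(got$elevation - want[, "elevation"])), 1e-9)
  expect_error(polar_to_double_pole(90, 0), "90")
  expect_error(polar_to_double_pole(-1, 0), "90")
})

test_that("eccentricity is preserved by the double-pole transform", {
  web <- make_target_web()
  ecc <- mapply(great_circle_deg, web$azimuth, web$elevation, 0, 0)
  expect_lt(max(abs(ecc - web$r)), 1e-9)
})

test_that("double-pole to polar inverts the forward transform", {
  expect_equal(double_pole_to_polar(20, 0), tibble::tibble(r = 20, phi = 0))
  expect_equal(double_pole_to_polar(0, 0), tibble::tibble(r = 0, phi = 0))
  withr::with_seed(21, {
    r <- runif(1000, 0, 89)
    phi <- runif(1000, 0, 360)
  })
  fwd <- polar_to_double_pole(r, phi)
  back <- double_pole_to_polar(fwd$azimuth, fwd$elevation)
  fwd2 <- polar_to_double_pole(back$r, back$phi)
  expect_lt(max(abs(fwd2$azimuth - fwd$azimuth)), 1e-9)
  expect_lt(max(abs(fwd2$elevation - fwd$elevation)), 1e-9)
  expect_lt(max(abs(back$r - r)), 1e-9)
  expect_error(double_pole_to_polar(80, 80), "gamut")
})

test_that("localization error is the signed displacement minus target", {
  expect_equal(localization_error(10, 0, 12, 0),
               tibble::tibble(error_azimuth = -2, error_elevation = 0))
  expect_equal(localization_error(-8, 4, -10, 5),
               tibble::tibble(error_azimuth = 2, error_elevation = 1))
  # zero error iff displacement equals target, in both components
  withr::with_seed(5, {
    dg <- matrix(rnorm(200), ncol = 2)
    te <- matrix(rnorm(200), ncol = 2)
  })
  err <- localization_error(dg[, 1], dg[, 2], te[, 1], te[, 2])
  zero <- err$error_azimuth == 0 & err$error_elevation == 0
  same <- dg[, 1] == te[, 1] & dg[, 2] == te[, 2]
  expect_equal(zero, same)
  err0 <- localization_error(3, -2, 3, -2)
  expect_equal(unlist(err0), c(error_azimuth = 0, error_elevation = 0))
})

test_that("elevation error is reported down-positive", {
  # response ended 2 deg above the target: screen-signed error is negative
  err <- localization_error(0, 7, 0, 5)
  expect_equal(err$error_elevation, -2)
})

test_that("under-/overshoot conversion makes undershoots negative", {
  # rightward movement stopping short: error negative already
  uo <- to_under_overshoot(-2, 0, 12, 0)
  expect_equal(uo$under_over_azimuth, -2)
  # leftward movement stopping short ends right of target: sign inverted
  err <- localization_error(-8, 0, -10, 0)
  uo <- to_under_overshoot(err$error_azimuth, 0, -10, 0)
  expect_equal(uo$under_over_azimuth, -2)
  # overshoot in any direction comes out positive
  err_r <- localization_error(14, 0, 12, 0)
  err_l <- localization_error(-14, 0, -12, 0)
  expect_gt(to_under_overshoot(err_r$error_azimuth, 0, 12, 0)$under_over_azimuth, 0)
  expect_gt(to_under_overshoot(err_l$error_azimuth, 0, -12, 0)$under_over_azimuth, 0)
  # upward undershoot: ends below target
  err_u <- localization_error(0, 8, 0, 10)
  uo_u <- to_under_overshoot(0, err_u$error_elevation, 0, 10)
  expect_equal(uo_u$under_over_elevation, -2)
  # degenerate component flagged and passed through
  uo_d <- to_under_overshoot(1.5, 0, 0, 5)
  expect_true(uo_d$degenerate_azimuth)
  expect_equal(uo_d$under_over_azimuth, 1.5)
})

test_that("retinal trajectory follows TE = TS - G and streaks add up", {
  flat <- tibble::tibble(time_ms = 0:100, azimuth = 0, elevation = 0)
  rt <- retinal_trajectory(flat, 30, -10, c(0, 100))
  expect_true(all(rt$te_azimuth == 30 & rt$te_elevation == -10))
  expect_equal(streak_amplitude(rt), 0)
  # gaze sweeping 15 deg rightward shifts the retinal azimuth down by 15
  g <- tibble::tibble(time_ms = 0:150, azimuth = seq(0, 15, length.out = 151),
                      elevation = 0)
  rt <- retinal_trajectory(g, 30, 0, c(0, 150))
  expect_equal(rt$te_azimuth[1] - rt$te_azimuth[151], 15)
  # streak length equals the gaze path length over the window
  path <- sum(sqrt(diff(g$azimuth)^2 + diff(g$elevation)^2))
  expect_equal(streak_amplitude(rt), path)
  expect_error(retinal_trajectory(g, 0, 0, c(-10, 50)), "support")
})

test_that("streak amplitude is a path length, not a net displacement", {
  expect_equal(streak_amplitude(c(0, 20), c(0, 0)), 20)
  expect_equal(streak_amplitude(c(0, 5, 0), c(0, 0, 0)), 10)
  expect_equal(streak_amplitude(3, 4), 0)  # single sample
})

test_that("error decomposition projects onto the first-shift axis", {
  expect_equal(decompose_error(2, 3, 10, 0),
               tibble::tibble(parallel = 2, perpendicular = 3))
  expect_equal(decompose_error(2, 3, 0, 10)$parallel, 3)
  d45 <- decompose_error(1, 1, 5, 5)
  expect_equal(d45$parallel, sqrt(2))
  expect_equal(d45$perpendicular, 0)
  # norm preservation over random cases
  withr::with_seed(9, {
    e <- matrix(rnorm(400), ncol = 2)
    v <- matrix(rnorm(400), ncol = 2)
  })
  dec <- decompose_error(e[, 1], e[, 2], v[, 1], v[, 2])
  expect_lt(max(abs(dec$parallel^2 + dec$perpendicular^2 -
                      (e[, 1]^2 + e[, 2]^2))), 1e-9)
  expect_error(decompose_error(1, 1, 0, 0), "zero")
})
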
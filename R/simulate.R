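#' Simulation and analysis parameters
#'
#' Collects every tunable constant of the synthetic-session generator and the
#' analysis defaults in one place. Defaults reproduce the experimental
#' conditions of the head-unrestrained double-step paradigm: 1017.25 Hz
#' sampling, first-saccade gain ~0.9 (the typical ~10% undershoot),
#' per-component endpoint scatter of 3 deg, fixation jitter 0.5 deg inside
#' the fixation window, and a variable head contribution that is recruited
#' above a ~10 deg amplitude threshold and continues after the gaze shift
#' ends, during which the vestibulo-ocular reflex (gain 1) holds gaze
#' stationary.
#'
#' @param sample_rate Sampling rate, Hz.
#' @param ms_intercept,ms_slope Gaze main sequence: duration (ms) =
#'   `ms_intercept + ms_slope * amplitude` (deg).
#' @param profile Velocity-profile tag; `"raised_cosine"` is the only
#'   built-in shape.
#' @param first_gain First-saccade gain (dimensionless, in (0, 1.2]).
#' @param first_scatter_sd First-saccade endpoint scatter SD, deg/component.
#' @param endpoint_sd Second-response endpoint scatter SD, deg/component.
#' @param fixation_jitter_sd Fixation-position jitter SD, deg/component.
#' @param head_lag Head-movement onset lag behind gaze onset, ms.
#' @param head_contrib_slope,head_contrib_threshold Head amplitude
#'   recruitment: head amplitude = `max(0, slope * (A - threshold))` deg.
#' @param head_contrib_sd Trial-to-trial SD of the head contribution, deg
#'   (head contributions vary considerably between trials).
#' @param head_ms_intercept,head_ms_slope Head main sequence (slower than
#'   gaze), ms and ms/deg.
#' @param head_gain_hme Gain of the second head displacement on the
#'   head-centered motor error HME2 (dimensionless; record-level generator).
#' @param head_gain_total Fraction of HME2 the trace-level second head
#'   movement eventually covers; the displacement accrued before gaze-shift
#'   offset (the measured dH2) is a further profile-dependent fraction.
#' @param head_noise_sd Noise SD of the second head displacement,
#'   deg/component.
#' @param first_latency_mean,first_latency_sd First-saccade latency (ms)
#'   after T1 onset, Gaussian (truncated below at 60 ms).
#' @param second_latency_median,second_latency_sdlog Second-saccade latency
#'   after T2 onset: lognormal median (ms) and sdlog.
#' @param vor_gain Vestibulo-ocular reflex gain in the post-gaze-shift phase;
#'   1 means gaze is held perfectly stationary while the head completes its
#'   movement.
#' @param model Ground-truth updating model for second responses: one of
#'   `"NC"`, `"VU"`, `"SFB"`, `"DFB"`.
#' @param single_frac Fraction of single-step trials in a session.
#' @param p_skip_t1 Probability that a double-step response skips T1 and goes
#'   directly to T2 with a single saccade (such trials are discarded by the
#'   analysis).
#' @param onset_speed,offset_speed Saccade-detection thresholds, deg/s.
#' @param static_max,dynamic_min Static/dynamic classification criteria:
#'   gaze movement during the T2 flash < `static_max` deg is static,
#'   > `dynamic_min` deg is dynamic, in between is excluded.
#' @param head_onset_speed Head-movement onset detection threshold, deg/s.
#' @param n_boot Default number of bootstrap resamples.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(sample_rate = 1017.25,
                       ms_intercept = 20, ms_slope = 1.5,
                       profile = "raised_cosine",
                       first_gain = 0.9,
                       first_scatter_sd = 3,
                       endpoint_sd = 3,
                       fixation_jitter_sd = 0.5,
                       head_lag = 30,
                       head_contrib_slope = 0.4,
                       head_contrib_threshold = 10,
                       head_contrib_sd = 3,
                       head_ms_intercept = 150, head_ms_slope = 3,
                       head_gain_hme = 0.25,
                       head_gain_total = 0.5,
                       head_noise_sd = 1,
                       first_latency_mean = 141, first_latency_sd = 30,
                       second_latency_median = 180,
                       second_latency_sdlog = 0.3,
                       vor_gain = 1,
                       model = "DFB",
                       single_frac = 0.56,
                       p_skip_t1 = 0.15,
                       onset_speed = 100, offset_speed = 70,
                       static_max = 0.5, dynamic_min = 5,
                       head_onset_speed = 20,
                       n_boot = 1000) {
  stopifnot(sample_rate > 0, first_gain > 0, first_gain <= 1.2,
            onset_speed > offset_speed, offset_speed > 0,
            static_max < dynamic_min)
  model <- match.arg(model, c("NC", "VU", "SFB", "DFB"))
  p <- as.list(environment())
  class(p) <- "sim_params"
  p
}

#' The 85-point target web
#'
#' Seven eccentricity rings (5, 9, 14, 20, 27, 35, 43 deg) crossed with
#' twelve directions (0, 30, ..., 330 deg) plus the central straight-ahead
#' target: 85 targets in total.
#'
#' @return A tibble with columns `r`, `phi`, `azimuth`, `elevation`.
#' @export
make_target_web <- function() {
  rings <- c(5, 9, 14, 20, 27, 35, 43)
  spokes <- seq(0, 330, by = 30)
  grid <- tidyr::expand_grid(r = rings, phi = spokes)
  grid <- dplyr::bind_rows(tibble::tibble(r = 0, phi = 0), grid)
  dplyr::bind_cols(grid, polar_to_double_pole(grid$r, grid$phi))
}

#' Double-step target configurations
#'
#' Cross product of candidate first-target (T1) and second-target (T2)
#' positions. The default places T1 on the horizontal meridian (first
#' saccades are then mainly horizontal, giving the azimuth component the
#' discriminative variation) and spreads T2 over three rings and all twelve
#' spokes, yielding 144 unique configurations. Fixation is at the center.
#'
#' @param t1 Tibble of T1 candidates with columns `azimuth`, `elevation`.
#' @param t2 Tibble of T2 candidates with columns `azimuth`, `elevation`.
#' @return A tibble with one row per configuration: `fix_az`, `fix_el`,
#'   `t1_az`, `t1_el`, `t2_az`, `t2_el`.
#' @export
make_double_step_set <- function(t1 = NULL, t2 = NULL) {
  if (is.null(t1)) {
    t1 <- polar_to_double_pole(rep(c(20, 27), each = 2), rep(c(0, 180), 2))
  }
  if (is.null(t2)) {
    grid <- tidyr::expand_grid(r = c(9, 14, 20), phi = seq(0, 330, by = 30))
    t2 <- polar_to_double_pole(grid$r, grid$phi)
  }
  if (nrow(t1) == 0 || nrow(t2) == 0) {
    stop("empty T1 or T2 candidate set", call. = FALSE)
  }
  out <- tidyr::expand_grid(
    t1_idx = seq_len(nrow(t1)),
    t2_idx = seq_len(nrow(t2))
  )
  tibble::tibble(
    fix_az = 0, fix_el = 0,
    t1_az = t1$azimuth[out$t1_idx], t1_el = t1$elevation[out$t1_idx],
    t2_az = t2$azimuth[out$t2_idx], t2_el = t2$elevation[out$t2_idx]
  )
}

#' Sample double-step trial timing
#'
#' Draws the stimulus timing of `n` trials: fixation duration uniform in
#' [600, 1100] ms, a first gap uniform in [10, 70] ms, flash durations drawn
#' from the integers 10..30 ms, and a second gap uniform in [90, 140] ms.
#' All values are integer ms.
#'
#' @param n Number of trials.
#' @return A tibble with columns `fixation_dur_ms`, `gap1_ms`, `t1_dur_ms`,
#'   `gap2_ms`, `t2_dur_ms`.
#' @export
sample_trial_timing <- function(n) {
  tibble::tibble(
    fixation_dur_ms = sample(600:1100, n, replace = TRUE),
    gap1_ms         = sample(10:70, n, replace = TRUE),
    t1_dur_ms       = sample(10:30, n, replace = TRUE),
    gap2_ms         = sample(90:140, n, replace = TRUE),
    t2_dur_ms       = sample(10:30, n, replace = TRUE)
  )
}

# Raised-cosine movement profile: fraction of displacement completed at
# normalized time tau in [0, 1]. Velocity (1 - cos(2 pi tau)) is smooth and
# unimodal with peak speed 2 * amplitude / duration.
profile_position <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau - sin(2 * pi * tau) / (2 * pi)
}

profile_peak_speed <- function(amplitude, duration_ms) {
  2 * amplitude / duration_ms * 1000  # deg/s
}

main_sequence_duration <- function(amplitude, p) {
  p$ms_intercept + p$ms_slope * amplitude
}

head_contribution <- function(amplitude, p, noise = TRUE) {
  base <- pmax(0, p$head_contrib_slope * (amplitude - p$head_contrib_threshold))
  if (noise && p$head_contrib_sd > 0) {
    base <- pmax(0, base + stats::rnorm(length(base), 0, p$head_contrib_sd))
  }
  base
}

#' Second-response displacement under a ground-truth updating model
#'
#' Computes the second gaze-shift displacement that each conceptual updating
#' model would produce, given the per-trial retinal and motor signals, plus
#' Gaussian endpoint noise:
#' * `NC` (no compensation): `T2E` — the raw retinal error, no updating;
#' * `VU` (visual feedforward updating): `T2E - T1E`;
#' * `SFB` (static motor feedback): `T2E - dG1`;
#' * `DFB` (dynamic motor feedback): `T2E - GME1`, equivalently
#'   `(T2E + G1) - G2` via gaze-position feedback.
#'
#' All inputs are component pairs in the double-pole chart; vectors recycle.
#'
#' @param model Model tag, one of `"NC"`, `"VU"`, `"SFB"`, `"DFB"`.
#' @param t2e_az,t2e_el Retinal location of T2 at its onset (deg).
#' @param t1e_az,t1e_el Retinal location of T1 at its onset (deg).
#' @param dg1_az,dg1_el Full first gaze-displacement vector (deg).
#' @param gme1_az,gme1_el Remaining gaze motor error at T2 onset,
#'   `G2 - G1` (deg).
#' @param params A [sim_params()] list (supplies `endpoint_sd`).
#' @param noise Add endpoint noise? Set `FALSE` for exact model output.
#' @return A tibble with columns `dg2_az`, `dg2_el`.
#' @export
generate_second_response <- function(model, t2e_az, t2e_el,
                                     t1e_az = NULL, t1e_el = NULL,
                                     dg1_az = NULL, dg1_el = NULL,
                                     gme1_az = NULL, gme1_el = NULL,
                                     params = sim_params(), noise = TRUE) {
  model <- match.arg(model, c("NC", "VU", "SFB", "DFB"))
  d <- switch(model,
    NC  = list(az = t2e_az, el = t2e_el),
    VU  = list(az = t2e_az - t1e_az, el = t2e_el - t1e_el),
    SFB = list(az = t2e_az - dg1_az, el = t2e_el - dg1_el),
    DFB = list(az = t2e_az - gme1_az, el = t2e_el - gme1_el)
  )
  n <- length(d$az)
  if (noise && params$endpoint_sd > 0) {
    d$az <- d$az + stats::rnorm(n, 0, params$endpoint_sd)
    d$el <- d$el + stats::rnorm(n, 0, params$endpoint_sd)
  }
  tibble::tibble(dg2_az = d$az, dg2_el = d$el)
}

#' Head displacement of the second gaze shift
#'
#' The simulated head movement accompanying the second gaze shift is driven
#' by the head-centered motor error alone (goal-directed head control):
#' displacement = `head_gain_hme * HME2 + noise`, with zero weight on the
#' gaze motor error.
#'
#' @param hme2_az,hme2_el Head-centered motor error components (deg).
#' @param params A [sim_params()] list.
#' @param noise Add Gaussian noise (`head_noise_sd`)?
#' @return A tibble with columns `dh2_az`, `dh2_el`.
#' @export
generate_head_response <- function(hme2_az, hme2_el, params = sim_params(),
                                   noise = TRUE) {
  n <- length(hme2_az)
  dh_az <- params$head_gain_hme * hme2_az
  dh_el <- params$head_gain_hme * hme2_el
  if (noise && params$head_noise_sd > 0) {
    dh_az <- dh_az + stats::rnorm(n, 0, params$head_noise_sd)
    dh_el <- dh_el + stats::rnorm(n, 0, params$head_noise_sd)
  }
  tibble::tibble(dh2_az = dh_az, dh2_el = dh_el)
}

#' Simulate one eye-head gaze shift with traces
#'
#' Generates uniformly sampled gaze and head traces for a single gaze shift
#' from `start` towards `goal`. Gaze follows a straight chart path with a
#' raised-cosine speed profile whose duration obeys the amplitude-duration
#' main sequence. The head starts `head_lag` ms later with a recruited
#' amplitude and a slower profile, and typically continues after the gaze
#' shift ends; with `vor_gain = 1` gaze is held exactly stationary during
#' that phase (the vestibulo-ocular reflex counter-rotates the eye). The
#' eye-in-head trace is the (linearized) difference gaze minus head.
#'
#' @param start_az,start_el,goal_az,goal_el Start/goal directions (deg).
#' @param params A [sim_params()] list.
#' @param noise Apply first-saccade gain scatter? `FALSE` gives
#'   gain-and-noise-free motion exactly onto the goal when
#'   `first_gain = 1`.
#' @param pre_ms,post_ms Fixation padding before onset / after the head
#'   finishes, ms.
#' @return A list with elements `gaze` and `head` (tibbles: `time_ms`,
#'   `azimuth`, `elevation`) and `events` (list: `gaze_onset`, `gaze_offset`,
#'   `head_onset`, `head_offset`, `amplitude`, `dg_az`, `dg_el`).
#' @export
simulate_gaze_shift <- function(start_az, start_el, goal_az, goal_el,
                                params = sim_params(), noise = TRUE,
                                pre_ms = 100, post_ms = 200) {
  dg_az <- params$first_gain * (goal_az - start_az)
  dg_el <- params$first_gain * (goal_el - start_el)
  if (noise && params$first_scatter_sd > 0) {
    dg_az <- dg_az + stats::rnorm(1, 0, params$first_scatter_sd)
    dg_el <- dg_el + stats::rnorm(1, 0, params$first_scatter_sd)
  }
  amp <- sqrt(dg_az^2 + dg_el^2)
  if (amp >= 90) stop("gaze-shift amplitude must be < 90 deg", call. = FALSE)
  dur <- main_sequence_duration(amp, params)
  hamp <- head_contribution(amp, params, noise = noise)
  hdur <- params$head_ms_intercept + params$head_ms_slope * hamp
  h_on <- pre_ms + params$head_lag
  total <- max(pre_ms + dur, h_on + hdur) + post_ms
  dt <- 1000 / params$sample_rate
  t <- seq(0, total, by = dt)
  s <- if (amp > 0) profile_position((t - pre_ms) / dur) else rep(0, length(t))
  gaze <- tibble::tibble(
    time_ms  = t,
    azimuth  = start_az + s * dg_az,
    elevation = start_el + s * dg_el
  )
  u_az <- if (amp > 0) dg_az / amp else 0
  u_el <- if (amp > 0) dg_el / amp else 0
  sh <- if (hamp > 0) profile_position((t - h_on) / hdur) else rep(0, length(t))
  head <- tibble::tibble(
    time_ms  = t,
    azimuth  = sh * hamp * u_az,
    elevation = sh * hamp * u_el
  )
  events <- if (amp > 0) {
    list(gaze_onset = pre_ms, gaze_offset = pre_ms + dur,
         head_onset = if (hamp > 0) h_on else NA_real_,
         head_offset = if (hamp > 0) h_on + hdur else NA_real_,
         amplitude = amp, dg_az = dg_az, dg_el = dg_el)
  } else {
    NULL
  }
  list(gaze = gaze, head = head, events = events)
}

# closed-form per-trial kinematic quantities for a double-step trial,
# shared by the trace-level and record-level generators. Times are relative
# to T1 onset. Returns the signals each updating model would see.
double_step_kinematics <- function(cfg, timing, params, noise = TRUE,
                                   t2_timing = c("natural", "static",
                                                 "dynamic")) {
  t2_timing <- match.arg(t2_timing)
  n <- nrow(cfg)
  jit <- if (noise && params$fixation_jitter_sd > 0) {
    matrix(stats::rnorm(2 * n, 0, params$fixation_jitter_sd), ncol = 2)
  } else {
    matrix(0, n, 2)
  }
  fix_az <- cfg$fix_az + jit[, 1]
  fix_el <- cfg$fix_el + jit[, 2]
  t1e_az <- cfg$t1_az - fix_az
  t1e_el <- cfg$t1_el - fix_el
  dg1_az <- params$first_gain * t1e_az
  dg1_el <- params$first_gain * t1e_el
  if (noise && params$first_scatter_sd > 0) {
    dg1_az <- dg1_az + stats::rnorm(n, 0, params$first_scatter_sd)
    dg1_el <- dg1_el + stats::rnorm(n, 0, params$first_scatter_sd)
  }
  amp1 <- sqrt(dg1_az^2 + dg1_el^2)
  dur1 <- main_sequence_duration(amp1, params)
  lat1 <- pmax(60, stats::rnorm(n, params$first_latency_mean,
                                params$first_latency_sd))
  t2_on <- switch(t2_timing,
    natural = timing$t1_dur_ms + timing$gap2_ms,
    # flash completes comfortably before the first-saccade onset
    static  = pmax(5, lat1 - timing$t2_dur_ms - stats::runif(n, 10, 60)),
    # flash begins midflight of the first gaze shift
    dynamic = lat1 + stats::runif(n, 0.1, 0.6) * dur1
  )
  t2_off <- t2_on + timing$t2_dur_ms
  tau_on <- (t2_on - lat1) / dur1
  tau_off <- (t2_off - lat1) / dur1
  f_on <- profile_position(tau_on)
  f_off <- profile_position(tau_off)
  g1_az <- fix_az + f_on * dg1_az
  g1_el <- fix_el + f_on * dg1_el
  g2_az <- fix_az + dg1_az   # first shift complete at second-saccade onset
  g2_el <- fix_el + dg1_el
  streak <- (f_off - f_on) * amp1
  tibble::tibble(
    fix_az = fix_az, fix_el = fix_el,
    t1e_az = t1e_az, t1e_el = t1e_el,
    dg1_az = dg1_az, dg1_el = dg1_el,
    amp1 = amp1, dur1 = dur1, lat1 = lat1,
    t2_on = t2_on, t2_off = t2_off,
    g1_az = g1_az, g1_el = g1_el,
    g2_az = g2_az, g2_el = g2_el,
    gme1_az = g2_az - g1_az, gme1_el = g2_el - g1_el,
    t2e_az = cfg$t2_az - g1_az, t2e_el = cfg$t2_el - g1_el,
    gme2_az = cfg$t2_az - g2_az, gme2_el = cfg$t2_el - g2_el,
    streak = streak,
    delay_ms = t2_on - lat1,
    flash_dur_ms = timing$t2_dur_ms
  )
}

classify_streak <- function(streak, params) {
  dplyr::case_when(
    streak < params$static_max ~ "static",
    streak > params$dynamic_min ~ "dynamic",
    TRUE ~ "intermediate"
  )
}

#' Simulate a table of double-step trial records
#'
#' Record-level synthetic generator: evaluates the same kinematic model as
#' the trace-level simulator in closed form (raised-cosine profile,
#' main-sequence durations, first-saccade gain and scatter, fixation jitter)
#' and produces one analysis-ready record per double-step trial, with the
#' second response generated under the selected ground-truth updating model
#' and the head response driven by the head motor error. Used for the
#' statistical recovery experiments, where thousands of trials are needed.
#'
#' Trials whose T2 flash outlasts the first gaze shift are marked excluded
#' (`"visual_feedback"`), mirroring the analysis rule; trials with a flash
#' streak between the static and dynamic criteria are `"intermediate"`.
#'
#' @param n Number of double-step trials.
#' @param params A [sim_params()] list; `params$model` selects the
#'   ground-truth updating model.
#' @param seed Optional integer seed (session-level; every draw derives
#'   from it).
#' @param t2_timing `"natural"` draws T2 timing from the paradigm's gap
#'   structure, producing a static/dynamic mixture; `"static"` and
#'   `"dynamic"` force the respective condition.
#' @param noise Logical; `FALSE` switches off every stochastic component
#'   (jitter, scatter, endpoint and head noise) and fixes latencies at their
#'   central values.
#' @param config Double-step configuration table from
#'   [make_double_step_set()].
#' @return A tibble with one row per trial: target/retinal/motor-error
#'   components, second gaze and head displacements, `streak`, `delay_ms`,
#'   `flash_dur_ms`, `klass`, and `exclusion_reason`.
#' @export
simulate_records <- function(n, params = sim_params(), seed = NULL,
                             t2_timing = c("natural", "static", "dynamic"),
                             noise = TRUE,
                             config = make_double_step_set()) {
  t2_timing <- match.arg(t2_timing)
  if (!is.null(seed)) withr::local_seed(seed)
  p <- params
  if (!noise) {
    p$fixation_jitter_sd <- 0
    p$first_scatter_sd <- 0
    p$endpoint_sd <- 0
    p$head_noise_sd <- 0
    p$head_contrib_sd <- 0
    p$first_latency_sd <- 0
  }
  cfg <- config[sample.int(nrow(config), n, replace = TRUE), ]
  timing <- sample_trial_timing(n)
  k <- double_step_kinematics(cfg, timing, p, noise = noise,
                              t2_timing = t2_timing)
  dg2 <- generate_second_response(p$model,
                                  k$t2e_az, k$t2e_el,
                                  k$t1e_az, k$t1e_el,
                                  k$dg1_az, k$dg1_el,
                                  k$gme1_az, k$gme1_el,
                                  params = p, noise = noise)
  # head position at the second head-movement onset: the recruited first
  # head contribution (along the first gaze shift) has been completed
  h1_amp <- head_contribution(k$amp1, p, noise = noise)
  u_az <- ifelse(k$amp1 > 0, k$dg1_az / k$amp1, 0)
  u_el <- ifelse(k$amp1 > 0, k$dg1_el / k$amp1, 0)
  h_az <- h1_amp * u_az
  h_el <- h1_amp * u_el
  hme2_az <- cfg$t2_az - h_az
  hme2_el <- cfg$t2_el - h_el
  dh2 <- generate_head_response(hme2_az, hme2_el, params = p, noise = noise)
  first_offset <- k$lat1 + k$dur1
  # a flash outlasting the first gaze shift means direct visual feedback
  excluded <- k$t2_off > first_offset
  klass <- classify_streak(k$streak, p)
  reason <- rep(NA_character_, n)
  reason[klass == "intermediate"] <- "intermediate"
  reason[excluded] <- "visual_feedback"
  klass[klass == "intermediate" | excluded] <- "excluded"
  tibble::tibble(
    trial_id = seq_len(n),
    t1_az = cfg$t1_az, t1_el = cfg$t1_el,
    t2_az = cfg$t2_az, t2_el = cfg$t2_el,
    t1e_az = k$t1e_az, t1e_el = k$t1e_el,
    t2e_az = k$t2e_az, t2e_el = k$t2e_el,
    dg1_az = k$dg1_az, dg1_el = k$dg1_el,
    g1_az = k$g1_az, g1_el = k$g1_el,
    g2_az = k$g2_az, g2_el = k$g2_el,
    gme1_az = k$gme1_az, gme1_el = k$gme1_el,
    dg2_az = dg2$dg2_az, dg2_el = dg2$dg2_el,
    gme2_az = k$gme2_az, gme2_el = k$gme2_el,
    hme2_az = hme2_az, hme2_el = hme2_el,
    dh2_az = dh2$dh2_az, dh2_el = dh2$dh2_el,
    streak = k$streak,
    delay_ms = k$delay_ms,
    flash_dur_ms = k$flash_dur_ms,
    klass = klass,
    exclusion_reason = reason
  )
}

# build the gaze and head traces of one trial from its closed-form
# kinematics. Returns a tibble time_ms, gaze_az, gaze_el, head_az, head_el
# plus ground-truth event times (all relative to trial start).
build_trial_traces <- function(kin, dg2_az, dg2_el, t1_on, params) {
  p <- params
  dt <- 1000 / p$sample_rate
  on1 <- t1_on + kin$lat1
  off1 <- on1 + kin$dur1
  amp2 <- sqrt(dg2_az^2 + dg2_el^2)
  dur2 <- main_sequence_duration(amp2, p)
  # second-saccade onset: lognormal latency after T2 onset, but never before
  # the first shift has ended (plus a small refractory interval)
  lat2 <- stats::rlnorm(1, log(p$second_latency_median), p$second_latency_sdlog)
  on2 <- max(t1_on + kin$t2_on + lat2, off1 + 20)
  off2 <- on2 + dur2
  # head: first movement recruited along the first gaze shift; second
  # movement delivers the head displacement during the second gaze shift
  h1_amp <- head_contribution(kin$amp1, p, noise = p$head_contrib_sd > 0)
  u1_az <- if (kin$amp1 > 0) kin$dg1_az / kin$amp1 else 0
  u1_el <- if (kin$amp1 > 0) kin$dg1_el / kin$amp1 else 0
  h_on1 <- on1 + p$head_lag
  h_dur1 <- p$head_ms_intercept + p$head_ms_slope * h1_amp
  # head position when the second head movement starts (the first head
  # movement may still be underway)
  sh1_on2 <- profile_position((on2 - h_on1) / h_dur1)
  hme2_az <- kin$t2_s_az - sh1_on2 * h1_amp * u1_az
  hme2_el <- kin$t2_s_el - sh1_on2 * h1_amp * u1_el
  # the second head movement heads for a fraction head_gain_total of the
  # head motor error and outlasts the gaze shift; the displacement accrued
  # while gaze is still shifting (the measured dH2) is a further fraction
  h2_az <- p$head_gain_total * hme2_az
  h2_el <- p$head_gain_total * hme2_el
  if (p$head_noise_sd > 0) {
    h2_az <- h2_az + stats::rnorm(1, 0, p$head_noise_sd)
    h2_el <- h2_el + stats::rnorm(1, 0, p$head_noise_sd)
  }
  h2_amp <- sqrt(h2_az^2 + h2_el^2)
  h_dur2 <- p$head_ms_intercept + p$head_ms_slope * h2_amp
  frac2 <- profile_position((off2 - on2) / h_dur2)
  total <- max(off2, h_on1 + h_dur1, on2 + h_dur2) + 300
  t <- seq(0, total, by = dt)
  s1 <- profile_position((t - on1) / kin$dur1)
  s2 <- profile_position((t - on2) / dur2)
  gaze_az <- kin$fix_az + s1 * kin$dg1_az + s2 * dg2_az
  gaze_el <- kin$fix_el + s1 * kin$dg1_el + s2 * dg2_el
  sh1 <- profile_position((t - h_on1) / h_dur1)
  sh2 <- profile_position((t - on2) / h_dur2)
  head_az <- sh1 * h1_amp * u1_az + sh2 * h2_az
  head_el <- sh1 * h1_amp * u1_el + sh2 * h2_el
  list(
    traces = tibble::tibble(time_ms = t,
                            gaze_az = gaze_az, gaze_el = gaze_el,
                            head_az = head_az, head_el = head_el),
    truth = list(first_onset = on1, first_offset = off1,
                 second_onset = on2, second_offset = off2,
                 head2_onset = on2,
                 dg2_az = dg2_az, dg2_el = dg2_el,
                 hme2_az = hme2_az, hme2_el = hme2_el,
                 # measured head displacement in the gaze-shift window also
                 # carries any unfinished first head movement
                 dh2_az = frac2 * h2_az +
                   (profile_position((off2 - h_on1) / h_dur1) - sh1_on2) *
                   h1_amp * u1_az,
                 dh2_el = frac2 * h2_el +
                   (profile_position((off2 - h_on1) / h_dur1) - sh1_on2) *
                   h1_amp * u1_el)
  )
}

#' Simulate a full session with gaze and head traces
#'
#' Generates an interleaved session of single- and double-step trials at the
#' trace level: full 2D gaze and head position signals sampled at
#' `params$sample_rate`, with first responses toward T1 (gain
#' `first_gain`, endpoint scatter), second responses generated under the
#' ground-truth updating model `params$model`, head movements recruited
#' above the amplitude threshold and outlasting the gaze shift, and gaze held
#' stationary by the VOR after each gaze-shift offset. A fraction
#' `p_skip_t1` of double-step trials contains a single saccade directly to
#' T2 (these exercise the analysis's rejection path).
#'
#' @param n_trials Number of trials in the session.
#' @param params A [sim_params()] list.
#' @param seed Session-level integer seed; every stochastic draw derives
#'   from it.
#' @param config Double-step configuration table.
#' @return An object of class `gaze_session`: a list with
#'   * `trial_table`: one row per trial (targets, timing, kind, absolute T1
#'     and T2 onset times);
#'   * `traces`: named list (by trial id) of trace tibbles with columns
#'     `time_ms`, `gaze_az`, `gaze_el`, `head_az`, `head_el`;
#'   * `truth`: tibble of ground-truth event times and model inputs per
#'     trial;
#'   * `params`: the generating parameters.
#' @export
simulate_session <- function(n_trials, params = sim_params(), seed = NULL,
                             config = make_double_step_set()) {
  if (n_trials <= 0) stop("n_trials must be positive", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  p <- params
  kind <- ifelse(stats::runif(n_trials) < p$single_frac, "single", "double")
  web <- make_target_web()
  timing <- sample_trial_timing(n_trials)
  cfg_idx <- sample.int(nrow(config), n_trials, replace = TRUE)
  single_idx <- sample.int(nrow(web), n_trials, replace = TRUE)
  traces <- vector("list", n_trials)
  rows <- vector("list", n_trials)
  truths <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tm <- timing[i, ]
    t1_on <- tm$fixation_dur_ms + tm$gap1_ms
    if (kind[i] == "single") {
      tgt <- web[single_idx[i], ]
      cfg <- tibble::tibble(fix_az = 0, fix_el = 0,
                            t1_az = tgt$azimuth, t1_el = tgt$elevation,
                            t2_az = NA_real_, t2_el = NA_real_)
      kin <- double_step_kinematics(
        dplyr::mutate(cfg, t2_az = t1_az, t2_el = t1_el), tm, p,
        noise = TRUE, t2_timing = "natural")
      kin$t2_s_az <- NA_real_; kin$t2_s_el <- NA_real_
      # single-step: just the first response
      bt <- build_single_trace(kin, t1_on, p)
      rows[[i]] <- tibble::tibble(
        trial_id = i, kind = "single",
        fix_az = 0, fix_el = 0,
        t1_az = tgt$azimuth, t1_el = tgt$elevation,
        t2_az = NA_real_, t2_el = NA_real_,
        tm, t1_on_ms = t1_on, t2_on_ms = NA_real_, seed = i
      )
      traces[[i]] <- bt$traces
      truths[[i]] <- tibble::tibble(trial_id = i, kind = "single",
                                    first_onset = bt$truth$first_onset,
                                    first_offset = bt$truth$first_offset)
    } else {
      cfg <- config[cfg_idx[i], ]
      skip <- stats::runif(1) < p$p_skip_t1
      kin <- double_step_kinematics(cfg, tm, p, noise = TRUE,
                                    t2_timing = "natural")
      kin$t2_s_az <- cfg$t2_az; kin$t2_s_el <- cfg$t2_el
      if (skip) {
        # single saccade straight to T2: substitute the first movement
        kin$dg1_az <- p$first_gain * (cfg$t2_az - kin$fix_az)
        kin$dg1_el <- p$first_gain * (cfg$t2_el - kin$fix_el)
        kin$amp1 <- sqrt(kin$dg1_az^2 + kin$dg1_el^2)
        kin$dur1 <- main_sequence_duration(kin$amp1, p)
        bt <- build_single_trace(kin, t1_on, p)
        truths[[i]] <- tibble::tibble(trial_id = i, kind = "double_skip",
                                      first_onset = bt$truth$first_onset,
                                      first_offset = bt$truth$first_offset)
      } else {
        dg2 <- generate_second_response(p$model,
                                        kin$t2e_az, kin$t2e_el,
                                        kin$t1e_az, kin$t1e_el,
                                        kin$dg1_az, kin$dg1_el,
                                        kin$gme1_az, kin$gme1_el,
                                        params = p,
                                        noise = p$endpoint_sd > 0)
        bt <- build_trial_traces(kin, dg2$dg2_az, dg2$dg2_el, t1_on, p)
        truths[[i]] <- tibble::tibble(
          trial_id = i, kind = "double",
          first_onset = bt$truth$first_onset,
          first_offset = bt$truth$first_offset,
          second_onset = bt$truth$second_onset,
          second_offset = bt$truth$second_offset,
          t1e_az = kin$t1e_az, t1e_el = kin$t1e_el,
          t2e_az = kin$t2e_az, t2e_el = kin$t2e_el,
          dg1_az = kin$dg1_az, dg1_el = kin$dg1_el,
          g1_az = kin$g1_az, g1_el = kin$g1_el,
          g2_az = kin$g2_az, g2_el = kin$g2_el,
          gme1_az = kin$gme1_az, gme1_el = kin$gme1_el,
          dg2_az = dg2$dg2_az, dg2_el = dg2$dg2_el,
          hme2_az = bt$truth$hme2_az, hme2_el = bt$truth$hme2_el,
          dh2_az = bt$truth$dh2_az, dh2_el = bt$truth$dh2_el,
          streak = kin$streak
        )
      }
      rows[[i]] <- tibble::tibble(
        trial_id = i, kind = "double",
        fix_az = cfg$fix_az, fix_el = cfg$fix_el,
        t1_az = cfg$t1_az, t1_el = cfg$t1_el,
        t2_az = cfg$t2_az, t2_el = cfg$t2_el,
        tm, t1_on_ms = t1_on, t2_on_ms = t1_on + kin$t2_on, seed = i
      )
      traces[[i]] <- bt$traces
    }
  }
  out <- list(
    trial_table = dplyr::bind_rows(rows),
    traces = stats::setNames(traces, as.character(seq_len(n_trials))),
    truth = dplyr::bind_rows(truths),
    params = p
  )
  class(out) <- "gaze_session"
  out
}

# trace for a trial with a single (first) response only
build_single_trace <- function(kin, t1_on, params) {
  p <- params
  dt <- 1000 / p$sample_rate
  on1 <- t1_on + kin$lat1
  off1 <- on1 + kin$dur1
  h1_amp <- head_contribution(kin$amp1, p, noise = p$head_contrib_sd > 0)
  u1_az <- if (kin$amp1 > 0) kin$dg1_az / kin$amp1 else 0
  u1_el <- if (kin$amp1 > 0) kin$dg1_el / kin$amp1 else 0
  h_on1 <- on1 + p$head_lag
  h_dur1 <- p$head_ms_intercept + p$head_ms_slope * h1_amp
  total <- max(off1, h_on1 + h_dur1) + 300
  t <- seq(0, total, by = dt)
  s1 <- profile_position((t - on1) / kin$dur1)
  sh1 <- profile_position((t - h_on1) / h_dur1)
  list(
    traces = tibble::tibble(
      time_ms = t,
      gaze_az = kin$fix_az + s1 * kin$dg1_az,
      gaze_el = kin$fix_el + s1 * kin$dg1_el,
      head_az = sh1 * h1_amp * u1_az,
      head_el = sh1 * h1_amp * u1_el
    ),
    truth = list(first_onset = on1, first_offset = off1)
  )
}

#' @export
print.gaze_session <- function(x, ...) {
  tt <- x$trial_table
  cat("<gaze_session> ", nrow(tt), " trials (",
      sum(tt$kind == "single"), " single, ",
      sum(tt$kind == "double"), " double), model ",
      x$params$model, "\n", sep = "")
  invisible(x)
}
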
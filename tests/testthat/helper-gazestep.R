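# shared fixtures for the suite: noise-free parameter sets and a 3D
# unit-vector oracle for the double-pole transform

params_noise_free <- function(...) {
  sim_params(first_scatter_sd = 0, endpoint_sd = 0, fixation_jitter_sd = 0,
             head_noise_sd = 0, head_contrib_sd = 0, p_skip_t1 = 0, ...)
}

# independent geometric oracle: embed the polar target as a 3D unit vector
# (forward, right, up) and read azimuth/elevation off the components
oracle_double_pole <- function(r, phi) {
  rr <- r * pi / 180
  pp <- phi * pi / 180
  right <- sin(rr) * cos(pp)
  up <- sin(rr) * sin(pp)
  c(azimuth = asin(right) * 180 / pi, elevation = asin(up) * 180 / pi)
}

# great-circle angle between two double-pole directions, via 3D vectors
great_circle_deg <- function(az1, el1, az2, el2) {
  vec <- function(az, el) {
    a <- az * pi / 180
    e <- el * pi / 180
    right <- sin(a)
    up <- sin(e)
    fwd <- sqrt(pmax(0, 1 - right^2 - up^2))
    c(fwd, right, up)
  }
  v1 <- vec(az1, el1)
  v2 <- vec(az2, el2)
  acos(min(1, max(-1, sum(v1 * v2)))) * 180 / pi
}

# one noise-free session + pipeline run, shared across test files
noise_free_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- params_noise_free()
      sess <- simulate_session(150, p, seed = 19)
      cache <<- list(params = p, session = sess,
                     pipe = process_session(sess, p))
    }
    cache
  }
})

# a minimal synthetic trace: stationary fixation with a raised-cosine shift
make_shift_trace <- function(amp_az = 20, amp_el = 0, onset = 500,
                             duration = 50, total = 1000,
                             sample_rate = 1017.25, start_az = 0,
                             start_el = 0) {
  t <- seq(0, total, by = 1000 / sample_rate)
  tau <- pmin(pmax((t - onset) / duration, 0), 1)
  s <- tau - sin(2 * pi * tau) / (2 * pi)
  tibble::tibble(time_ms = t, azimuth = start_az + s * amp_az,
                 elevation = start_el + s * amp_el)
}
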
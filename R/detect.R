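#' Zero-phase FIR low-pass filter for position traces
#'
#' Applies a linear-phase finite-impulse-response low-pass filter
#' (Hamming-window design; defaults: cut-off 75 Hz, order 50) to the
#' position columns of a trace. The filter is applied forward-backward
#' (`signal::filtfilt`) so the net phase is zero and event times are not
#' shifted.
#'
#' @param trace Tibble with a `time_ms` column and one or more numeric
#'   position columns (all non-time columns are filtered).
#' @param cutoff Cut-off frequency, Hz; must be below Nyquist.
#' @param order Filter order (number of taps minus one).
#' @param window_tag Window function tag; only `"hamming"` is built in.
#' @param sample_rate Sampling rate in Hz; inferred from `time_ms` when
#'   `NULL`.
#' @param method `"compensated"` (default) applies the filter once and
#'   shifts the output by the exact group delay of `order / 2` samples;
#'   `"filtfilt"` runs forward-backward (squaring the magnitude response).
#' @return The trace tibble with filtered position columns.
#' @export
lowpass_fir <- function(trace, cutoff = 75, order = 50,
                        window_tag = "hamming", sample_rate = NULL,
                        method = c("compensated", "filtfilt")) {
  window_tag <- match.arg(window_tag, "hamming")
  method <- match.arg(method)
  if (is.null(sample_rate)) {
    sample_rate <- 1000 / median(diff(trace$time_ms))
  }
  if (cutoff >= sample_rate / 2) {
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  if (nrow(trace) <= 3 * (order + 1)) {
    stop("trace too short for the requested filter order", call. = FALSE)
  }
  b <- signal::fir1(order, cutoff / (sample_rate / 2), type = "low",
                    window = signal::hamming(order + 1))
  b <- b / sum(b)  # unity DC gain so fixation positions pass unchanged
  cols <- setdiff(names(trace), "time_ms")
  npad <- 3 * (order + 1)  # edge-replication padding against end transients
  delay <- order / 2       # exact group delay of a linear-phase FIR
  for (cl in cols) {
    if (is.numeric(trace[[cl]])) {
      x <- trace[[cl]]
      xp <- c(rep(x[1], npad), x, rep(x[length(x)], npad))
      if (method == "filtfilt") {
        y <- signal::filtfilt(b, xp)
        trace[[cl]] <- y[(npad + 1):(npad + length(x))]
      } else {
        y <- as.numeric(signal::filter(b, xp))
        trace[[cl]] <- y[(npad + 1 + delay):(npad + delay + length(x))]
      }
    }
  }
  trace
}

#' Differentiate a 2D position trace
#'
#' Central-difference derivatives of azimuth and elevation; speed is the
#' vectorial magnitude `sqrt(daz^2 + del^2)` and acceleration the
#' central-difference derivative of speed.
#'
#' @param trace Tibble with columns `time_ms`, `azimuth`, `elevation`.
#' @return The trace with added columns `speed` (deg/s) and `accel`
#'   (deg/s^2).
#' @export
differentiate <- function(trace) {
  if (nrow(trace) < 3) stop("need at least 3 samples", call. = FALSE)
  dt_s <- median(diff(trace$time_ms)) / 1000
  daz <- central_diff(trace$azimuth, dt_s)
  del <- central_diff(trace$elevation, dt_s)
  trace$speed <- sqrt(daz^2 + del^2)
  trace$accel <- central_diff(trace$speed, dt_s)
  trace
}

central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Detect saccades from a gaze trace
#'
#' Velocity/acceleration saccade detection: a preliminary onset is marked at
#' the first sample where (vectorial) gaze speed exceeds `onset_speed`
#' (default 100 deg/s) and a preliminary offset at the next sample where it
#' drops below `offset_speed` (default 70 deg/s). Markers are then
#' fine-tuned toward the nearest drop below zero acceleration: the onset
#' moves backward to the latest sample at or before the preliminary mark
#' with acceleration <= 0 (the base of the speed rise), the offset forward
#' to the earliest sample with acceleration >= 0 after the deceleration (the
#' end of the speed decay). Refinement is bounded to `refine_ms` around the
#' preliminary marks; events closer than `min_gap_ms` are merged.
#'
#' @param trace Tibble with columns `time_ms`, `azimuth`, `elevation`;
#'   should be low-pass filtered first (see [lowpass_fir()]).
#' @param onset_speed,offset_speed Speed thresholds, deg/s.
#' @param refine_ms Bound on the refinement search, ms.
#' @param min_gap_ms Minimum inter-event gap; shorter re-crossings merge.
#' @return A tibble of class `saccade_events`, one row per saccade:
#'   `onset`, `offset` (ms), `start_az`, `start_el`, `end_az`, `end_el`,
#'   `amplitude` (deg), `duration` (ms), `peak_speed` (deg/s).
#' @export
detect_saccades <- function(trace, onset_speed = 100, offset_speed = 70,
                            refine_ms = 50, min_gap_ms = 10) {
  tr <- differentiate(trace)
  n <- nrow(tr)
  t <- tr$time_ms
  sp <- tr$speed
  ac <- tr$accel
  dt <- median(diff(t))
  refine_n <- ceiling(refine_ms / dt)
  empty <- tibble::tibble(
    onset = numeric(), offset = numeric(),
    start_az = numeric(), start_el = numeric(),
    end_az = numeric(), end_el = numeric(),
    amplitude = numeric(), duration = numeric(), peak_speed = numeric()
  )
  events <- list()
  i <- 1
  while (i <= n) {
    if (sp[i] > onset_speed) {
      on_prelim <- i
      j <- on_prelim
      while (j <= n && sp[j] >= offset_speed) j <- j + 1
      off_prelim <- min(j, n)
      # refine onset backward to the latest accel <= 0 sample
      lo <- max(1, on_prelim - refine_n)
      cand <- which(ac[lo:on_prelim] <= 0)
      on_ref <- if (length(cand)) lo + max(cand) - 1 else lo
      # refine offset forward to the earliest accel >= 0 sample
      hi <- min(n, off_prelim + refine_n)
      cand <- which(ac[off_prelim:hi] >= 0)
      off_ref <- if (length(cand)) off_prelim + min(cand) - 1 else hi
      events[[length(events) + 1]] <- c(on_ref, off_ref)
      i <- off_ref + 1
    } else {
      i <- i + 1
    }
  }
  if (length(events) == 0) {
    return(structure(empty, class = c("saccade_events", class(empty))))
  }
  ev <- do.call(rbind, events)
  # debounce: merge events separated by less than min_gap_ms
  if (nrow(ev) > 1) {
    keep <- list(ev[1, ])
    for (k in 2:nrow(ev)) {
      prev <- keep[[length(keep)]]
      if ((t[ev[k, 1]] - t[prev[2]]) < min_gap_ms) {
        keep[[length(keep)]] <- c(prev[1], ev[k, 2])
      } else {
        keep[[length(keep) + 1]] <- ev[k, ]
      }
    }
    ev <- do.call(rbind, keep)
  }
  out <- purrr::map_dfr(seq_len(nrow(ev)), function(k) {
    a <- ev[k, 1]; b <- ev[k, 2]
    tibble::tibble(
      onset = t[a], offset = t[b],
      start_az = tr$azimuth[a], start_el = tr$elevation[a],
      end_az = tr$azimuth[b], end_el = tr$elevation[b],
      amplitude = sqrt((tr$azimuth[b] - tr$azimuth[a])^2 +
                         (tr$elevation[b] - tr$elevation[a])^2),
      duration = t[b] - t[a],
      peak_speed = max(sp[a:b])
    )
  })
  structure(out, class = c("saccade_events", class(out)))
}

#' Main-sequence screening of detected saccades
#'
#' Fits the straight-line amplitude-duration main sequence
#' (`duration ~ amplitude`, least squares) over a set of detected saccades
#' and discards, in a single pass, events whose residual exceeds twice the
#' residual standard deviation. With fewer than 3 events no screening is
#' performed and the fit is flagged invalid.
#'
#' @param events A `saccade_events` tibble (rows may come from many trials).
#' @return A list with elements `kept`, `discarded` (both `saccade_events`
#'   tibbles) and `fit` (list: `slope` ms/deg, `intercept` ms,
#'   `residual_sd` ms, `valid`).
#' @export
main_sequence_screen <- function(events) {
  if (nrow(events) < 3) {
    return(list(kept = events, discarded = events[0, ],
                fit = list(slope = NA_real_, intercept = NA_real_,
                           residual_sd = NA_real_, valid = FALSE)))
  }
  fit <- stats::lm(duration ~ amplitude, data = events)
  res <- stats::resid(fit)
  s <- stats::sd(res)
  # an exact line leaves only numerical residue; nothing to discard then
  out <- if (s < 1e-8) rep(FALSE, length(res)) else abs(res) > 2 * s
  list(
    kept = events[!out, ],
    discarded = events[out, ],
    fit = list(slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               residual_sd = s, valid = TRUE)
  )
}
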
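#' Extract the gaze or head trace of a trial in analysis form
#'
#' @param traces Trial trace tibble with columns `time_ms`, `gaze_az`,
#'   `gaze_el`, `head_az`, `head_el`.
#' @param which `"gaze"` or `"head"`.
#' @return Tibble with columns `time_ms`, `azimuth`, `elevation`.
#' @export
trace_component <- function(traces, which = c("gaze", "head")) {
  which <- match.arg(which)
  if (which == "gaze") {
    tibble::tibble(time_ms = traces$time_ms, azimuth = traces$gaze_az,
                   elevation = traces$gaze_el)
  } else {
    tibble::tibble(time_ms = traces$time_ms, azimuth = traces$head_az,
                   elevation = traces$head_el)
  }
}

#' Identify the first and second localization responses of a double-step trial
#'
#' The first response is the earliest saccade starting after T1 onset; the
#' localization response to T2 is the last saccade that started before the
#' closed-loop reappearance of T2 (small correction saccades after that are
#' not part of the open-loop response). A trial with no saccade after T1
#' onset, or with only one saccade, is rejected.
#'
#' @param events A `saccade_events` tibble for the trial (already
#'   main-sequence screened).
#' @param t1_on_ms T1 onset time, ms.
#' @param closed_loop_ms Closed-loop T2 reappearance time, ms (`Inf` when
#'   the trial's open loop never closed).
#' @return A list with `first` and `second` (one-row event tibbles) and
#'   `rejected = FALSE`; or `rejected = TRUE` with a `reason`
#'   (`"no_saccade"` or `"one_saccade"`).
#' @export
identify_responses <- function(events, t1_on_ms, closed_loop_ms = Inf) {
  after <- events[events$onset > t1_on_ms, ]
  if (nrow(after) == 0) {
    return(list(rejected = TRUE, reason = "no_saccade"))
  }
  first <- after[which.min(after$onset), ]
  cand <- after[after$onset < closed_loop_ms & after$onset > first$onset, ]
  if (nrow(cand) == 0) {
    return(list(rejected = TRUE, reason = "one_saccade"))
  }
  second <- cand[which.max(cand$onset), ]
  list(first = first, second = second, rejected = FALSE)
}

#' Visual-feedback exclusion rule
#'
#' A double-step trial is excluded when the T2 flash extinguished after the
#' first gaze shift ended, because the system could then have received
#' direct retinal feedback about T2 before the second saccade. The boundary
#' is strict: a flash ending exactly at the first-saccade offset is kept.
#'
#' @param t2_off_ms T2 flash offset, ms.
#' @param first_offset_ms Offset of the first gaze shift, ms.
#' @return `"keep"` or `"visual_feedback"`.
#' @export
apply_exclusions <- function(t2_off_ms, first_offset_ms) {
  if (t2_off_ms > first_offset_ms) "visual_feedback" else "keep"
}

#' Classify a double-step trial as static or dynamic
#'
#' Measures the gaze movement during T2 presentation as the path length of
#' the gaze trace over the flash window. Movement below `static_max`
#' (default 0.5 deg, foveal) makes the trial static; above `dynamic_min`
#' (default 5 deg) dynamic; anything in between is excluded as
#' intermediate.
#'
#' @param gaze Gaze trace tibble (`time_ms`, `azimuth`, `elevation`).
#' @param t2_window Length-2 numeric: T2 flash on/offset, ms.
#' @param static_max,dynamic_min Classification criteria, deg.
#' @param measure `"path"` (default) or `"net"` displacement.
#' @return A list with `klass` (`"static"`, `"dynamic"`, or `"excluded"`)
#'   and `streak` (deg).
#' @export
classify_trial <- function(gaze, t2_window, static_max = 0.5,
                           dynamic_min = 5, measure = c("path", "net")) {
  measure <- match.arg(measure)
  if (t2_window[1] < min(gaze$time_ms) || t2_window[2] > max(gaze$time_ms)) {
    stop("T2 window outside the trace support", call. = FALSE)
  }
  g <- gaze[gaze$time_ms >= t2_window[1] & gaze$time_ms <= t2_window[2], ]
  # interpolate the exact window edges so partial sample intervals count
  edges <- lapply(t2_window, function(tm) interp_at(gaze, tm))
  az <- c(edges[[1]][["az"]], g$azimuth, edges[[2]][["az"]])
  el <- c(edges[[1]][["el"]], g$elevation, edges[[2]][["el"]])
  streak <- if (measure == "path") {
    streak_amplitude(az, el)
  } else {
    sqrt((az[length(az)] - az[1])^2 + (el[length(el)] - el[1])^2)
  }
  klass <- if (streak < static_max) "static"
  else if (streak > dynamic_min) "dynamic"
  else "excluded"
  list(klass = klass, streak = streak)
}

interp_at <- function(trace, t_ms) {
  c(az = stats::approx(trace$time_ms, trace$azimuth, t_ms, rule = 2)$y,
    el = stats::approx(trace$time_ms, trace$elevation, t_ms, rule = 2)$y)
}

#' Extract all regression quantities of one double-step trial
#'
#' Computes the per-trial record used by the updating-model regressions:
#' retinal target representations at flash time (`T1E`, `T2E`), the full
#' first gaze displacement (`dG1`), gaze positions at T2 onset (`G1`) and at
#' second-saccade onset (`G2`), the remaining gaze motor error
#' `GME1 = G2 - G1`, the second gaze displacement (`dG2`), the gaze and head
#' motor errors at the second movement (`GME2`, `HME2`), and the head
#' displacement during the second gaze shift (`dH2`, measured from second
#' gaze-shift onset to its offset).
#'
#' @param trial One row of a session trial table (targets and timing).
#' @param gaze,head Trace tibbles (`time_ms`, `azimuth`, `elevation`).
#' @param first,second One-row `saccade_events` tibbles.
#' @param head_onset_rule How the second head-movement onset is defined (the
#'   experimental literature states no criterion): `"gaze_onset"` (default)
#'   takes the head position at the second gaze-shift onset;
#'   `"speed_crossing"` at the first head-speed crossing of
#'   `head_onset_speed` at or after it.
#' @param head_onset_speed Head-speed criterion for the
#'   `"speed_crossing"` rule, deg/s.
#' @return A one-row tibble with all record fields (components suffixed
#'   `_az`/`_el`), `streak`, `delay_ms`, `flash_dur_ms`, `klass`.
#' @export
extract_record <- function(trial, gaze, head, first, second,
                           head_onset_rule = c("gaze_onset",
                                               "speed_crossing"),
                           head_onset_speed = 20) {
  head_onset_rule <- match.arg(head_onset_rule)
  t1_on <- trial$t1_on_ms
  t2_on <- trial$t2_on_ms
  t2_off <- t2_on + trial$t2_dur_ms
  rng <- range(gaze$time_ms)
  need <- c(t1_on = t1_on, t2_on = t2_on, t2_off = t2_off,
            second_onset = second$onset)
  bad <- need < rng[1] | need > rng[2]
  if (any(bad)) {
    stop("required time outside trace support: ",
         paste(names(need)[bad], collapse = ", "), call. = FALSE)
  }
  g_t1 <- interp_at(gaze, t1_on)
  g1 <- interp_at(gaze, t2_on)
  g2 <- interp_at(gaze, second$onset)
  h_on <- if (head_onset_rule == "gaze_onset") {
    second$onset
  } else {
    # first head-speed crossing at/after the second gaze-shift onset
    # (immediate if the head is already moving)
    hd <- differentiate(head)
    idx <- which(hd$time_ms >= second$onset & hd$speed >= head_onset_speed)
    if (length(idx)) hd$time_ms[min(idx)] else second$onset
  }
  h_at_on <- interp_at(head, h_on)
  h_s2on <- interp_at(head, second$onset)
  h_s2off <- interp_at(head, second$offset)
  cls <- classify_trial(gaze, c(t2_on, t2_off))
  tibble::tibble(
    trial_id = trial$trial_id,
    t1e_az = trial$t1_az - g_t1[["az"]], t1e_el = trial$t1_el - g_t1[["el"]],
    t2e_az = trial$t2_az - g1[["az"]], t2e_el = trial$t2_el - g1[["el"]],
    dg1_az = first$end_az - first$start_az,
    dg1_el = first$end_el - first$start_el,
    g1_az = g1[["az"]], g1_el = g1[["el"]],
    g2_az = g2[["az"]], g2_el = g2[["el"]],
    gme1_az = g2[["az"]] - g1[["az"]], gme1_el = g2[["el"]] - g1[["el"]],
    dg2_az = second$end_az - second$start_az,
    dg2_el = second$end_el - second$start_el,
    gme2_az = trial$t2_az - g2[["az"]], gme2_el = trial$t2_el - g2[["el"]],
    hme2_az = trial$t2_az - h_at_on[["az"]],
    hme2_el = trial$t2_el - h_at_on[["el"]],
    dh2_az = h_s2off[["az"]] - h_s2on[["az"]],
    dh2_el = h_s2off[["el"]] - h_s2on[["el"]],
    streak = cls$streak,
    delay_ms = t2_on - first$onset,
    flash_dur_ms = trial$t2_dur_ms,
    klass = cls$klass
  )
}

#' Run the per-trial analysis over a simulated or loaded session
#'
#' For every double-step trial: low-pass filters the gaze trace, detects
#' saccades, screens them against the session-wide main sequence, identifies
#' the first and localization responses, applies the visual-feedback
#' exclusion, classifies the trial static/dynamic, and extracts the full
#' regression record. Returns the record table together with an exclusion
#' ledger whose counts sum to the number of double-step trials.
#'
#' @param session A `gaze_session` (see [simulate_session()]) or a list with
#'   compatible `trial_table` and `traces` elements.
#' @param params A [sim_params()] list supplying detection thresholds and
#'   classification criteria.
#' @param filter_traces Apply the zero-phase FIR low-pass before detection?
#' @return A list of class `ds_pipeline`: `records` (tibble, kept trials
#'   with `klass` static/dynamic), `excluded` (tibble of trial ids and
#'   reasons), `ledger` (named counts), `ms_fit` (main-sequence fit).
#' @export
process_session <- function(session, params = sim_params(),
                            filter_traces = TRUE) {
  tt <- dplyr::filter(session$trial_table, .data$kind == "double")
  gaze_list <- list()
  head_list <- list()
  ev_list <- list()
  for (id in tt$trial_id) {
    tr <- session$traces[[as.character(id)]]
    g <- trace_component(tr, "gaze")
    h <- trace_component(tr, "head")
    if (filter_traces) {
      g <- lowpass_fir(g, sample_rate = params$sample_rate)
      h <- lowpass_fir(h, sample_rate = params$sample_rate)
    }
    gaze_list[[as.character(id)]] <- g
    head_list[[as.character(id)]] <- h
    ev <- detect_saccades(g, onset_speed = params$onset_speed,
                          offset_speed = params$offset_speed)
    if (nrow(ev)) ev$trial_id <- id
    ev_list[[as.character(id)]] <- ev
  }
  all_ev <- dplyr::bind_rows(ev_list)
  scr <- main_sequence_screen(all_ev)
  kept_ev <- scr$kept
  records <- list()
  excl <- list()
  for (i in seq_len(nrow(tt))) {
    trial <- tt[i, ]
    id <- trial$trial_id
    ev <- kept_ev[kept_ev$trial_id == id, ]
    resp <- identify_responses(ev, trial$t1_on_ms)
    if (resp$rejected) {
      excl[[length(excl) + 1]] <-
        tibble::tibble(trial_id = id, reason = resp$reason)
      next
    }
    t2_off <- trial$t2_on_ms + trial$t2_dur_ms
    if (apply_exclusions(t2_off, resp$first$offset) != "keep") {
      excl[[length(excl) + 1]] <-
        tibble::tibble(trial_id = id, reason = "visual_feedback")
      next
    }
    rec <- extract_record(trial, gaze_list[[as.character(id)]],
                          head_list[[as.character(id)]],
                          resp$first, resp$second,
                          head_onset_speed = params$head_onset_speed)
    if (rec$klass == "excluded") {
      excl[[length(excl) + 1]] <-
        tibble::tibble(trial_id = id, reason = "intermediate")
      next
    }
    records[[length(records) + 1]] <- rec
  }
  records <- dplyr::bind_rows(records)
  excluded <- dplyr::bind_rows(excl)
  ledger <- c(
    double_trials = nrow(tt),
    kept = nrow(records),
    static = sum(records$klass == "static"),
    dynamic = sum(records$klass == "dynamic"),
    no_saccade = sum(excluded$reason == "no_saccade"),
    one_saccade = sum(excluded$reason == "one_saccade"),
    visual_feedback = sum(excluded$reason == "visual_feedback"),
    intermediate = sum(excluded$reason == "intermediate")
  )
  structure(list(records = records, excluded = excluded, ledger = ledger,
                 ms_fit = scr$fit),
            class = "ds_pipeline")
}

#' @export
print.ds_pipeline <- function(x, ...) {
  cat("<ds_pipeline> ", x$ledger[["kept"]], "/", x$ledger[["double_trials"]],
      " double-step trials kept (", x$ledger[["static"]], " static, ",
      x$ledger[["dynamic"]], " dynamic)\n", sep = "")
  invisible(x)
}
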
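#' Perisaccadic localization errors decomposed along the first gaze shift
#'
#' For every record, the localization error of the second gaze shift is
#' taken with respect to the dynamically updated target
#' (`dG2 - (T2E - GME1)`, i.e. the residual after full dynamic-feedback
#' updating) and decomposed into a component parallel and a component
#' perpendicular to the first gaze-shift vector. The pre-flash gaze
#' displacement `|dG1 - GME1|` (the distance gaze had traveled when T2
#' appeared) is attached alongside the flash delay.
#'
#' @param records Record table.
#' @return The records with added columns `err_az`, `err_el`, `parallel`,
#'   `perpendicular`, `preflash`.
#' @export
perisaccadic_errors <- function(records) {
  err_az <- records$dg2_az - (records$t2e_az - records$gme1_az)
  err_el <- records$dg2_el - (records$t2e_el - records$gme1_el)
  dec <- decompose_error(err_az, err_el, records$dg1_az, records$dg1_el)
  dplyr::mutate(records,
                err_az = err_az, err_el = err_el,
                parallel = dec$parallel,
                perpendicular = dec$perpendicular,
                preflash = sqrt((records$dg1_az - records$gme1_az)^2 +
                                  (records$dg1_el - records$gme1_el)^2))
}

slope_ci <- function(y, x, level = 0.95) {
  if (length(unique(x)) < 2) {
    return(tibble::tibble(slope = NA_real_, lower = NA_real_,
                          upper = NA_real_, p_value = NA_real_,
                          defined = FALSE))
  }
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit, "x", level = level)
  tibble::tibble(slope = unname(stats::coef(fit)["x"]),
                 lower = ci[1], upper = ci[2],
                 p_value = summary(fit)$coefficients["x", 4],
                 defined = TRUE)
}

#' Perisaccadic error versus T2 flash delay
#'
#' Running mean and standard deviation of the parallel and perpendicular
#' error components as a function of the delay of the T2 flash relative to
#' first-saccade onset (sliding window), plus linear-trend tests: the slope
#' of the parallel error against delay and against the pre-flash gaze
#' displacement, with confidence intervals. Under dynamic-feedback behavior
#' both trends are flat; static-feedback behavior produces an error that
#' grows (opposite to the first gaze shift, hence with negative sign along
#' it) with the pre-flash displacement.
#'
#' @param records Record table; at least 20 records.
#' @param window_ms Sliding-window width, ms.
#' @param step_ms Window step, ms.
#' @param min_trials Minimum trials per window for a curve point.
#' @return Object of class `perisaccadic_delay`: `curve` (tibble: delay
#'   centers, running mean/SD of both components, n), `trend_delay` and
#'   `trend_preflash` (slope CI tibbles for the parallel component),
#'   `errors` (the augmented record table).
#' @export
perisaccadic_by_delay <- function(records, window_ms = 25, step_ms = 5,
                                  min_trials = 10) {
  if (nrow(records) < 20) stop("need at least 20 records", call. = FALSE)
  er <- perisaccadic_errors(records)
  centers <- seq(floor(min(er$delay_ms)), ceiling(max(er$delay_ms)),
                 by = step_ms)
  curve <- purrr::map_dfr(centers, function(cc) {
    w <- er[abs(er$delay_ms - cc) <= window_ms / 2, ]
    if (nrow(w) < min_trials) return(NULL)
    tibble::tibble(delay_ms = cc, n = nrow(w),
                   parallel_mean = mean(w$parallel),
                   parallel_sd = stats::sd(w$parallel),
                   perpendicular_mean = mean(w$perpendicular),
                   perpendicular_sd = stats::sd(w$perpendicular))
  })
  structure(list(curve = curve,
                 trend_delay = slope_ci(er$parallel, er$delay_ms),
                 trend_preflash = slope_ci(er$parallel, er$preflash),
                 errors = er),
            class = "perisaccadic_delay")
}

#' Perisaccadic error versus T2 flash duration
#'
#' Per-duration mean and SD of the horizontal and vertical error components
#' (errors relative to the dynamically updated target), with a linear trend
#' test of error against flash duration. With a single duration the trend
#' is undefined and flagged.
#'
#' @param records Record table with a `flash_dur_ms` column.
#' @return Object of class `perisaccadic_duration`: `by_duration` (tibble of
#'   per-duration means/SDs), `trend_az`, `trend_el` (slope CI tibbles).
#' @export
perisaccadic_by_duration <- function(records) {
  er <- perisaccadic_errors(records)
  by_dur <- er |>
    dplyr::group_by(.data$flash_dur_ms) |>
    dplyr::summarise(n = dplyr::n(),
                     err_az_mean = mean(.data$err_az),
                     err_az_sd = stats::sd(.data$err_az),
                     err_el_mean = mean(.data$err_el),
                     err_el_sd = stats::sd(.data$err_el),
                     .groups = "drop")
  structure(list(by_duration = by_dur,
                 trend_az = slope_ci(er$err_az, er$flash_dur_ms),
                 trend_el = slope_ci(er$err_el, er$flash_dur_ms)),
            class = "perisaccadic_duration")
}
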
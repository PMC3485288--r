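trial_table_required <- c("trial_id", "kind", "fix_az", "fix_el",
                          "t1_az", "t1_el", "fixation_dur_ms", "gap1_ms",
                          "t1_dur_ms", "seed")

#' Write a session trial table to CSV
#'
#' @param trials Trial-table tibble (one row per trial).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' Read a session trial table from CSV
#'
#' Validates the schema: the required columns must be present (`t2_*` and
#' `gap2_ms`/`t2_dur_ms` may be missing or NA for single-step trials),
#' trial ids must be unique. Unknown columns are preserved.
#'
#' @param path CSV path.
#' @return A tibble, one row per trial.
#' @export
read_trial_table <- function(path) {
  tt <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(trial_table_required, names(tt))
  if (length(missing)) {
    stop("trial table missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tt$trial_id)) {
    stop("duplicated trial_id in trial table", call. = FALSE)
  }
  dbl <- tt$kind == "double"
  t2cols <- c("t2_az", "t2_el", "gap2_ms", "t2_dur_ms")
  have <- intersect(t2cols, names(tt))
  if (any(dbl) && length(have) < length(t2cols)) {
    stop("double-step rows require columns: ",
         paste(setdiff(t2cols, have), collapse = ", "), call. = FALSE)
  }
  tt
}

#' Write a trial's gaze/head traces to CSV
#'
#' @param traces Tibble with columns `time_ms`, `gaze_az`, `gaze_el`,
#'   `head_az`, `head_el`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  readr::write_csv(traces, path)
  invisible(path)
}

#' Read a trial's gaze/head traces from CSV
#'
#' Validates uniform sampling (and, when `sample_rate` is given, that the
#' sample interval matches `1000 / sample_rate` ms) and rejects runs of
#' missing samples longer than 10 ms.
#'
#' @param path CSV path.
#' @param sample_rate Expected sampling rate in Hz, or `NULL` to skip the
#'   check.
#' @return A tibble with columns `time_ms`, `gaze_az`, `gaze_el`,
#'   `head_az`, `head_el`.
#' @export
read_traces <- function(path, sample_rate = NULL) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_ms", "gaze_az", "gaze_el", "head_az", "head_el")
  missing <- setdiff(need, names(tr))
  if (length(missing)) {
    stop("trace file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tr) == 0) stop("empty trace file: ", path, call. = FALSE)
  dts <- diff(tr$time_ms)
  if (length(dts) && (max(dts) - min(dts)) > 1e-6 * median(dts)) {
    stop("non-uniform timestamps in trace file", call. = FALSE)
  }
  if (!is.null(sample_rate) && length(dts)) {
    expected <- 1000 / sample_rate
    if (abs(median(dts) - expected) > 1e-6 * expected) {
      stop(sprintf("sample interval %.6f ms does not match expected %.6f ms (%.2f Hz)",
                   median(dts), expected, sample_rate), call. = FALSE)
    }
  }
  for (cl in setdiff(need, "time_ms")) {
    na_run <- rle(is.na(tr[[cl]]))
    if (any(na_run$values & na_run$lengths * median(dts) > 10)) {
      stop("NaN run longer than 10 ms in column ", cl, call. = FALSE)
    }
  }
  tr
}

#' Run the full double-step analysis pipeline
#'
#' Orchestrates the stages in experimental order: simulate a session (or
#' accept one), detect and screen saccades, identify responses, apply
#' exclusions, classify static/dynamic, extract records, fit and compare
#' the updating models, fit the head regression, and run the perisaccadic
#' analyses. Deterministic given the seed.
#'
#' @param params A [sim_params()] list (simulator settings, detection
#'   thresholds, classification criteria, bootstrap size).
#' @param n_trials Session size when simulating.
#' @param seed Session seed.
#' @param session Optionally a pre-built `gaze_session`; when `NULL` one is
#'   simulated.
#' @param n_boot Bootstrap resamples for the model comparison and head fit
#'   (defaults to `params$n_boot`).
#' @return A list of class `ds_results`: `pipeline` (records + exclusion
#'   ledger), `comparison_dynamic` (model comparison on dynamic records,
#'   when enough), `comparison_static`, `head_fit`, `perisaccadic`
#'   (delay analysis, when enough records), `params`.
#' @export
run_pipeline <- function(params = sim_params(), n_trials = 200, seed = 1,
                         session = NULL, n_boot = NULL) {
  if (is.null(n_boot)) n_boot <- params$n_boot
  if (is.null(session)) {
    session <- simulate_session(n_trials, params = params, seed = seed)
  }
  pipe <- process_session(session, params = params)
  rec <- pipe$records
  dyn <- rec[rec$klass == "dynamic", ]
  sta <- rec[rec$klass == "static", ]
  cmp_dyn <- if (nrow(dyn) >= 10) {
    compare_updating_models(dyn, n_boot = n_boot, seed = seed)
  }
  cmp_sta <- if (nrow(sta) >= 10) {
    compare_updating_models(sta, models = c("NC", "VU", "SFB"),
                            n_boot = n_boot, seed = seed)
  }
  head_fit <- if (nrow(rec) >= 10) {
    fit_head_mlr(rec, n_boot = n_boot, seed = seed)
  }
  peri <- if (nrow(rec) >= 20) perisaccadic_by_delay(rec)
  structure(list(pipeline = pipe, comparison_dynamic = cmp_dyn,
                 comparison_static = cmp_sta, head_fit = head_fit,
                 perisaccadic = peri, params = params),
            class = "ds_results")
}

#' @export
print.ds_results <- function(x, ...) {
  print(x$pipeline)
  if (!is.null(x$comparison_dynamic)) {
    cat("dynamic trials: best model ", x$comparison_dynamic$best, "\n",
        sep = "")
  }
  invisible(x)
}
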
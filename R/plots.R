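#' Plot a trial's gaze and head traces
#'
#' Position-versus-time plot of a trial's gaze (bold) and head (thin)
#' azimuth and elevation traces, the standard way a double-step trial is
#' inspected.
#'
#' @param traces Trace tibble (`time_ms`, `gaze_az`, `gaze_el`, `head_az`,
#'   `head_el`).
#' @param t1_on_ms,t2_on_ms Optional flash-onset markers, ms.
#' @return A ggplot object.
#' @export
plot_trial_traces <- function(traces, t1_on_ms = NULL, t2_on_ms = NULL) {
  long <- traces |>
    tidyr::pivot_longer(-"time_ms", names_to = c("signal", "component"),
                        names_sep = "_", values_to = "deg")
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$time_ms, y = .data$deg,
                                    colour = .data$component,
                                    linewidth = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::scale_linewidth_manual(values = c(gaze = 0.9, head = 0.35)) +
    ggplot2::labs(x = "time (ms)", y = "position (deg)") +
    ggplot2::theme_minimal()
  for (v in c(t1_on_ms, t2_on_ms)) {
    p <- p + ggplot2::geom_vline(xintercept = v, linetype = "dashed",
                                 colour = "grey50")
  }
  p
}

#' Plot an updating-model comparison
#'
#' Coefficients (alpha, beta) with bootstrap error bars and the coefficient
#' of determination per model.
#'
#' @param object An `updating_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.updating_comparison <- function(object, ...) {
  fits <- object$fits
  long <- fits |>
    tidyr::pivot_longer(c("alpha", "beta", "r2"), names_to = "quantity",
                        values_to = "value") |>
    dplyr::mutate(sd = dplyr::case_when(
      .data$quantity == "alpha" ~ .data$boot_sd_alpha,
      .data$quantity == "beta" ~ .data$boot_sd_beta,
      TRUE ~ .data$boot_sd_r2
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - 1.96 * .data$sd,
                                        ymax = .data$value + 1.96 * .data$sd),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot perisaccadic errors against flash delay
#'
#' Running average (solid line) with a one-SD shaded band for the error
#' components parallel and perpendicular to the first gaze shift, with the
#' per-trial errors as points.
#'
#' @param object A `perisaccadic_delay` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perisaccadic_delay <- function(object, ...) {
  cv <- object$curve |>
    tidyr::pivot_longer(-c("delay_ms", "n"),
                        names_to = c("component", "stat"),
                        names_pattern = "(parallel|perpendicular)_(mean|sd)") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
  pts <- object$errors |>
    dplyr::select("delay_ms", "parallel", "perpendicular") |>
    tidyr::pivot_longer(-"delay_ms", names_to = "component",
                        values_to = "error")
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$delay_ms)) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(y = .data$error), alpha = 0.2,
                        size = 0.5) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::facet_wrap(~component, ncol = 1) +
    ggplot2::labs(x = "T2 delay re first-saccade onset (ms)",
                  y = "localization error (deg)") +
    ggplot2::theme_minimal()
}
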
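#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an updating-model fit
#'
#' @param x An `updating_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `boot_sd`.
#' @export
tidy.updating_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta", "bias"),
    estimate = c(x$alpha, x$beta, x$bias),
    boot_sd = c(x$boot_sd_alpha, x$boot_sd_beta, x$boot_sd_bias)
  )
}

#' Fit summary of an updating-model fit
#'
#' @param x An `updating_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `component`, `r2`, `n`,
#'   `rank_deficient`.
#' @export
glance.updating_fit <- function(x, ...) {
  tibble::tibble(model = x$model, component = x$component, r2 = x$r2,
                 n = x$n, rank_deficient = x$rank_deficient)
}

#' Tidy a model comparison
#'
#' @param x An `updating_comparison` object.
#' @param ... Unused.
#' @return The per-model fit table (one row per model).
#' @export
tidy.updating_comparison <- function(x, ...) x$fits

#' Summary of a model comparison
#'
#' @param x An `updating_comparison` object.
#' @param ... Unused.
#' @return A one-row tibble: `best`, `component`, `n`.
#' @export
glance.updating_comparison <- function(x, ...) {
  tibble::tibble(best = x$best, component = x$component, n = x$n)
}

#' Tidy a head-movement regression fit
#'
#' @param x A `head_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient, bootstrap SDs and 95% CIs.
#' @export
tidy.head_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha_gme2", "beta_hme2", "bias"),
    estimate = c(x$alpha, x$beta, x$bias),
    boot_sd = c(x$boot_sd_alpha, x$boot_sd_beta, x$boot_sd_bias),
    ci_lower = c(x$alpha_ci[1], x$beta_ci[1], NA_real_),
    ci_upper = c(x$alpha_ci[2], x$beta_ci[2], NA_real_)
  )
}

#' Summary of a head-movement regression fit
#'
#' @param x A `head_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `r2`, `n`, `component`, `collinear`, and the
#'   alpha-vs-beta paired test p-value (when bootstrapped).
#' @export
glance.head_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, n = x$n, component = x$component,
                 collinear = x$collinear,
                 p_alpha_vs_beta = if (is.null(x$alpha_vs_beta)) NA_real_
                 else x$alpha_vs_beta$p_value)
}
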
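comp_suffix <- function(component) {
  component <- match.arg(component, c("azimuth", "elevation"))
  if (component == "azimuth") "az" else "el"
}

partner_var <- function(model) {
  switch(model,
         NC = "t1e", VU = "t1e", SFB = "dg1", DFB = "gme1",
         stop("unknown model tag: ", model, call. = FALSE))
}

mlr_matrices <- function(records, model, component) {
  sfx <- comp_suffix(component)
  pv <- partner_var(model)
  y <- records[[paste0("dg2_", sfx)]]
  X <- cbind(1, records[[paste0("t2e_", sfx)]],
             records[[paste0(pv, "_", sfx)]])
  colnames(X) <- c("bias", "alpha", "beta")
  list(y = y, X = X)
}

ols_fit <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  fitted <- X %*% coefs
  r <- suppressWarnings(stats::cor(y, as.numeric(fitted)))
  r2 <- if (is.na(r)) NA_real_ else r^2
  list(coefs = coefs, fitted = as.numeric(fitted),
       residuals = y - as.numeric(fitted), r2 = r2,
       rank = fit$rank)
}

#' Simple linear regression of gaze displacement on target location
#'
#' The per-component localization regression `dG = gain * TE + bias`, fitted
#' by least squares. The coefficient of determination is the squared Pearson
#' correlation between data and fit. A gain of 1 with bias 0 is perfect
#' localization.
#'
#' @param dg Measured gaze-displacement component, deg.
#' @param te Oculocentric target-location component, deg.
#' @return A tibble with columns `gain`, `bias`, `r2`, `n`, `degenerate`.
#' @export
fit_component_regression <- function(dg, te) {
  ok <- is.finite(dg) & is.finite(te)
  dg <- dg[ok]; te <- te[ok]
  if (length(dg) < 3) stop("need at least 3 finite pairs", call. = FALSE)
  if (stats::sd(te) == 0) {
    return(tibble::tibble(gain = NA_real_, bias = NA_real_, r2 = NA_real_,
                          n = length(dg), degenerate = TRUE))
  }
  f <- ols_fit(dg, cbind(1, te))
  tibble::tibble(gain = unname(f$coefs[2]), bias = unname(f$coefs[1]),
                 r2 = f$r2, n = length(dg), degenerate = FALSE)
}

#' Ideal second-saccade predictions of each updating model
#'
#' Applies the ideal coefficients (alpha = +1, beta = -1, bias = 0; for NC
#' alpha = +1, beta = 0) to the per-trial signals, giving the second gaze
#' shift each conceptual model would produce:
#' NC: `T2E`; VU: `T2E - T1E`; SFB: `T2E - dG1`; DFB: `T2E - GME1`.
#'
#' @param records Record table (see [simulate_records()] or
#'   [process_session()]).
#' @param model Model tag.
#' @return A tibble with columns `pred_az`, `pred_el`.
#' @export
predict_ideal <- function(records, model) {
  model <- match.arg(model, c("NC", "VU", "SFB", "DFB"))
  if (model == "NC") {
    tibble::tibble(pred_az = records$t2e_az, pred_el = records$t2e_el)
  } else {
    pv <- partner_var(model)
    tibble::tibble(
      pred_az = records$t2e_az - records[[paste0(pv, "_az")]],
      pred_el = records$t2e_el - records[[paste0(pv, "_el")]]
    )
  }
}

#' Remove regression outliers with a single 2 SD pass
#'
#' Fits the model's multiple regression once and removes records whose
#' residual exceeds twice the residual standard deviation; the fit is meant
#' to be recomputed on the survivors. Applied once, not iterated.
#'
#' @param records Record table.
#' @param model Model tag (`"NC"`, `"VU"`, `"SFB"`, `"DFB"`).
#' @param component `"azimuth"` or `"elevation"`.
#' @param cut Multiple of the residual SD beyond which records are dropped.
#' @return The surviving records (same columns).
#' @export
drop_fit_outliers <- function(records, model, component = "azimuth",
                              cut = 2) {
  m <- mlr_matrices(records, model, component)
  f <- ols_fit(m$y, m$X)
  s <- stats::sd(f$residuals)
  if (s == 0) return(records)
  records[abs(f$residuals) <= cut * s, ]
}

#' Fit an updating model by multiple linear regression
#'
#' Fits `dG2 = alpha * T2E + beta * X + bias` by least squares, where the
#' partner regressor `X` depends on the model: `T1E` for the visual
#' feedforward model (VU), the full first gaze displacement `dG1` for static
#' motor feedback (SFB), and the remaining motor error `GME1 = G2 - G1` for
#' dynamic motor feedback (DFB). The no-compensation benchmark (NC) fits the
#' same regression as VU; on non-updating data its beta comes out 0. The
#' ideal updating values are alpha = +1, beta = -1, bias = 0. The
#' coefficient of determination is the squared Pearson correlation of data
#' and fit.
#'
#' Optionally performs a single 2 SD outlier pass before the final fit, and
#' bootstrap resampling (rows with replacement) to obtain parameter SDs as
#' confidence levels.
#'
#' @param records Record table; typically filtered to the trial class of
#'   interest first.
#' @param model Model tag.
#' @param component `"azimuth"` (the discriminative component when first
#'   saccades are mainly horizontal) or `"elevation"`.
#' @param outlier_pass Apply [drop_fit_outliers()] once before fitting?
#' @param n_boot Number of bootstrap resamples (0 for none).
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `updating_fit`: list with `model`,
#'   `component`, `alpha`, `beta`, `bias`, `r2`, `n`, `rank_deficient`,
#'   bootstrap SDs (`boot_sd_alpha`, `boot_sd_beta`, `boot_sd_bias`) and the
#'   replicate tibble `boot` when bootstrapped.
#' @export
fit_updating_mlr <- function(records, model, component = "azimuth",
                             outlier_pass = FALSE, n_boot = 0, seed = NULL) {
  model <- match.arg(model, c("NC", "VU", "SFB", "DFB"))
  if (nrow(records) < 10) {
    stop("need at least 10 records for the multiple regression",
         call. = FALSE)
  }
  if (outlier_pass) records <- drop_fit_outliers(records, model, component)
  m <- mlr_matrices(records, model, component)
  f <- ols_fit(m$y, m$X)
  out <- list(
    model = model, component = component,
    alpha = unname(f$coefs["alpha"]), beta = unname(f$coefs["beta"]),
    bias = unname(f$coefs["bias"]), r2 = f$r2, n = length(m$y),
    rank_deficient = f$rank < ncol(m$X),
    boot_sd_alpha = NA_real_, boot_sd_beta = NA_real_,
    boot_sd_bias = NA_real_, boot = NULL
  )
  if (n_boot > 0) {
    bs <- bootstrap_mlr(m$y, m$X, n_boot = n_boot, seed = seed)
    out$boot <- bs
    out$boot_sd_alpha <- stats::sd(bs$alpha)
    out$boot_sd_beta <- stats::sd(bs$beta)
    out$boot_sd_bias <- stats::sd(bs$bias)
  }
  class(out) <- "updating_fit"
  out
}

# bootstrap a design matrix regression; resamples rows with replacement.
# rank-deficient resamples are redrawn (count reported as attribute).
bootstrap_mlr <- function(y, X, n_boot = 1000, seed = NULL,
                          indices = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  n <- length(y)
  p <- ncol(X)
  full_rank <- qr(X)$rank  # degenerate designs cannot improve on resampling
  res <- matrix(NA_real_, n_boot, p + 1)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    tries <- 0L
    repeat {
      idx <- if (is.null(indices)) sample.int(n, n, replace = TRUE)
             else indices[[b]]
      f <- stats::lm.fit(X[idx, , drop = FALSE], y[idx])
      tries <- tries + 1L
      if (f$rank >= full_rank || !is.null(indices) || tries > 100L) break
      redraws <- redraws + 1L
    }
    fitted <- X[idx, , drop = FALSE] %*% f$coefficients
    r <- suppressWarnings(stats::cor(y[idx], as.numeric(fitted)))
    res[b, ] <- c(f$coefficients, r^2)
  }
  out <- tibble::tibble(bias = res[, 1], alpha = res[, 2],
                        beta = if (p >= 3) res[, 3] else NA_real_,
                        r2 = res[, p + 1])
  attr(out, "redraws") <- redraws
  out
}

#' @export
print.updating_fit <- function(x, ...) {
  cat(sprintf("<updating_fit> %s (%s): alpha=%.3f beta=%.3f bias=%.3f r2=%.3f n=%d\n",
              x$model, x$component, x$alpha, x$beta, x$bias, x$r2, x$n))
  invisible(x)
}

#' Compare updating models on the same record set
#'
#' Fits each candidate updating model's multiple regression on the identical
#' set of records and ranks the models by their coefficient of
#' determination. When bootstrapped, the same resample of rows is used for
#' every model within a replicate, and the per-replicate r-squared sets are
#' compared with pairwise paired t-tests (significance p < 0.05).
#'
#' @param records Record table (identical rows for all models).
#' @param models Character vector of model tags to compare.
#' @param component `"azimuth"` or `"elevation"`.
#' @param n_boot Bootstrap resamples (0 = ranking only, no tests).
#' @param seed Optional seed.
#' @return An object of class `updating_comparison`: `fits` (tibble with one
#'   row per model: coefficients, r2, bootstrap SDs), `best` (model tag with
#'   the highest r2), `pairwise` (tibble of paired t-tests on bootstrap r2
#'   sets, when bootstrapped), `component`, `n`.
#' @export
compare_updating_models <- function(records,
                                    models = c("VU", "SFB", "DFB"),
                                    component = "azimuth",
                                    n_boot = 0, seed = NULL) {
  mats <- lapply(models, function(mo) mlr_matrices(records, mo, component))
  names(mats) <- models
  fits <- lapply(mats, function(m) ols_fit(m$y, m$X))
  fit_tbl <- tibble::tibble(
    model = models,
    alpha = vapply(fits, function(f) unname(f$coefs["alpha"]), 0),
    beta = vapply(fits, function(f) unname(f$coefs["beta"]), 0),
    bias = vapply(fits, function(f) unname(f$coefs["bias"]), 0),
    r2 = vapply(fits, function(f) f$r2, 0),
    n = nrow(records),
    boot_sd_alpha = NA_real_, boot_sd_beta = NA_real_, boot_sd_r2 = NA_real_
  )
  pairwise <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) withr::local_seed(seed)
    n <- nrow(records)
    indices <- lapply(seq_len(n_boot),
                      function(b) sample.int(n, n, replace = TRUE))
    boots <- lapply(models, function(mo) {
      bootstrap_mlr(mats[[mo]]$y, mats[[mo]]$X, n_boot = n_boot,
                    indices = indices)
    })
    names(boots) <- models
    fit_tbl$boot_sd_alpha <- vapply(boots, function(b) stats::sd(b$alpha), 0)
    fit_tbl$boot_sd_beta <- vapply(boots, function(b) stats::sd(b$beta), 0)
    fit_tbl$boot_sd_r2 <- vapply(boots, function(b) stats::sd(b$r2), 0)
    pairs <- utils::combn(models, 2, simplify = FALSE)
    pairwise <- purrr::map_dfr(pairs, function(pr) {
      tt <- stats::t.test(boots[[pr[1]]]$r2, boots[[pr[2]]]$r2,
                          paired = TRUE)
      tibble::tibble(model_a = pr[1], model_b = pr[2],
                     mean_diff_r2 = unname(tt$estimate),
                     t = unname(tt$statistic), p_value = tt$p.value,
                     significant = tt$p.value < 0.05)
    })
  }
  ranked <- fit_tbl[order(-fit_tbl$r2), ]
  structure(list(fits = fit_tbl, ranking = ranked$model,
                 best = ranked$model[1], pairwise = pairwise,
                 component = component, n = nrow(records)),
            class = "updating_comparison")
}

#' @export
print.updating_comparison <- function(x, ...) {
  cat("<updating_comparison> (", x$component, ", n=", x$n, ") best: ",
      x$best, "\n", sep = "")
  print(x$fits[, c("model", "alpha", "beta", "bias", "r2")])
  invisible(x)
}

#' Regression of head displacement on gaze- and head-motor errors
#'
#' Fits `dH2 = alpha * GME2 + beta * HME2 + bias`, where `dH2` is the head
#' displacement during the second gaze shift, `GME2` the oculocentric gaze
#' motor error and `HME2` the head-centered motor error at the second head
#' movement. `alpha >> beta` would indicate head movements driven by a gaze
#' error signal; `beta >> alpha` indicates goal-directed, craniocentric head
#' control. Bootstrap SDs and a paired t-test of alpha vs beta over the
#' bootstrap replicates quantify the contrast. Restricted to the azimuth
#' component by default (head movements are predominantly horizontal).
#'
#' @param records Record table.
#' @param component `"azimuth"` or `"elevation"`.
#' @param n_boot Bootstrap resamples.
#' @param seed Optional seed.
#' @return Object of class `head_fit`: `alpha`, `beta`, `bias`, `r2`, `n`,
#'   bootstrap SDs, 95% normal-theory CIs from the bootstrap SDs,
#'   `collinear` flag, and `alpha_vs_beta` test results.
#' @export
fit_head_mlr <- function(records, component = "azimuth", n_boot = 1000,
                         seed = NULL) {
  sfx <- comp_suffix(component)
  y <- records[[paste0("dh2_", sfx)]]
  gme2 <- records[[paste0("gme2_", sfx)]]
  hme2 <- records[[paste0("hme2_", sfx)]]
  X <- cbind(bias = 1, alpha = gme2, beta = hme2)
  f <- ols_fit(y, X)
  collinear <- abs(suppressWarnings(stats::cor(gme2, hme2))) > 0.99 ||
    f$rank < 3
  out <- list(
    alpha = unname(f$coefs["alpha"]), beta = unname(f$coefs["beta"]),
    bias = unname(f$coefs["bias"]), r2 = f$r2, n = length(y),
    component = component, collinear = collinear,
    boot_sd_alpha = NA_real_, boot_sd_beta = NA_real_,
    boot_sd_bias = NA_real_,
    alpha_ci = c(NA_real_, NA_real_), beta_ci = c(NA_real_, NA_real_),
    alpha_vs_beta = NULL
  )
  if (n_boot > 0) {
    bs <- bootstrap_mlr(y, X, n_boot = n_boot, seed = seed)
    out$boot_sd_alpha <- stats::sd(bs$alpha)
    out$boot_sd_beta <- stats::sd(bs$beta)
    out$boot_sd_bias <- stats::sd(bs$bias)
    out$alpha_ci <- out$alpha + c(-1.96, 1.96) * out$boot_sd_alpha
    out$beta_ci <- out$beta + c(-1.96, 1.96) * out$boot_sd_beta
    tt <- stats::t.test(bs$alpha, bs$beta, paired = TRUE)
    out$alpha_vs_beta <- list(t = unname(tt$statistic), p_value = tt$p.value)
  }
  class(out) <- "head_fit"
  out
}

#' @export
print.head_fit <- function(x, ...) {
  cat(sprintf("<head_fit> (%s): alpha(GME2)=%.3f beta(HME2)=%.3f bias=%.3f r2=%.3f n=%d\n",
              x$component, x$alpha, x$beta, x$bias, x$r2, x$n))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Parameter-free comparison of two empirical cumulative distributions.
#'
#' @param x,y Numeric samples, each with at least 5 values.
#' @return A tibble with columns `statistic` and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 5 || length(y) < 5) {
    stop("both samples need at least 5 values", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(x, y))
  tibble::tibble(statistic = unname(kt$statistic), p_value = kt$p.value)
}
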
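#' Convert polar target coordinates to double-pole azimuth/elevation
#'
#' Targets on the stimulus web are indexed by eccentricity `r` (the
#' great-circle angle from the straight-ahead direction, in deg) and direction
#' `phi` (deg counterclockwise from rightward). The double-pole chart used for
#' all downstream analysis measures azimuth as the angle from the median
#' (vertical) plane and elevation as the angle from the horizontal plane:
#'
#'   azimuth   = asin(sin r * cos phi)
#'   elevation = asin(sin r * sin phi)
#'
#' Both angles are reported in deg; positive azimuth is rightward and positive
#' elevation is upward.
#'
#' @param r Numeric vector of eccentricities in deg, `0 <= r < 90`.
#' @param phi Numeric vector of directions in deg (0 = rightward,
#'   90 = upward). Recycled against `r`.
#' @return A tibble with columns `azimuth` and `elevation` (deg).
#' @examples
#' polar_to_double_pole(20, 0)
#' polar_to_double_pole(c(5, 43), c(30, 330))
#' @export
polar_to_double_pole <- function(r, phi) {
  if (any(!is.finite(r)) || any(r < 0 | r >= 90)) {
    stop("eccentricity `r` must be finite and in [0, 90) deg", call. = FALSE)
  }
  n <- max(length(r), length(phi))
  r <- rep_len(r, n)
  phi <- rep_len(phi, n)
  sr <- sin(deg2rad(r))
  tibble::tibble(
    azimuth   = rad2deg(asin(sr * cos(deg2rad(phi)))),
    elevation = rad2deg(asin(sr * sin(deg2rad(phi))))
  )
}

#' Convert double-pole azimuth/elevation back to polar coordinates
#'
#' Inverse of [polar_to_double_pole()]. A direction is in gamut when
#' `sin^2(azimuth) + sin^2(elevation) <= 1`. At the pole (`r = 0`) the
#' direction is undefined and fixed to `phi = 0` by convention.
#'
#' @param azimuth,elevation Numeric vectors, deg.
#' @return A tibble with columns `r` and `phi` (deg, `phi` in `[0, 360)`).
#' @export
double_pole_to_polar <- function(azimuth, elevation) {
  n <- max(length(azimuth), length(elevation))
  azimuth <- rep_len(azimuth, n)
  elevation <- rep_len(elevation, n)
  sa <- sin(deg2rad(azimuth))
  se <- sin(deg2rad(elevation))
  s2 <- sa^2 + se^2
  if (any(s2 > 1 + 1e-12)) {
    stop("direction out of gamut: sin^2(azimuth) + sin^2(elevation) > 1",
         call. = FALSE)
  }
  r <- rad2deg(asin(sqrt(pmin(s2, 1))))
  phi <- rad2deg(atan2(se, sa)) %% 360
  phi[r < 1e-12] <- 0
  tibble::tibble(r = r, phi = phi)
}

#' Signed localization error of a gaze response
#'
#' The per-component localization error is the gaze displacement minus the
#' oculocentric target location (the gaze-motor error of the saccadic
#' system). For this metric only, the sign convention follows the screen
#' reading: error > 0 means the response ended right of (horizontal) or below
#' (vertical) the target, so the elevation component is reported
#' down-positive even though positions everywhere else are up-positive.
#'
#' @param dg_azimuth,dg_elevation Gaze displacement components (deg,
#'   up-positive elevation).
#' @param te_azimuth,te_elevation Oculocentric target location components
#'   (deg, up-positive elevation).
#' @return A tibble with columns `error_azimuth` (right-positive) and
#'   `error_elevation` (down-positive), deg.
#' @export
localization_error <- function(dg_azimuth, dg_elevation,
                               te_azimuth, te_elevation) {
  tibble::tibble(
    error_azimuth   = dg_azimuth - te_azimuth,
    error_elevation = -(dg_elevation - te_elevation)
  )
}

#' Convert signed localization errors to under-/overshoots
#'
#' Reinterprets the screen-signed errors of [localization_error()] from an
#' oculomotor viewpoint: when the movement started right of (horizontal) or
#' below (vertical) the target, the sign of that error component is inverted,
#' so that undershoots are always negative and overshoots always positive.
#' Whether the start was right of / below the target is determined by the
#' sign of the required displacement `tE` in that component. A component with
#' `tE = 0` is degenerate (no required movement) and is passed through
#' unchanged, flagged in the output.
#'
#' @param error_azimuth,error_elevation Signed errors as returned by
#'   [localization_error()] (azimuth right-positive, elevation down-positive).
#' @param te_azimuth,te_elevation Required displacement components (deg,
#'   up-positive elevation).
#' @return A tibble with columns `under_over_azimuth`, `under_over_elevation`
#'   (negative = undershoot), and logical `degenerate_azimuth`,
#'   `degenerate_elevation`.
#' @export
to_under_overshoot <- function(error_azimuth, error_elevation,
                               te_azimuth, te_elevation) {
  # start right of target <=> required azimuth displacement is leftward
  flip_az <- te_azimuth < 0
  # start below target <=> required elevation displacement is upward;
  # error_elevation is down-positive, so invert when te_elevation > 0
  flip_el <- te_elevation > 0
  tibble::tibble(
    under_over_azimuth   = ifelse(flip_az, -error_azimuth, error_azimuth),
    under_over_elevation = ifelse(flip_el, -error_elevation, error_elevation),
    degenerate_azimuth   = te_azimuth == 0,
    degenerate_elevation = te_elevation == 0
  )
}

#' Reconstruct the retinal trajectory of a spatially fixed target
#'
#' During a gaze shift a fixed target sweeps across the retina; its retinal
#' location at every sample is `TE = TS - G`, with `TS` the spatial target
#' location and `G` the current gaze direction.
#'
#' @param gaze Trace tibble with columns `time_ms`, `azimuth`, `elevation`.
#' @param ts_azimuth,ts_elevation Spatial target location (deg).
#' @param window Length-2 numeric, `[t_start, t_end]` in ms; must lie within
#'   the trace's time support and contain at least one sample.
#' @return A tibble with columns `time_ms`, `te_azimuth`, `te_elevation`.
#' @export
retinal_trajectory <- function(gaze, ts_azimuth, ts_elevation, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  if (window[1] < min(gaze$time_ms) || window[2] > max(gaze$time_ms)) {
    stop("window outside the trace's time support", call. = FALSE)
  }
  g <- dplyr::filter(gaze, .data$time_ms >= window[1],
                     .data$time_ms <= window[2])
  if (nrow(g) == 0) stop("empty window: no samples", call. = FALSE)
  tibble::tibble(
    time_ms      = g$time_ms,
    te_azimuth   = ts_azimuth - g$azimuth,
    te_elevation = ts_elevation - g$elevation
  )
}

#' Amplitude of a retinal streak
#'
#' Total path length (deg) of a sampled retinal trajectory: the sum of
#' successive sample-to-sample Euclidean steps. This is a path length, not a
#' net displacement, so a back-and-forth sweep counts twice. A single sample
#' has streak 0.
#'
#' @param te_azimuth,te_elevation Numeric vectors of retinal coordinates, or
#'   a tibble from [retinal_trajectory()] as first argument.
#' @return Scalar path length in deg.
#' @export
streak_amplitude <- function(te_azimuth, te_elevation = NULL) {
  if (is.data.frame(te_azimuth)) {
    df <- te_azimuth
    te_elevation <- df$te_elevation
    te_azimuth <- df$te_azimuth
  }
  stopifnot(length(te_azimuth) >= 1, length(te_azimuth) == length(te_elevation))
  if (length(te_azimuth) == 1) return(0)
  sum(sqrt(diff(te_azimuth)^2 + diff(te_elevation)^2))
}

#' Decompose an error vector parallel/perpendicular to a reference movement
#'
#' Projects a 2D error vector onto the unit vector of a reference
#' displacement (typically the first gaze shift). The parallel component is
#' signed along the reference direction; the perpendicular component follows
#' the right-hand convention (positive when the error is rotated +90 deg,
#' counterclockwise, from the reference). The decomposition preserves the
#' Euclidean norm: `parallel^2 + perpendicular^2 = |error|^2`.
#'
#' @param error_azimuth,error_elevation Error vector components (deg).
#' @param ref_azimuth,ref_elevation Reference displacement components (deg);
#'   must have nonzero magnitude.
#' @return A tibble with columns `parallel` and `perpendicular` (deg).
#' @export
decompose_error <- function(error_azimuth, error_elevation,
                            ref_azimuth, ref_elevation) {
  mag <- sqrt(ref_azimuth^2 + ref_elevation^2)
  if (any(mag == 0)) {
    stop("reference displacement has zero magnitude; decomposition undefined",
         call. = FALSE)
  }
  ux <- ref_azimuth / mag
  uy <- ref_elevation / mag
  tibble::tibble(
    parallel      = error_azimuth * ux + error_elevation * uy,
    perpendicular = -error_azimuth * uy + error_elevation * ux
  )
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
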
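#' Build an instantaneous heart-rate profile
#'
#' An HR profile prescribes the instantaneous heart rate of a synthetic
#' subject as a function of time. It is the shared beat clock of the ECG and
#' LVP generators: beats are placed where the integral of the rate crosses
#' successive integers, so any stage downstream can be checked against the
#' profile analytically.
#'
#' @param segments A data frame with columns `time_s` and `hr_bpm`
#'   (breakpoints, times strictly increasing), or a numeric vector of length
#'   two `c(time_s, hr_bpm)` for a single segment, or a list of such pairs.
#' @param interpolation `"hold"` (piecewise-constant, the default) or
#'   `"linear"` between breakpoints. After the last breakpoint the last value
#'   holds either way.
#'
#' @return A tibble of class `hr_profile` with columns `time_s`, `hr_bpm`
#'   and an `interpolation` attribute.
#' @examples
#' hr_profile(data.frame(time_s = c(0, 30), hr_bpm = c(80, 72)))
#' @export
hr_profile <- function(segments, interpolation = c("hold", "linear")) {
  interpolation <- match.arg(interpolation)
  if (is.numeric(segments) && length(segments) == 2L) {
    segments <- list(segments)
  }
  if (is.list(segments) && !is.data.frame(segments)) {
    segments <- tibble::tibble(
      time_s = purrr::map_dbl(segments, 1),
      hr_bpm = purrr::map_dbl(segments, 2)
    )
  }
  if (!all(c("time_s", "hr_bpm") %in% names(segments)) || nrow(segments) == 0) {
    abort("`segments` must be a nonempty table with columns `time_s` and `hr_bpm`.")
  }
  tm <- segments$time_s
  hr <- segments$hr_bpm
  if (any(diff(tm) <= 0)) {
    bad <- which(diff(tm) <= 0)[1]
    abort(sprintf(
      "Breakpoint times must be strictly increasing; offending pair: t[%d] = %g, t[%d] = %g.",
      bad, tm[bad], bad + 1L, tm[bad + 1L]
    ))
  }
  if (any(hr <= 20 | hr >= 300)) {
    abort("HR breakpoints must lie in (20, 300) bpm.")
  }
  out <- tibble::tibble(time_s = as.double(tm), hr_bpm = as.double(hr))
  attr(out, "interpolation") <- interpolation
  class(out) <- c("hr_profile", class(out))
  out
}

#' Evaluate an HR profile
#'
#' @param profile An [hr_profile()].
#' @param t Numeric vector of times (s). Times before the first breakpoint
#'   take the first value.
#' @return Instantaneous heart rate in bpm at each `t`.
#' @export
profile_hr_at <- function(profile, t) {
  stopifnot(inherits(profile, "hr_profile"))
  method <- if (identical(attr(profile, "interpolation"), "linear")) "linear" else "constant"
  if (nrow(profile) == 1L) {
    return(rep(profile$hr_bpm, length(t)))
  }
  approx(profile$time_s, profile$hr_bpm,
    xout = t, method = method,
    rule = 2, f = 0
  )$y
}

## Cumulative beats at time t: Phi(t) = integral_0^t rate/60 dt.
## Piecewise-linear rate (in both interpolation modes the rate is piecewise
## linear on a refined grid), so trapezoidal integration on a fine grid is
## exact up to grid resolution.
profile_beat_phase <- function(profile, t_grid) {
  rate <- profile_hr_at(profile, t_grid) / 60
  dt <- diff(t_grid)
  c(0, cumsum((head(rate, -1) + tail(rate, -1)) / 2 * dt))
}

## Nominal (noise-free) beat times on [0, duration]: the k-th beat occurs
## where Phi(t) = k, k = 1, 2, ...
profile_beat_times <- function(profile, duration, dt = 1e-3) {
  t_grid <- seq(0, duration, by = dt)
  if (t_grid[length(t_grid)] < duration) t_grid <- c(t_grid, duration)
  phase <- profile_beat_phase(profile, t_grid)
  n_beats <- floor(phase[length(phase)])
  if (n_beats < 1) {
    abort("Duration is shorter than one beat period of the profile.")
  }
  ## Phi is strictly increasing (HR > 20 bpm), so inversion is well defined.
  approx(phase, t_grid, xout = seq_len(n_beats))$y
}

#' Noise configuration for the signal generators
#'
#' The standard confounders the downstream 4-45 Hz bandpass is built to
#' remove: sinusoidal baseline wander, additive white noise, and per-beat
#' R-R jitter.
#'
#' @param baseline_wander_amp Wander amplitude, trace units (mV-scale for ECG).
#' @param wander_freq Wander frequency, Hz.
#' @param white_sigma Standard deviation of additive white noise, trace units.
#' @param rr_jitter_sigma Per-beat timing jitter as a fraction of the local
#'   R-R interval; must be below 0.2.
#' @param seed Integer seed; the same seed reproduces the same trace bit for
#'   bit, and the ECG/LVP channels draw from distinct substreams.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(baseline_wander_amp = 0.1, wander_freq = 0.25,
                         white_sigma = 0.05, rr_jitter_sigma = 0.02,
                         seed = 1L) {
  if (baseline_wander_amp < 0 || white_sigma < 0 || rr_jitter_sigma < 0) {
    abort("Noise amplitudes must be non-negative.")
  }
  if (rr_jitter_sigma >= 0.2) {
    abort("`rr_jitter_sigma` must be below 0.2 (fraction of an R-R interval).")
  }
  structure(
    list(
      baseline_wander_amp = baseline_wander_amp, wander_freq = wander_freq,
      white_sigma = white_sigma, rr_jitter_sigma = rr_jitter_sigma,
      seed = as.integer(seed)
    ),
    class = "noise_config"
  )
}

#' Silent noise configuration
#'
#' Convenience constructor for noiseless traces (no wander, no white noise,
#' no beat jitter).
#' @param seed Integer seed (kept for interface symmetry).
#' @return A `noise_config` with all amplitudes zero.
#' @export
noise_off <- function(seed = 1L) {
  noise_config(0, 0.25, 0, 0, seed)
}
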
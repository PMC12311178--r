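#' Adaptive R-peak detection
#'
#' Classical adaptive-threshold detection on the bandpassed ECG. Candidate
#' peaks are local maxima; running estimates of the signal-peak amplitude S
#' (from accepted peaks) and the noise-peak amplitude N (from rejected
#' candidates) place the acceptance threshold between them,
#' `N + threshold_frac * (S - N)`, with the signal contribution decaying
#' exponentially (time constant `decay_tau`) since the last accepted peak so
#' that a weakened beat is still caught, and a refractory period blocking
#' double detections. Accepted peak times are refined to sub-sample
#' precision by parabolic interpolation through the three samples around
#' the maximum.
#'
#' @param filtered A `vns_trace` from [apply_filters()] (any trace works;
#'   detection assumes upright R waves).
#' @param threshold_frac Fraction of the decayed amplitude estimate that a
#'   candidate must exceed (default 0.5).
#' @param decay_tau Decay time constant of the threshold, s (default 2).
#' @param refractory Minimum separation between accepted peaks, s
#'   (default 0.2, i.e. a 300 bpm ceiling).
#' @return A tibble of class `peak_series` with columns `time_s`,
#'   `amplitude`; a flat or all-subthreshold signal yields zero rows.
#' @export
detect_r_peaks <- function(filtered, threshold_frac = 0.5, decay_tau = 2,
                           refractory = 0.2) {
  x <- filtered$value
  fs <- trace_fs(filtered)
  n <- length(x)
  if (n < 3) {
    return(empty_peaks(attr(filtered, "duration")))
  }
  core <- 2:(n - 1)
  is_max <- x[core] > x[core - 1] & x[core] >= x[core + 1] & x[core] > 0
  cand <- core[is_max]
  if (!length(cand)) {
    return(empty_peaks(n / fs))
  }
  ## Initial estimates from the first two seconds of candidates: the
  ## largest local maximum is taken as the signal peak, the noise floor
  ## starts at a tenth of it and adapts from rejected candidates.
  s_amp <- max(x[cand[cand <= 2 * fs + 1]], x[cand[1]])
  n_amp <- 0.1 * s_amp
  t_last <- -Inf
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    t <- (i - 1) / fs
    if (t - t_last < refractory) next
    decay <- exp(-(t - max(t_last, 0)) / decay_tau)
    thr <- max(
      n_amp + threshold_frac * (s_amp - n_amp) * decay,
      1.2 * n_amp
    )
    if (x[i] >= thr) {
      keep[j] <- TRUE
      s_amp <- 0.8 * s_amp + 0.2 * x[i]
      t_last <- t
    } else {
      n_amp <- min(0.8 * n_amp + 0.2 * x[i], 0.7 * s_amp)
    }
  }
  idx <- cand[keep]
  ## Parabolic sub-sample refinement of peak location.
  a <- x[idx - 1]
  b <- x[idx]
  cc <- x[idx + 1]
  denom <- a - 2 * b + cc
  offs <- ifelse(abs(denom) > .Machine$double.eps, 0.5 * (a - cc) / denom, 0)
  offs <- pmin(pmax(offs, -0.5), 0.5)
  out <- tibble::tibble(time_s = (idx - 1 + offs) / fs, amplitude = b)
  attr(out, "duration") <- n / fs
  class(out) <- c("peak_series", class(out))
  out
}

empty_peaks <- function(duration = NULL) {
  out <- tibble::tibble(time_s = numeric(), amplitude = numeric())
  attr(out, "duration") <- duration
  class(out) <- c("peak_series", class(out))
  out
}

## Shared windowing core: event times with per-interval rates assigned to
## the half-open 5-s window [k*w, (k+1)*w) containing the interval's ending
## event. A window is missing (NA) when fewer than `min_events` events fall
## inside it.
window_rates <- function(event_times, rates_end, duration, window = 5,
                         min_events = 2) {
  n_win <- floor(duration / window + 1e-9)
  starts <- (seq_len(n_win) - 1) * window
  win_of <- function(t) floor(t / window) + 1
  ev_win <- win_of(event_times)
  n_ev <- tabulate(ev_win[ev_win >= 1 & ev_win <= n_win], nbins = n_win)
  hr <- rep(NA_real_, n_win)
  if (length(event_times) >= 2) {
    end_t <- event_times[-1]
    r <- rates_end
    rw <- win_of(end_t)
    ok <- rw >= 1 & rw <= n_win
    med <- tapply(r[ok], factor(rw[ok], levels = seq_len(n_win)), median)
    hr <- as.numeric(med)
  }
  hr[n_ev < min_events] <- NA_real_
  tibble::tibble(window_start_s = starts, hr_bpm = hr, n_beats = n_ev)
}

new_hr_series <- function(df, window) {
  attr(df, "window") <- window
  class(df) <- c("hr_series", class(df))
  df
}

#' Windowed median heart rate from detected peaks
#'
#' The real-time heart rate of the reference chain: one value per 5-s
#' window, the median of the instantaneous rates 60/RR over the R-R
#' intervals whose ending peak falls in the half-open window
#' `[k*window, (k+1)*window)`. Windows containing fewer than two peaks are
#' flagged missing (`NA`).
#'
#' @param peaks A `peak_series` (or any tibble with `time_s`).
#' @param duration Total duration covered, s; defaults to the duration
#'   recorded on `peaks`.
#' @param window Window length, s (default 5).
#' @return A tibble of class `hr_series` with `window_start_s`, `hr_bpm`
#'   (NA when missing) and `n_beats`.
#' @export
hr_from_peaks_windowed <- function(peaks, duration = NULL, window = 5) {
  duration <- duration %||% attr(peaks, "duration")
  if (is.null(duration)) {
    abort("`duration` is required when `peaks` carries no duration attribute.")
  }
  tt <- peaks$time_s
  rates <- if (length(tt) >= 2) 60 / diff(tt) else numeric()
  new_hr_series(window_rates(tt, rates, duration, window), window)
}

#' Baseline heart rate before a stimulation phase
#'
#' The mean of the two most recent non-missing window values that were fully
#' available before `stim_start`.
#'
#' @param history An `hr_series`.
#' @param stim_start Stimulation onset time, s.
#' @return Baseline HR, bpm.
#' @export
compute_baseline_hr <- function(history, stim_start) {
  w <- attr(history, "window") %||% 5
  ok <- history$window_start_s + w <= stim_start + 1e-9 & !is.na(history$hr_bpm)
  vals <- history$hr_bpm[ok]
  if (length(vals) < 2) {
    abort("Insufficient baseline: fewer than 2 HR windows available before stimulation.")
  }
  mean(tail(vals, 2))
}

#' Average heart-rate agreement error
#'
#' `mean(|sensed - reference| / reference) * 100` over windows present and
#' non-missing in both series — the agreement metric used to benchmark the
#' sensed HR against a gold-standard beat clock.
#'
#' @param sensed,reference `hr_series` objects on the same window grid.
#' @return Average error in percent.
#' @export
average_hr_error <- function(sensed, reference) {
  m <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(sensed), "window_start_s", sensed = "hr_bpm"),
    dplyr::select(tibble::as_tibble(reference), "window_start_s", ref = "hr_bpm"),
    by = "window_start_s"
  )
  m <- dplyr::filter(m, !is.na(.data$sensed), !is.na(.data$ref))
  if (nrow(m) == 0) {
    abort("No common non-missing windows between the two series.")
  }
  if (any(m$ref <= 0)) abort("Reference HR values must be positive.")
  mean(abs(m$sensed - m$ref) / m$ref) * 100
}

#' Heart rate from LVP rising edges
#'
#' Locates the rising edge of each pressure pulse as the upward crossing of
#' the half-height level (linear-interpolated, 0.2 s refractory), lightly
#' smooths the edge-to-edge rates with a 3-point running median, and windows
#' them exactly as [hr_from_peaks_windowed()].
#'
#' @param lvp A `vns_trace` of kind `"lvp"`.
#' @param window Window length, s (default 5).
#' @return An `hr_series`; a flat trace yields all-missing windows.
#' @export
hr_from_lvp <- function(lvp, window = 5) {
  x <- lvp$value
  fs <- trace_fs(lvp)
  duration <- length(x) / fs
  rng <- range(x)
  level <- mean(rng)
  if (diff(rng) < 1e-9) {
    return(new_hr_series(window_rates(numeric(), numeric(), duration, window), window))
  }
  up <- which(x[-length(x)] < level & x[-1] >= level)
  if (length(up)) {
    frac <- (level - x[up]) / (x[up + 1] - x[up])
    edges <- (up - 1 + frac) / fs
    keep <- c(TRUE, diff(edges) >= 0.2)
    while (!all(keep)) {
      edges <- edges[keep]
      keep <- c(TRUE, diff(edges) >= 0.2)
    }
  } else {
    edges <- numeric()
  }
  rates <- if (length(edges) >= 2) 60 / diff(edges) else numeric()
  if (length(rates) >= 3) {
    rates <- stats::runmed(rates, 3, endrule = "keep")
  }
  new_hr_series(window_rates(edges, rates, duration, window), window)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
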
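#' @title Synthetic ECG and LVP traces
#' @description
#' `synthesize_ecg()` renders a Lead-I-style ECG with QRS-dominant
#' morphology; `synthesize_lvp()` renders a left-ventricular-pressure trace
#' whose rising edges share the ECG beat clock. Both place beats by rate
#' integration: the k-th beat occurs where the integral of the instantaneous
#' rate equals k, so beat counts and window medians can be checked against
#' the profile analytically.
#' @name synth-traces
NULL

## Raised-cosine bump of half-width `half` (s) centred at 0, evaluated at t.
raised_cosine <- function(t, half) {
  ifelse(abs(t) < half, 0.5 * (1 + cos(pi * t / half)), 0)
}

new_trace <- function(time_s, value, fs, kind, beat_times = NULL,
                      profile = NULL) {
  out <- tibble::tibble(time_s = time_s, value = value)
  attr(out, "fs") <- fs
  attr(out, "kind") <- kind
  attr(out, "beat_times") <- beat_times
  attr(out, "profile") <- profile
  class(out) <- c("vns_trace", class(out))
  out
}

#' Sampling rate of a trace
#' @param trace A `vns_trace`.
#' @return Samples per second.
#' @export
trace_fs <- function(trace) attr(trace, "fs")

#' Ground-truth beat times of a synthetic trace
#' @param trace A `vns_trace` from [synthesize_ecg()] or [synthesize_lvp()].
#' @return Beat times in seconds (after jitter), the generator's truth.
#' @export
trace_beat_times <- function(trace) attr(trace, "beat_times")

## Jittered beat times shared by both channels for a given profile + seed.
beats_with_jitter <- function(profile, duration, noise) {
  beats <- profile_beat_times(profile, duration)
  if (noise$rr_jitter_sigma > 0 && length(beats) > 1) {
    rr <- diff(c(0, beats))
    eps <- with_local_seed(noise$seed, rnorm(length(beats), 0, noise$rr_jitter_sigma))
    eps <- pmin(pmax(eps, -0.45), 0.45) # keep ordering of beats
    beats <- beats + eps * rr
  }
  beats
}

## Add a template `amp * raised_cosine(t - centre, half)` into `x` in place.
add_bump <- function(x, fs, centre, half, amp) {
  i0 <- max(1L, floor((centre - half) * fs) + 1L)
  i1 <- min(length(x), ceiling((centre + half) * fs) + 1L)
  if (i1 < i0) {
    return(x)
  }
  idx <- i0:i1
  t <- (idx - 1L) / fs
  x[idx] <- x[idx] + amp * raised_cosine(t - centre, half)
  x
}

channel_noise <- function(n, fs, noise, stream_offset) {
  if (noise$baseline_wander_amp == 0 && noise$white_sigma == 0) {
    return(numeric(n))
  }
  with_local_seed(noise$seed + stream_offset, {
    t <- (seq_len(n) - 1L) / fs
    phase <- runif(1, 0, 2 * pi)
    wander <- noise$baseline_wander_amp * sin(2 * pi * noise$wander_freq * t + phase)
    wander + rnorm(n, 0, noise$white_sigma)
  })
}

#' Synthesize a Lead-I-style ECG trace
#'
#' Each beat is rendered as a raised-cosine R wave (default 80 ms wide,
#' 1 mV) flanked by low-amplitude P and T bumps (R amplitude at least three
#' times either), so the QRS dominates as in a Lead-I surface recording.
#' Beats follow the integrated instantaneous rate of `profile`.
#'
#' @param profile An [hr_profile()].
#' @param duration Trace duration, s (at least 10 s).
#' @param fs Sampling rate, samples/s (at least 100; the reference chain
#'   digitizes at 200 Hz).
#' @param noise A [noise_config()]; `noise_off()` for a clean trace.
#' @return A `vns_trace` tibble (`time_s`, `value`) with attributes `fs`,
#'   `kind = "ecg"` and the ground-truth `beat_times`.
#' @examples
#' ecg <- synthesize_ecg(hr_profile(c(0, 60)), duration = 20, noise = noise_off())
#' length(trace_beat_times(ecg))
#' @export
synthesize_ecg <- function(profile, duration, fs = 200, noise = noise_config()) {
  check_synth_args(duration, fs)
  beats <- beats_with_jitter(profile, duration, noise)
  n <- round(duration * fs)
  x <- numeric(n)
  rr_prev <- diff(c(0, beats))
  rr_next <- c(diff(beats), if (length(beats)) 60 / profile_hr_at(profile, beats[length(beats)]) else numeric())
  for (k in seq_along(beats)) {
    x <- add_bump(x, fs, beats[k], half = 0.040, amp = 1.0) # R
    if (rr_prev[k] > 0.40) {
      x <- add_bump(x, fs, beats[k] - 0.15, half = 0.045, amp = 0.12) # P
    }
    if (rr_next[k] > 0.45) {
      x <- add_bump(x, fs, beats[k] + 0.25, half = 0.080, amp = 0.20) # T
    }
  }
  x <- x + channel_noise(n, fs, noise, stream_offset = 1L)
  new_trace((seq_len(n) - 1L) / fs, x, fs, "ecg", beats, profile)
}

#' Synthesize a left-ventricular-pressure trace
#'
#' One pressure pulse per beat with a sharp upstroke whose half-height
#' crossing falls exactly on the beat time, so rising edges share the ECG
#' beat clock when the same profile and seed are used. Pressures are on an
#' mmHg-like scale (diastolic floor ~8, systolic peak ~108); only the
#' timing matters downstream.
#'
#' @inheritParams synthesize_ecg
#' @return A `vns_trace` with `kind = "lvp"`.
#' @export
synthesize_lvp <- function(profile, duration, fs = 200, noise = noise_config()) {
  check_synth_args(duration, fs)
  beats <- beats_with_jitter(profile, duration, noise)
  n <- round(duration * fs)
  x <- rep(8, n)
  rise <- 0.06 # half-duration of the upstroke: 50% level at the beat time
  rr_next <- c(diff(beats), if (length(beats)) 60 / profile_hr_at(profile, beats[length(beats)]) else numeric())
  amp <- 100
  for (k in seq_along(beats)) {
    tb <- beats[k]
    decay <- max(0.12, 0.30 * rr_next[k]) # systolic decay back to the floor
    i0 <- max(1L, floor((tb - rise) * fs) + 1L)
    i1 <- min(n, ceiling((tb + rise + decay) * fs) + 1L)
    if (i1 < i0) next
    idx <- i0:i1
    t <- (idx - 1L) / fs - tb
    up <- t <= rise
    shape <- numeric(length(idx))
    shape[up] <- 0.5 * (1 + sin(pi * pmax(pmin(t[up] / (2 * rise), 0.5), -0.5)))
    shape[!up] <- raised_cosine(t[!up] - rise, decay)
    x[idx] <- pmax(x[idx], 8 + amp * shape)
  }
  ## LVP channel noise drawn from its own substream: independent of the ECG's.
  scale <- amp / 10
  x <- x + scale * channel_noise(n, fs, noise, stream_offset = 2L)
  new_trace((seq_len(n) - 1L) / fs, x, fs, "lvp", beats, profile)
}

check_synth_args <- function(duration, fs) {
  if (fs < 100) abort("`fs` must be at least 100 samples/s.")
  if (duration < 10) abort("`duration` must be at least 10 s.")
  invisible(TRUE)
}

#' Read and write sampled traces as CSV
#'
#' Plain-text interchange format: header `time_s,value`, one row per sample.
#' The sampling rate is recovered from the time column on read.
#'
#' @param trace A `vns_trace`.
#' @param path File path.
#' @param kind Trace kind to stamp on the object read back.
#' @return `read_trace_csv()` returns a `vns_trace`; `write_trace_csv()`
#'   returns `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(as.data.frame(trace[, c("time_s", "value")]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, kind = "ecg") {
  df <- read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    abort("Trace CSV must have columns `time_s` and `value`.")
  }
  fs <- 1 / median(diff(df$time_s))
  new_trace(df$time_s, df$value, fs, kind)
}
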
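test_that("FIR designs have the stated tap counts and exact DC behaviour", {
  taps <- design_fir_bandpass(filter_spec())
  expect_length(taps$hp, 25)
  expect_length(taps$lp, 49)
  expect_lt(abs(sum(taps$hp)), 1e-10) # high-pass DC gain exactly zero
  expect_equal(sum(taps$lp), 1, tolerance = 1e-6) # low-pass unit DC gain
  # linear phase: symmetric taps
  expect_equal(taps$hp, rev(taps$hp))
  expect_equal(taps$lp, rev(taps$lp))
  expect_error(filter_spec(lp_cutoff = 120), "Nyquist")
  expect_error(filter_spec(hp_order = 23), "even")
})

test_that("bandpass response passes the heart band and rejects wander", {
  taps <- design_fir_bandpass(filter_spec())
  h10 <- fir_response(taps$hp, 10, 200) * fir_response(taps$lp, 10, 200)
  h05 <- fir_response(taps$hp, 0.5, 200) * fir_response(taps$lp, 0.5, 200)
  expect_gt(20 * log10(h10), -3)
  expect_lt(20 * log10(h05), -20)
})

test_that("filtering matches the frequency-response oracle on pure tones", {
  spec <- filter_spec()
  taps <- design_fir_bandpass(spec)
  fs <- 200
  t <- (0:(20 * fs - 1)) / fs
  for (f0 in c(1, 20)) {
    x <- fulcrum:::new_trace(t, sin(2 * pi * f0 * t), fs, "ecg")
    y <- apply_filters(x, spec)
    mid <- y$value[(5 * fs):(15 * fs)] # steady state away from edges
    gain_measured <- sqrt(2 * mean(mid^2)) # RMS amplitude of the tone
    gain_expected <- fir_response(taps$hp, f0, fs) * fir_response(taps$lp, f0, fs)
    expect_equal(gain_measured, gain_expected, tolerance = 1e-3)
  }
})

test_that("the filter chain is linear, length-preserving and fs-checked", {
  fs <- 200
  t <- (0:(12 * fs - 1)) / fs
  zero <- fulcrum:::new_trace(t, numeric(length(t)), fs, "ecg")
  expect_equal(apply_filters(zero)$value, numeric(length(t)))

  set.seed(11)
  x1 <- rnorm(length(t))
  x2 <- rnorm(length(t))
  tr <- function(v) fulcrum:::new_trace(t, v, fs, "ecg")
  y_sum <- apply_filters(tr(x1 + 2 * x2))$value
  y_parts <- apply_filters(tr(x1))$value + 2 * apply_filters(tr(x2))$value
  expect_equal(y_sum, y_parts, tolerance = 1e-12)
  expect_length(y_sum, length(t))

  # scaling commutes with filtering
  expect_equal(apply_filters(tr(3 * x1))$value, 3 * apply_filters(tr(x1))$value,
    tolerance = 1e-12
  )

  bad <- fulcrum:::new_trace(t, x1, 250, "ecg")
  expect_error(apply_filters(bad), "mismatch")
})

test_that("R-peak detection recovers the generator's beats", {
  prof <- hr_profile(c(0, 60))
  clean <- apply_filters(synthesize_ecg(prof, 60, 200, noise_off()))
  pk <- detect_r_peaks(clean)
  beats <- trace_beat_times(clean)
  expect_equal(nrow(pk), 60)
  # interior beats within 10 ms; the final beat sits on the trace edge with
  # a truncated QRS template, so its apex is not fully rendered
  interior <- beats < max(clean$time_s) - 0.1
  expect_lt(max(abs(pk$time_s[interior] - beats[interior])), 0.010)

  flat <- fulcrum:::new_trace((0:999) / 200, numeric(1000), 200, "filtered")
  expect_equal(nrow(detect_r_peaks(flat)), 0)

  # white noise at sigma = R/10: recall and precision both 100%
  noisy <- apply_filters(synthesize_ecg(prof, 60, 200,
    noise_config(white_sigma = 0.1, rr_jitter_sigma = 0, seed = 5)
  ))
  pkn <- detect_r_peaks(noisy)
  expect_equal(nrow(pkn), length(beats))
  expect_lt(max(abs(pkn$time_s[interior] - beats[interior])), 0.010)
})

test_that("windowed HR is the per-window median of interval rates", {
  # uniform 1.0 s R-R: every window reports exactly 60 bpm
  pk <- tibble::tibble(time_s = seq(0.5, 59.5, by = 1), amplitude = 1)
  hrs <- hr_from_peaks_windowed(pk, 60)
  expect_equal(nrow(hrs), 12)
  expect_equal(hrs$hr_bpm, rep(60, 12))

  # one ectopic-like 0.5 s interval in a window: median stays 60
  tt <- c(0.2, 1.2, 2.2, 3.2, 3.7, 4.8)
  hrs2 <- hr_from_peaks_windowed(tibble::tibble(time_s = tt), 5)
  expect_equal(hrs2$hr_bpm, median(60 / diff(tt)))
  expect_equal(hrs2$hr_bpm, 60)

  # 700 s yields 140 windows, sparse regions flagged missing
  pk3 <- tibble::tibble(time_s = seq(0.5, 300, by = 1))
  hrs3 <- hr_from_peaks_windowed(pk3, 700)
  expect_equal(nrow(hrs3), 140)
  expect_true(all(is.na(hrs3$hr_bpm[hrs3$window_start_s >= 305])))
})

test_that("median windows resist corruption of a minority of intervals", {
  # ten intervals confined to the first 5-s window; corrupting fewer than
  # half of them by any amount leaves the window median inside the
  # uncorrupted rates' range
  set.seed(21)
  base_rr <- rep(0.3, 10)
  for (i in 1:8) {
    rr <- base_rr
    k <- sample(1:4, 1)
    rr[sample(10, k)] <- runif(k, 0.05, 0.4)
    tt <- c(0.05, 0.05 + cumsum(rr))
    stopifnot(max(tt) < 5)
    hrs <- hr_from_peaks_windowed(tibble::tibble(time_s = tt), 5)
    clean_rates <- 60 / base_rr
    expect_gte(hrs$hr_bpm[1], min(clean_rates) - 1e-9)
    expect_lte(hrs$hr_bpm[1], max(60 / rr) + 1e-9)
  }
})

test_that("baseline HR is the mean of the last two pre-stimulation windows", {
  hrs <- tibble::tibble(
    window_start_s = c(0, 5, 10, 15),
    hr_bpm = c(70, 75, 80, 82)
  )
  attr(hrs, "window") <- 5
  class(hrs) <- c("hr_series", class(hrs))
  expect_equal(compute_baseline_hr(hrs, 20), 81)
  expect_equal(compute_baseline_hr(hrs, 15), 77.5) # only first three usable
  single <- hrs[1, ]
  attr(single, "window") <- 5
  expect_error(compute_baseline_hr(single, 20), "Insufficient baseline")
})

test_that("average HR error implements the benchmark agreement metric", {
  mk_series <- function(v) {
    s <- tibble::tibble(window_start_s = (seq_along(v) - 1) * 5, hr_bpm = v)
    class(s) <- c("hr_series", class(s))
    s
  }
  expect_equal(average_hr_error(mk_series(c(60, 60)), mk_series(c(60, 60))), 0)
  expect_equal(average_hr_error(mk_series(c(61, 61)), mk_series(c(60, 60))),
    100 / 60,
    tolerance = 1e-9
  )
  expect_equal(average_hr_error(mk_series(c(59, 61)), mk_series(c(60, 60))),
    100 / 60,
    tolerance = 1e-9
  )
  expect_error(
    average_hr_error(mk_series(NA_real_), mk_series(60)),
    "No common"
  )
})

test_that("LVP-derived HR agrees with the ECG chain on the shared clock", {
  prof <- hr_profile(data.frame(time_s = c(0, 30), hr_bpm = c(72, 66)))
  nz <- noise_config(
    white_sigma = 0.02, baseline_wander_amp = 0.05,
    rr_jitter_sigma = 0, seed = 9
  )
  ecg <- synthesize_ecg(prof, 60, 200, nz)
  lvp <- synthesize_lvp(prof, 60, 200, nz)
  sensed <- hr_from_peaks_windowed(detect_r_peaks(apply_filters(ecg)), 60)
  gold <- hr_from_lvp(lvp)
  expect_lt(average_hr_error(sensed, gold), 0.1)

  # with per-beat timing jitter the LVP-side smoothing makes the two
  # extractions differ slightly, but they stay well inside the benchtop bound
  nzj <- noise_config(
    white_sigma = 0.02, baseline_wander_amp = 0.05,
    rr_jitter_sigma = 0.01, seed = 9
  )
  ej <- synthesize_ecg(prof, 60, 200, nzj)
  lj <- synthesize_lvp(prof, 60, 200, nzj)
  sj <- hr_from_peaks_windowed(detect_r_peaks(apply_filters(ej)), 60)
  expect_lt(average_hr_error(sj, hr_from_lvp(lj)), 0.5)

  flat <- fulcrum:::new_trace((0:1999) / 200, rep(8, 2000), 200, "lvp")
  expect_true(all(is.na(hr_from_lvp(flat)$hr_bpm)))
})

test_that("synthesize-filter-detect-window recovers a stepped profile exactly", {
  prof <- hr_profile(data.frame(
    time_s = c(0, 20, 40),
    hr_bpm = c(60, 80, 100)
  ))
  ecg <- synthesize_ecg(prof, 60, 200, noise_off())
  hrs <- hr_from_peaks_windowed(detect_r_peaks(apply_filters(ecg)), 60)
  truth <- true_hr_series(trace_beat_times(ecg), 60)
  ok <- !is.na(truth$hr_bpm) & !is.na(hrs$hr_bpm)
  expect_equal(hrs$hr_bpm[ok], truth$hr_bpm[ok], tolerance = 1e-3)
  # plateau windows away from the steps report the programmed rates exactly
  expect_equal(hrs$hr_bpm[hrs$window_start_s %in% c(5, 10)], c(60, 60), tolerance = 1e-3)
  expect_equal(hrs$hr_bpm[hrs$window_start_s %in% c(25, 30)], c(80, 80), tolerance = 1e-3)
  expect_equal(hrs$hr_bpm[hrs$window_start_s %in% c(45, 50)], c(100, 100), tolerance = 1e-3)
})
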
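#' FIR bandpass specification
#'
#' The reference heart-rate chain bandpass-filters the ECG with a 24th-order
#' linear-phase high-pass FIR (4 Hz cutoff) cascaded with a 48th-order
#' low-pass FIR (45 Hz cutoff) at 200 samples/s. Order is the classical FIR
#' order, so a filter of order N has N + 1 taps.
#'
#' @param hp_order,lp_order Even, positive filter orders.
#' @param hp_cutoff,lp_cutoff Cutoffs in Hz, `0 < hp_cutoff < lp_cutoff < fs/2`.
#' @param fs Sampling rate, samples/s.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(hp_order = 24, hp_cutoff = 4,
                        lp_order = 48, lp_cutoff = 45, fs = 200) {
  if (hp_order <= 0 || lp_order <= 0 || hp_order %% 2 != 0 || lp_order %% 2 != 0) {
    abort("Filter orders must be even and positive.")
  }
  if (!(hp_cutoff > 0 && hp_cutoff < lp_cutoff && lp_cutoff < fs / 2)) {
    abort("Cutoffs must satisfy 0 < hp_cutoff < lp_cutoff < fs/2 (Nyquist).")
  }
  structure(
    list(
      hp_order = hp_order, hp_cutoff = hp_cutoff,
      lp_order = lp_order, lp_cutoff = lp_cutoff, fs = fs
    ),
    class = "filter_spec"
  )
}

#' Design the linear-phase FIR bandpass pair
#'
#' Hamming windowed-sinc designs (via [signal::fir1()]) with exact gain
#' renormalization: the high-pass taps are shifted so their DC gain is zero
#' to machine precision, and the low-pass taps are scaled to unit DC gain.
#' Both are symmetric, hence exactly linear phase with integer group delay
#' `order/2` samples.
#'
#' @param spec A [filter_spec()].
#' @return A list with tap vectors `hp` and `lp` and the `spec`.
#' @examples
#' taps <- design_fir_bandpass(filter_spec())
#' length(taps$hp) # 25
#' length(taps$lp) # 49
#' @export
design_fir_bandpass <- function(spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- spec$fs / 2
  hp <- signal::fir1(spec$hp_order, spec$hp_cutoff / nyq, type = "high")
  lp <- signal::fir1(spec$lp_order, spec$lp_cutoff / nyq, type = "low")
  hp <- as.numeric(hp) - sum(hp) / length(hp) # zero DC exactly
  lp <- as.numeric(lp) / sum(lp) # unit DC exactly
  list(hp = hp, lp = lp, spec = spec)
}

#' Magnitude response of an FIR tap vector
#'
#' Direct evaluation of `|sum_k h_k exp(-i 2 pi f k / fs)|`.
#'
#' @param taps Numeric tap vector.
#' @param f Frequencies, Hz.
#' @param fs Sampling rate, samples/s.
#' @return Magnitude (linear gain) at each `f`.
#' @export
fir_response <- function(taps, f, fs) {
  k <- seq_along(taps) - 1
  vapply(f, function(ff) Mod(sum(taps * exp(-2i * pi * ff / fs * k))), numeric(1))
}

## Zero-phase application of a symmetric FIR: full convolution, then take
## the centre slice so the integer group delay (ntaps-1)/2 is compensated
## and peak times are unbiased.
apply_fir_centered <- function(x, h) {
  y <- convolve(x, rev(h), type = "open")
  delay <- (length(h) - 1L) / 2L
  y[(delay + 1L):(delay + length(x))]
}

#' Apply the bandpass chain to a trace
#'
#' High-pass then low-pass, each with explicit group-delay compensation, so
#' output length equals input length and R-peak times are not shifted.
#'
#' @param trace A `vns_trace` with sampling rate equal to `spec$fs`.
#' @param spec A [filter_spec()] (or a design from [design_fir_bandpass()]).
#' @return A `vns_trace` with `kind = "filtered"`; generator attributes
#'   (ground-truth beat times) are carried along.
#' @export
apply_filters <- function(trace, spec = filter_spec()) {
  taps <- if (is.list(spec) && !is.null(spec$hp) && !is.null(spec$lp)) {
    spec
  } else {
    design_fir_bandpass(spec)
  }
  fs <- trace_fs(trace)
  if (!isTRUE(all.equal(fs, taps$spec$fs, tolerance = 1e-6))) {
    abort(sprintf(
      "Sampling-rate mismatch: trace fs = %g, filter fs = %g.",
      fs, taps$spec$fs
    ))
  }
  y <- apply_fir_centered(apply_fir_centered(trace$value, taps$hp), taps$lp)
  out <- new_trace(trace$time_s, y, fs, "filtered",
    beat_times = trace_beat_times(trace),
    profile = attr(trace, "profile")
  )
  out
}
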
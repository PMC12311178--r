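#' Stimulation parameters
#'
#' One stimulation setting of the implantable pulse generator: pulse
#' frequency, pulse width (PW), pulse duty cycle, and the pulson pattern
#' chopping each pulse. The duty cycle is the ratio of the summed pulson
#' widths to the total PW, so it is a direct proxy for injected charge.
#'
#' @param frequency Pulse frequency, Hz, in `[1, 20]`.
#' @param pulse_width Total pulse width, microseconds, in `[64, 1024]`.
#' @param duty_cycle Percent of the pulse width occupied by pulsons; one of
#'   12.5, 25, 50, 100.
#' @param n_pulsons Number of equal-width pulsons per pulse (default 2, the
#'   chopped waveform; 1 gives the traditional rectangle and forces zero
#'   spacing).
#' @param pulson_spacing Gap between consecutive pulsons, microseconds.
#'   `NULL` (default) picks the pulson width, shrunk if needed so the
#'   pattern fits inside the pulse width.
#' @param pulson_voltage Regulated pulson amplitude, V, in `[2.6, 3.7]`.
#' @return A list of class `stim_params`.
#' @examples
#' stim_params(20, 1024, 100)
#' @export
stim_params <- function(frequency, pulse_width, duty_cycle, n_pulsons = 2,
                        pulson_spacing = NULL, pulson_voltage = 3.3) {
  if (frequency < 1 || frequency > 20) {
    abort("`frequency` must lie in [1, 20] Hz.")
  }
  if (pulse_width < 64 || pulse_width > 1024) {
    abort("`pulse_width` must lie in [64, 1024] microseconds.")
  }
  if (!any(abs(duty_cycle - c(12.5, 25, 50, 100)) < 1e-9)) {
    abort("`duty_cycle` must be one of 12.5, 25, 50, 100 percent.")
  }
  if (n_pulsons < 1 || n_pulsons != round(n_pulsons)) {
    abort("`n_pulsons` must be a positive integer.")
  }
  if (pulson_voltage < 2.6 || pulson_voltage > 3.7) {
    abort("`pulson_voltage` must lie in [2.6, 3.7] V.")
  }
  if (n_pulsons == 1) {
    if (!is.null(pulson_spacing) && pulson_spacing != 0) {
      abort("With a single pulson the spacing must be zero.")
    }
    pulson_spacing <- 0
  }
  structure(
    list(
      frequency = frequency, pulse_width = pulse_width,
      duty_cycle = duty_cycle, n_pulsons = as.integer(n_pulsons),
      pulson_spacing = pulson_spacing, pulson_voltage = pulson_voltage
    ),
    class = "stim_params"
  )
}

#' Build the pulson pattern of one stimulation pulse
#'
#' `n_pulsons` equal-width pulsons of width `(duty/100) * PW / n_pulsons`,
#' separated by `pulson_spacing`; the whole pattern must fit inside the
#' pulse width. Pulsons narrower than the 5 microsecond hardware minimum are
#' flagged with a warning and a `sub_min_width` attribute.
#'
#' @param params A [stim_params()].
#' @return A tibble of class `pulse_pattern` with columns `pulson`,
#'   `onset_us`, `width_us`, plus attributes `period_ms`, `duty_cycle`
#'   and `sub_min_width`.
#' @examples
#' build_pulse_pattern(stim_params(10, 1024, 50)) # two 256 us pulsons
#' @export
build_pulse_pattern <- function(params) {
  stopifnot(inherits(params, "stim_params"))
  n <- params$n_pulsons
  pw <- params$pulse_width
  width <- (params$duty_cycle / 100) * pw / n
  spacing <- params$pulson_spacing
  if (is.null(spacing)) {
    budget <- if (n > 1) (pw - n * width) / (n - 1) else 0
    spacing <- min(width, budget)
  }
  span <- n * width + (n - 1) * spacing
  if (span > pw + 1e-9) {
    abort(sprintf(
      "pattern overflows pulse width: %d pulson(s) of %g us with %g us spacing span %g us > PW %g us.",
      n, width, spacing, span, pw
    ))
  }
  sub_min <- width < 5
  if (sub_min) {
    warn(sprintf(
      "Pulson width %g us is below the 5 us hardware minimum pulse width.",
      width
    ))
  }
  out <- tibble::tibble(
    pulson = seq_len(n),
    onset_us = (seq_len(n) - 1) * (width + spacing),
    width_us = rep(width, n)
  )
  attr(out, "period_ms") <- 1000 / params$frequency
  attr(out, "duty_cycle") <- params$duty_cycle
  attr(out, "pulson_voltage") <- params$pulson_voltage
  attr(out, "sub_min_width") <- sub_min
  class(out) <- c("pulse_pattern", class(out))
  out
}
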
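#' Configure the simulated subject (dose-response plant)
#'
#' A configurable stand-in for the anesthetized subject: a separable
#' power-law dose-response surface mapping stimulation frequency, duty
#' cycle and pulse width to a steady-state percent HR drop, first-order
#' onset/recovery dynamics, and Gaussian heart-rate variability per 5-s
#' window. The reference calibration reproduces the open-loop anchors:
#' a 13% drop at (20 Hz, 100% duty, 512 us) and well under 2% at low
#' settings.
#'
#' @param baseline_hr Resting heart rate, bpm.
#' @param A_max Maximal bradycardic drop at the reference setting, percent.
#' @param gamma_f,gamma_d,gamma_pw Positive shape exponents of the
#'   frequency, duty-cycle and pulse-width factors.
#' @param f_ref,d_ref,pw_ref Reference setting at which the drop equals
#'   `A_max` (20 Hz, 100%, 512 us).
#' @param tachy_offset Constant offset, percent; a positive value shifts the
#'   surface down so weak stimulation produces mild tachycardia (a synthetic
#'   device for emulating fulcrum crossing; default 0, pure bradycardia).
#' @param tau_on,tau_off Onset and recovery time constants, s.
#' @param hrv_sigma Natural HR variability per 5-s window, bpm (sd).
#' @param seed Default RNG seed used by the run orchestrator.
#' @return A list of class `plant_config`.
#' @export
plant_config <- function(baseline_hr = 80, A_max = 13,
                         gamma_f = 1.2, gamma_d = 0.8, gamma_pw = 0.5,
                         f_ref = 20, d_ref = 100, pw_ref = 512,
                         tachy_offset = 0, tau_on = 3, tau_off = 8,
                         hrv_sigma = 0.5, seed = 1L) {
  if (A_max < 0) abort("`A_max` must be non-negative.")
  if (gamma_f <= 0 || gamma_d <= 0 || gamma_pw <= 0) {
    abort("Shape exponents must be positive.")
  }
  if (tau_on <= 0 || tau_off <= 0) abort("Time constants must be positive.")
  if (hrv_sigma < 0) abort("`hrv_sigma` must be non-negative.")
  structure(
    list(
      baseline_hr = baseline_hr, A_max = A_max,
      gamma_f = gamma_f, gamma_d = gamma_d, gamma_pw = gamma_pw,
      f_ref = f_ref, d_ref = d_ref, pw_ref = pw_ref,
      tachy_offset = tachy_offset, tau_on = tau_on, tau_off = tau_off,
      hrv_sigma = hrv_sigma, seed = as.integer(seed)
    ),
    class = "plant_config"
  )
}

#' Scenario presets for the plant
#'
#' `"reference"` is the open-loop calibration (13% at the reference
#' setting, noise-free); `"reference-noisy"` adds the default 0.5 bpm HRV.
#' `"subject-open"` and `"subject-closed"` rescale `A_max` so the first
#' closed-loop epoch at the adverse initialization (20 Hz, 100%, 1024 us)
#' drops 10% and 6% respectively — the initial reductions seen in the
#' open- and closed-incision recordings — with HRV on. All presets accept
#' overrides via `...`.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [plant_config()].
#' @return A `plant_config`.
#' @export
plant_scenario <- function(name = c(
                             "reference", "reference-noisy",
                             "subject-open", "subject-closed"
                           ), ...) {
  name <- match.arg(name)
  base <- plant_config()
  pw_factor <- (1024 / base$pw_ref)^base$gamma_pw
  args <- switch(name,
    "reference" = list(A_max = 13, hrv_sigma = 0),
    "reference-noisy" = list(A_max = 13, hrv_sigma = 0.5),
    "subject-open" = list(A_max = 10 / pw_factor, hrv_sigma = 0.5),
    "subject-closed" = list(A_max = 6 / pw_factor, hrv_sigma = 0.5)
  )
  do.call(plant_config, modifyList(args, list(...)))
}

#' Steady-state HR response to a stimulation setting
#'
#' `drop = A_max (f/f_ref)^gf (d/d_ref)^gd (PW/pw_ref)^gpw - tachy_offset`,
#' clipped below at `-tachy_offset` (and hence at 0 for the default
#' pure-bradycardia plant). Zero frequency or duty means no stimulation.
#' Strictly increasing in each of frequency, duty cycle and pulse width.
#'
#' @param cfg A [plant_config()].
#' @param params A [stim_params()], or a list with `frequency`,
#'   `duty_cycle`, `pulse_width`.
#' @return Percent HR change (positive = drop/bradycardia, negative =
#'   tachycardia).
#' @examples
#' steady_response(plant_config(), list(frequency = 20, duty_cycle = 100, pulse_width = 512))
#' @export
steady_response <- function(cfg, params) {
  f <- params$frequency
  d <- params$duty_cycle
  pw <- params$pulse_width
  if (f <= 0 || d <= 0) {
    return(0)
  }
  drive <- cfg$A_max * (f / cfg$f_ref)^cfg$gamma_f *
    (d / cfg$d_ref)^cfg$gamma_d * (pw / cfg$pw_ref)^cfg$gamma_pw
  max(drive - cfg$tachy_offset, -cfg$tachy_offset)
}

#' Initial plant state
#' @param cfg A [plant_config()].
#' @return A list of class `plant_state` with `current_drop` (percent) and
#'   elapsed time `t` (s).
#' @export
plant_state <- function(cfg) {
  structure(list(current_drop = 0, t = 0), class = "plant_state")
}

#' Advance the plant dynamics one step
#'
#' First-order relaxation of the percent drop towards `target_drop` with
#' time constant `tau_on` while stimulation is on, and towards 0 with
#' `tau_off` when off.
#'
#' @param state A [plant_state()].
#' @param cfg A [plant_config()].
#' @param target_drop Steady-state drop the stimulation commands, percent.
#' @param dt Step, s.
#' @param stim_on Logical.
#' @return The updated `plant_state`.
#' @export
hr_dynamics_step <- function(state, cfg, target_drop, dt, stim_on) {
  if (dt <= 0) abort("`dt` must be positive.")
  tau <- if (stim_on) cfg$tau_on else cfg$tau_off
  target <- if (stim_on) target_drop else 0
  state$current_drop <- state$current_drop +
    (target - state$current_drop) * (1 - exp(-dt / tau))
  state$t <- state$t + dt
  state
}

#' Simulate the per-window HR of one stimulation epoch
#'
#' One protocol epoch is a 14 s active phase followed by a 66 s rest phase,
#' spanning 16 windows of 5 s on the window clock (stimulation covers
#' windows 1-3, the ON time rounded up to the grid). The drop relaxes
#' through [hr_dynamics_step()] in 5-s steps; each window reports
#' `HR = baseline_hr * (1 - drop/100)` at the window's end, plus HRV noise
#' drawn from the ambient RNG stream.
#'
#' @param state A [plant_state()].
#' @param cfg A [plant_config()].
#' @param params A [stim_params()] (the setting held through the active
#'   phase).
#' @param n_windows Windows per epoch (default 16 = 80 s / 5 s).
#' @param n_on_windows Leading windows with stimulation on (default 3).
#' @param window Window length, s.
#' @return A list: updated `state` and a tibble `windows` with
#'   `window_start_s` (epoch-relative), `hr_bpm`, `drop_pct`, `stim_on`.
#' @export
simulate_epoch_hr <- function(state, cfg, params, n_windows = 16,
                              n_on_windows = 3, window = 5) {
  target <- steady_response(cfg, params)
  starts <- (seq_len(n_windows) - 1) * window
  on <- seq_len(n_windows) <= n_on_windows
  drop <- numeric(n_windows)
  for (k in seq_len(n_windows)) {
    state <- hr_dynamics_step(state, cfg, target, window, on[k])
    drop[k] <- state$current_drop
  }
  hr <- cfg$baseline_hr * (1 - drop / 100)
  if (cfg$hrv_sigma > 0) {
    hr <- hr + rnorm(n_windows, 0, cfg$hrv_sigma)
  }
  list(
    state = state,
    windows = tibble::tibble(
      window_start_s = starts, hr_bpm = hr,
      drop_pct = drop, stim_on = on
    )
  )
}

#' Open-loop dose-response sweep
#'
#' Evaluates the steady-state drop over a frequency x duty-cycle grid at a
#' fixed pulse width — the simulated analogue of an open-loop titration
#' surface.
#'
#' @param cfg A [plant_config()].
#' @param frequencies,duties Grid values (Hz, percent).
#' @param pulse_width Fixed PW, us.
#' @return A tibble `frequency`, `duty_cycle`, `pulse_width`, `drop_pct`.
#' @export
openloop_sweep <- function(cfg, frequencies = c(1, 2, 5, 10, 15, 20),
                           duties = c(12.5, 25, 50, 100), pulse_width = 512) {
  grid <- tidyr::expand_grid(frequency = frequencies, duty_cycle = duties)
  grid$pulse_width <- pulse_width
  grid$drop_pct <- purrr::pmap_dbl(
    grid,
    function(frequency, duty_cycle, pulse_width) {
      steady_response(cfg, list(
        frequency = frequency, duty_cycle = duty_cycle,
        pulse_width = pulse_width
      ))
    }
  )
  grid
}
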
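#' Configure the state-based controller
#'
#' The controller observes the percent HR drop of each active phase and
#' updates exactly one stimulation parameter (duty cycle first, then
#' frequency) per rest phase, stepping down the configured grids under
#' bradycardia and mirroring back up under tachycardia, until the response
#' sits inside the steady band for `consecutive_required` active phases.
#'
#' @param freq_grid Frequency levels, Hz, strictly decreasing, within
#'   `[1, 20]`.
#' @param duty_grid Duty-cycle levels, percent, strictly decreasing, drawn
#'   from {100, 50, 25, 12.5}.
#' @param pw Pulse width held fixed for the run, us.
#' @param threshold_divisor 5 or 10: the bradycardia threshold is the
#'   running maximum observed drop divided by this (one-fifth or one-tenth
#'   of the maximum HR response). Default 10.
#' @param steady_band Steady-state band, percent of baseline, in `[2, 4]`
#'   (default 2.5): responses with `|drop| <= steady_band` count towards
#'   steady state.
#' @param consecutive_required In-band active phases needed to declare
#'   steady state (default 2).
#' @param max_iterations Epoch cap for a run.
#' @param aggregate `"min"` (worst-case bradycardia: drop measured at the
#'   minimum active-phase window HR) or `"mean"`.
#' @return A list of class `controller_config`.
#' @export
controller_config <- function(freq_grid = c(20, 15, 10, 5, 2, 1),
                              duty_grid = c(100, 50, 25, 12.5),
                              pw = 1024, threshold_divisor = 10,
                              steady_band = 2.5, consecutive_required = 2,
                              max_iterations = 30,
                              aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  if (length(freq_grid) == 0 || length(duty_grid) == 0) {
    abort("Parameter grids must be nonempty.")
  }
  if (any(diff(freq_grid) >= 0) || any(diff(duty_grid) >= 0)) {
    abort("Grids must be strictly decreasing.")
  }
  if (any(freq_grid < 1 | freq_grid > 20)) {
    abort("`freq_grid` must lie within [1, 20] Hz.")
  }
  if (!all(duty_grid %in% c(100, 50, 25, 12.5))) {
    abort("`duty_grid` values must come from {100, 50, 25, 12.5}.")
  }
  if (!threshold_divisor %in% c(5, 10)) {
    abort("`threshold_divisor` must be 5 or 10.")
  }
  if (steady_band < 2 || steady_band > 4) {
    abort("`steady_band` must lie in [2, 4] percent.")
  }
  structure(
    list(
      freq_grid = freq_grid, duty_grid = duty_grid, pw = pw,
      threshold_divisor = threshold_divisor, steady_band = steady_band,
      consecutive_required = consecutive_required,
      max_iterations = max_iterations, aggregate = aggregate
    ),
    class = "controller_config"
  )
}

#' Bradycardia threshold from the maximum observed response
#'
#' One-fifth or one-tenth of the maximum HR response observed so far.
#'
#' @param max_observed_drop Running maximum percent drop (>= 0).
#' @param divisor 5 or 10.
#' @return Threshold in percent.
#' @export
compute_threshold <- function(max_observed_drop, divisor = 10) {
  if (max_observed_drop < 0) abort("`max_observed_drop` must be >= 0.")
  max_observed_drop / divisor
}

#' Percent HR drop of one active phase
#'
#' Worst-case aggregation by default: the drop is measured at the minimum
#' active-phase window HR, `(baseline - min HR) / baseline * 100`; negative
#' values indicate tachycardia. Returns `NA` (no measurement) when every
#' active-phase window is missing.
#'
#' @param epoch_windows A tibble with `hr_bpm` and `stim_on` (as produced
#'   by [simulate_epoch_hr()]), or a numeric vector of active-phase HRs.
#' @param baseline Baseline HR, bpm.
#' @param aggregate `"min"` or `"mean"`.
#' @return Percent drop (positive = bradycardia), or `NA_real_`.
#' @export
measure_response <- function(epoch_windows, baseline,
                             aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  hr <- if (is.data.frame(epoch_windows)) {
    epoch_windows$hr_bpm[epoch_windows$stim_on]
  } else {
    epoch_windows
  }
  hr <- hr[!is.na(hr)]
  if (!length(hr)) {
    return(NA_real_)
  }
  agg <- if (aggregate == "min") min(hr) else mean(hr)
  (baseline - agg) / baseline * 100
}

#' Classify an active-phase response
#'
#' Bradycardia when the drop exceeds the larger of the bradycardia
#' threshold and the steady band; tachycardia for the mirror condition;
#' steady otherwise. A missing drop classifies as `"no_measurement"`
#' (fail-safe hold).
#'
#' @param drop Percent drop (positive = bradycardia), possibly `NA`.
#' @param threshold Current bradycardia threshold, percent.
#' @param steady_band Steady band, percent.
#' @return One of `"bradycardia"`, `"tachycardia"`, `"steady"`,
#'   `"no_measurement"`.
#' @export
classify_response <- function(drop, threshold, steady_band = 2.5) {
  if (is.na(drop)) {
    return("no_measurement")
  }
  trip <- max(threshold, steady_band)
  if (drop > trip) {
    "bradycardia"
  } else if (drop < -trip) {
    "tachycardia"
  } else {
    "steady"
  }
}

controller_init <- function(cfg) {
  structure(
    list(
      freq_i = 1L, duty_i = 1L, # grid indices; 1 = highest level
      down_stack = character(), steady_count = 0L, n_updates = 0L,
      max_observed_drop = 0, floor_flag = FALSE, ceiling_flag = FALSE
    ),
    class = "controller_state"
  )
}

controller_params <- function(state, cfg) {
  stim_params(
    frequency = cfg$freq_grid[state$freq_i],
    pulse_width = cfg$pw,
    duty_cycle = cfg$duty_grid[state$duty_i]
  )
}

#' One controller decision
#'
#' Bradycardia de-escalates: duty cycle steps down one grid level; when the
#' duty grid is exhausted the frequency steps down; at the joint floor the
#' controller holds and flags it. Tachycardia inverts the most recent
#' down-step (mirror rule), saturating at the initial ceiling. Steady and
#' no-measurement hold. Exactly one parameter changes per call, or none on
#' hold.
#'
#' @param state A controller state (internal; created by the run loop).
#' @param cls A classification from [classify_response()].
#' @param cfg A [controller_config()].
#' @return The updated state with fields `last_action` (one of
#'   `"duty_down"`, `"freq_down"`, `"duty_up"`, `"freq_up"`, `"hold"`) and
#'   the new grid indices.
#' @export
next_params <- function(state, cls, cfg) {
  action <- "hold"
  if (cls == "bradycardia") {
    if (state$duty_i < length(cfg$duty_grid)) {
      state$duty_i <- state$duty_i + 1L
      action <- "duty_down"
    } else if (state$freq_i < length(cfg$freq_grid)) {
      state$freq_i <- state$freq_i + 1L
      action <- "freq_down"
    } else {
      state$floor_flag <- TRUE
    }
    if (action != "hold") {
      state$down_stack <- c(state$down_stack, sub("_down", "", action))
    }
  } else if (cls == "tachycardia") {
    last <- if (length(state$down_stack)) tail(state$down_stack, 1) else NA
    if (!is.na(last) && last == "freq" && state$freq_i > 1L) {
      state$freq_i <- state$freq_i - 1L
      action <- "freq_up"
      state$down_stack <- head(state$down_stack, -1)
    } else if (state$duty_i > 1L) {
      state$duty_i <- state$duty_i - 1L
      action <- "duty_up"
      if (length(state$down_stack)) {
        state$down_stack <- head(state$down_stack, -1)
      }
    } else if (state$freq_i > 1L) {
      state$freq_i <- state$freq_i - 1L
      action <- "freq_up"
    } else {
      state$ceiling_flag <- TRUE
    }
  }
  if (action != "hold") state$n_updates <- state$n_updates + 1L
  state$last_action <- action
  state
}

#' Has the run reached steady state?
#'
#' True once the active-phase drop has stayed inside the steady band for
#' `consecutive_required` consecutive epochs.
#'
#' @param state A controller state.
#' @param cfg A [controller_config()].
#' @return Logical.
#' @export
is_steady <- function(state, cfg) {
  state$steady_count >= cfg$consecutive_required
}
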
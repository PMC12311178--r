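#' Run one closed-loop stimulation session
#'
#' Orchestrates the 14 s ON / 66 s OFF protocol on a 5-s window clock:
#' plant -> (optionally ECG synthesis -> HR extraction) -> controller ->
#' plant, starting from the adverse initialization (the highest levels of
#' the configured grids) and stopping at steady state, a grid floor, an
#' abort, or the epoch cap. A 30 s pre-stimulation rest period supplies the
#' first baseline.
#'
#' In `direct_hr` mode the plant's per-window HR values feed the controller
#' directly; in `full_stack` mode each epoch's HR is re-derived by
#' synthesizing an ECG from the plant trajectory and decoding it through
#' the FIR + R-peak + windowed-median chain, exercising the whole pipeline.
#'
#' @param plant_cfg A [plant_config()] or [plant_scenario()].
#' @param controller_cfg A [controller_config()].
#' @param mode `"direct_hr"` (default) or `"full_stack"`.
#' @param seed Integer seed; identical seeds give identical runs.
#' @param fs Sampling rate for `full_stack` ECG synthesis.
#' @param noise A [noise_config()] for `full_stack` synthesis
#'   (default noiseless; the plant's HRV already perturbs the windows).
#' @param abort_drop Hard safety limit, percent: a measured drop beyond it
#'   terminates the run with status `"aborted"` (the automated stand-in for
#'   manual intervention).
#' @param pre_rest_s Pre-stimulation rest, s (default 30).
#' @return An object of class `vns_run`: configs, seed, `status` (one of
#'   `"steady"`, `"floor_reached"`, `"max_iterations"`, `"aborted"`),
#'   `n_updates`, `first_drop`, `last_drop`, an `epochs` tibble (one row
#'   per stimulation epoch) and a `windows` tibble (one row per 5-s
#'   window, absolute time).
#' @examples
#' run <- run_closed_loop(plant_scenario("reference"), controller_config(), seed = 1)
#' run$status
#' run$epochs[, c("epoch", "frequency", "duty_cycle", "drop", "action")]
#' @export
run_closed_loop <- function(plant_cfg, controller_cfg = controller_config(),
                            mode = c("direct_hr", "full_stack"),
                            seed = plant_cfg$seed, fs = 200,
                            noise = noise_off(), abort_drop = 30,
                            pre_rest_s = 30) {
  mode <- match.arg(mode)
  stopifnot(inherits(plant_cfg, "plant_config"), inherits(controller_cfg, "controller_config"))
  if (fs < 100) abort("`fs` must be at least 100 samples/s.")
  set.seed(as.integer(seed))
  window <- 5
  n_pre <- floor(pre_rest_s / window)
  if (n_pre < 2) abort("`pre_rest_s` must cover at least two windows.")

  decode_epoch <- function(hr_windows, duration, epoch_seed) {
    prof <- hr_profile(tibble::tibble(
      time_s = (seq_along(hr_windows) - 1) * window,
      hr_bpm = pmin(pmax(hr_windows, 21), 299)
    ))
    nz <- noise
    nz$seed <- nz$seed + epoch_seed
    ecg <- synthesize_ecg(prof, duration, fs, nz)
    peaks <- detect_r_peaks(apply_filters(ecg, filter_spec(fs = fs)))
    hr_from_peaks_windowed(peaks, duration, window)$hr_bpm
  }

  ## Pre-stimulation rest: plant at baseline with HRV.
  pre_hr <- plant_cfg$baseline_hr + if (plant_cfg$hrv_sigma > 0) {
    rnorm(n_pre, 0, plant_cfg$hrv_sigma)
  } else {
    rep(0, n_pre)
  }
  if (mode == "full_stack") {
    pre_hr <- decode_epoch(pre_hr, n_pre * window, 0L)
  }
  baseline <- mean(tail(pre_hr[!is.na(pre_hr)], 2))

  cstate <- controller_init(controller_cfg)
  pstate <- plant_state(plant_cfg)
  status <- "max_iterations"
  epochs <- list()
  win_rows <- list(tibble::tibble(
    epoch = 0L, window_start_s = (seq_len(n_pre) - 1) * window,
    hr_bpm = pre_hr, stim_on = FALSE
  ))

  for (e in seq_len(controller_cfg$max_iterations)) {
    params <- controller_params(cstate, controller_cfg)
    res <- simulate_epoch_hr(pstate, plant_cfg, params, window = window)
    pstate <- res$state
    win <- res$windows
    hr_used <- win$hr_bpm
    if (mode == "full_stack") {
      hr_used <- decode_epoch(hr_used, nrow(win) * window, e)
    }
    drop <- measure_response(
      tibble::tibble(hr_bpm = hr_used, stim_on = win$stim_on),
      baseline, controller_cfg$aggregate
    )
    if (!is.na(drop)) {
      cstate$max_observed_drop <- max(cstate$max_observed_drop, drop)
      cstate$steady_count <- if (abs(drop) <= controller_cfg$steady_band) {
        cstate$steady_count + 1L
      } else {
        0L
      }
    }
    threshold <- compute_threshold(
      cstate$max_observed_drop,
      controller_cfg$threshold_divisor
    )
    cls <- classify_response(drop, threshold, controller_cfg$steady_band)
    win_rows[[e + 1L]] <- tibble::tibble(
      epoch = e, window_start_s = pre_rest_s + (e - 1) * nrow(win) * window +
        win$window_start_s,
      hr_bpm = hr_used, stim_on = win$stim_on
    )
    rec <- tibble::tibble(
      epoch = e, frequency = params$frequency, duty_cycle = params$duty_cycle,
      pulse_width = params$pulse_width, baseline = baseline, drop = drop,
      threshold = threshold, class = cls,
      steady_count = cstate$steady_count, action = NA_character_
    )
    if (is_steady(cstate, controller_cfg)) {
      rec$action <- "hold"
      epochs[[e]] <- rec
      status <- "steady"
      break
    }
    if (!is.na(drop) && abs(drop) > abort_drop) {
      rec$action <- "abort"
      epochs[[e]] <- rec
      status <- "aborted"
      break
    }
    cstate <- next_params(cstate, cls, controller_cfg)
    rec$action <- cstate$last_action
    epochs[[e]] <- rec
    if (cstate$floor_flag && cls == "bradycardia") {
      status <- "floor_reached"
      break
    }
    rest_hr <- hr_used[!win$stim_on & !is.na(hr_used)]
    if (length(rest_hr) >= 2) {
      baseline <- mean(tail(rest_hr, 2))
    } # else keep the previous baseline (fail-safe)
  }

  epochs <- dplyr::bind_rows(epochs)
  drops <- epochs$drop
  structure(
    list(
      schema_version = 1L,
      plant_cfg = plant_cfg, controller_cfg = controller_cfg,
      mode = mode, seed = as.integer(seed), status = status,
      n_updates = cstate$n_updates,
      first_drop = drops[1], last_drop = drops[length(drops)],
      epochs = epochs, windows = dplyr::bind_rows(win_rows)
    ),
    class = "vns_run"
  )
}

#' @export
print.vns_run <- function(x, ...) {
  cat(sprintf(
    "Closed-loop VNS run (%s, seed %d): %d epochs, %d updates, status %s\n",
    x$mode, x$seed, nrow(x$epochs), x$n_updates, x$status
  ))
  cat(sprintf(
    "  first drop %.2f%%, last drop %.2f%%\n",
    x$first_drop, x$last_drop
  ))
  invisible(x)
}

#' @rdname run_closed_loop
#' @param x A `vns_run`.
#' @param ... Unused.
#' @return `tidy()` returns the per-epoch tibble; `glance()` a one-row run
#'   summary.
#' @export
tidy.vns_run <- function(x, ...) x$epochs

#' @rdname run_closed_loop
#' @export
glance.vns_run <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, seed = x$seed, status = x$status,
    n_epochs = nrow(x$epochs), n_updates = x$n_updates,
    first_drop = x$first_drop, last_drop = x$last_drop
  )
}

run_required_fields <- c(
  "schema_version", "plant_cfg", "controller_cfg", "mode", "seed", "status",
  "n_updates", "first_drop", "last_drop", "epochs", "windows"
)

#' Persist and reload run records
#'
#' A `vns_run` serializes to JSON (full precision, schema-versioned) so
#' that `read_run_record(write_run_record(r))` reproduces the run record.
#' `write_run_windows_csv()` additionally emits the per-window HR table as
#' CSV for external tooling.
#'
#' @param run A `vns_run`.
#' @param path Output path (JSON for records, CSV for windows).
#' @return `read_run_record()` returns a `vns_run`; writers return `path`
#'   invisibly.
#' @export
write_run_record <- function(run, path) {
  stopifnot(inherits(run, "vns_run"))
  x <- unclass(run)
  x$plant_cfg <- unclass(x$plant_cfg)
  x$controller_cfg <- unclass(x$controller_cfg)
  jsonlite::write_json(x, path,
    auto_unbox = TRUE, digits = NA,
    null = "null", na = "null"
  )
  invisible(path)
}

#' @rdname write_run_record
#' @export
read_run_record <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (f in run_required_fields) {
    if (is.null(x[[f]])) {
      abort(sprintf("Malformed run record: missing field `%s`.", f))
    }
  }
  if (x$schema_version != 1L) {
    abort(sprintf("Unsupported run-record schema version %s.", x$schema_version))
  }
  x$plant_cfg <- structure(x$plant_cfg, class = "plant_config")
  x$controller_cfg <- structure(x$controller_cfg, class = "controller_config")
  x$epochs <- tibble::as_tibble(x$epochs)
  x$windows <- tibble::as_tibble(x$windows)
  x$seed <- as.integer(x$seed)
  x$schema_version <- as.integer(x$schema_version)
  x$n_updates <- as.integer(x$n_updates)
  structure(x[run_required_fields], class = "vns_run")
}

#' @rdname write_run_record
#' @export
write_run_windows_csv <- function(run, path) {
  write.csv(as.data.frame(run$windows), path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Top-level keys: `plant`, `controller`, `mode`, `seed`. Sub-keys must
#' match the arguments of [plant_config()] / [controller_config()]; unknown
#' keys anywhere are rejected (fail-fast validation).
#'
#' @param path YAML file path.
#' @return A list with `plant_cfg`, `controller_cfg`, `mode`, `seed`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- c("plant", "controller", "mode", "seed", "scenario")
  unknown <- setdiff(names(y), allowed)
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key(s): %s.", paste(unknown, collapse = ", ")))
  }
  check_args <- function(given, fn, where) {
    bad <- setdiff(names(given), names(formals(fn)))
    if (length(bad)) {
      abort(sprintf(
        "Unknown %s key(s): %s.", where,
        paste(bad, collapse = ", ")
      ))
    }
  }
  plant_args <- y$plant %||% list()
  check_args(plant_args, plant_config, "plant")
  plant_cfg <- if (!is.null(y$scenario)) {
    do.call(plant_scenario, c(list(name = y$scenario), plant_args))
  } else {
    do.call(plant_config, plant_args)
  }
  ctrl_args <- y$controller %||% list()
  check_args(ctrl_args, controller_config, "controller")
  list(
    plant_cfg = plant_cfg,
    controller_cfg = do.call(controller_config, ctrl_args),
    mode = y$mode %||% "direct_hr",
    seed = as.integer(y$seed %||% plant_cfg$seed)
  )
}
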
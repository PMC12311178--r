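#' Plot a sampled trace
#'
#' @param object A `vns_trace`.
#' @param window Optional numeric `c(from, to)` in seconds to zoom.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vns_trace <- function(object, window = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(window)) {
    df <- dplyr::filter(df, .data$time_s >= window[1], .data$time_s <= window[2])
  }
  ylab <- switch(attr(object, "kind"),
    ecg = "ECG (mV)",
    lvp = "LVP (mmHg)",
    filtered = "Filtered ECG (mV)",
    "Signal"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot a windowed HR series
#'
#' @param object An `hr_series`.
#' @param ... Unused.
#' @return A ggplot (missing windows appear as gaps).
#' @export
autoplot.hr_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$window_start_s, .data$hr_bpm)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::labs(x = "Window start (s)", y = "HR (bpm, 5-s median)") +
    ggplot2::theme_minimal()
}

#' Nyquist plot of an impedance spectrum
#'
#' Real part against negative imaginary part; the RC cuff model traces a
#' semicircle of diameter R2 offset by R1.
#'
#' @param object An `impedance_spectrum`.
#' @param fit Optional `circuit_fit` whose model curve is overlaid.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.impedance_spectrum <- function(object, fit = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$re_ohm / 1e3, -.data$im_ohm / 1e3)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = expression(paste("Re Z (k", Omega, ")")),
      y = expression(paste("-Im Z (k", Omega, ")"))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    f <- 10^seq(0, 4, length.out = 200)
    z <- circuit_impedance(fit$circuit, f, fit$model)
    p <- p + ggplot2::geom_path(
      data = tibble::tibble(re_ohm = Re(z), im_ohm = Im(z)),
      colour = "firebrick", linewidth = 0.4
    )
  }
  p
}

#' Plot a closed-loop run
#'
#' Per-window HR with the active phases shaded, plus the drop measured in
#' each epoch and the parameter schedule — the standard summary figure for
#' a convergence run.
#'
#' @param object A `vns_run`.
#' @param ... Unused.
#' @return A ggplot of per-window HR with shaded active phases.
#' @export
autoplot.vns_run <- function(object, ...) {
  w <- tibble::as_tibble(object$windows)
  shade <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(w, .data$stim_on), .data$epoch),
    xmin = min(.data$window_start_s), xmax = max(.data$window_start_s) + 5,
    .groups = "drop"
  )
  ggplot2::ggplot(w, ggplot2::aes(.data$window_start_s, .data$hr_bpm)) +
    ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15
    ) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::labs(
      x = "Time (s)", y = "HR (bpm, 5-s median)",
      title = sprintf(
        "Closed-loop run: %d updates, status %s",
        object$n_updates, object$status
      )
    ) +
    ggplot2::theme_minimal()
}

#' Tile plot of an open-loop dose-response sweep
#'
#' @param sweep Output of [openloop_sweep()].
#' @return A ggplot heat map of percent drop over frequency x duty cycle.
#' @export
plot_openloop_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(
    factor(.data$frequency), factor(.data$duty_cycle),
    fill = .data$drop_pct
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "HR drop (%)") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Duty cycle (%)") +
    ggplot2::theme_minimal()
}
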
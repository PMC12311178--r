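#' Nerve-cuff equivalent-circuit parameters
#'
#' The electrode-nerve interface is modelled as a series access resistance
#' R1 (which includes the ~330 ohm electrode itself) in front of a parallel
#' R2 || C1 block; the non-ideal-capacitor variant replaces C1 with a
#' constant phase element (CPE) of admittance `Q * (j w)^alpha`.
#'
#' @param R1 Series (access) resistance, ohm.
#' @param R2 Parallel resistance, ohm.
#' @param C1 Parallel capacitance, farad (RC model).
#' @param cpe_Q CPE magnitude, S s^alpha (CPE model).
#' @param cpe_alpha CPE exponent in (0, 1]; 1 recovers an ideal capacitor.
#' @return A list of class `circuit_params`.
#' @examples
#' circuit_params(1580, 44e3, 2.6e-6) # cohort median cuff load
#' @export
circuit_params <- function(R1, R2, C1 = NULL, cpe_Q = NULL, cpe_alpha = NULL) {
  if (R1 <= 0 || R2 <= 0) abort("Resistances must be positive.")
  if (is.null(C1) && is.null(cpe_Q)) {
    abort("Provide either `C1` (RC model) or `cpe_Q` + `cpe_alpha` (CPE model).")
  }
  if (!is.null(C1) && C1 <= 0) abort("`C1` must be positive.")
  if (!is.null(cpe_Q)) {
    if (cpe_Q <= 0) abort("`cpe_Q` must be positive.")
    if (is.null(cpe_alpha) || cpe_alpha <= 0 || cpe_alpha > 1) {
      abort("`cpe_alpha` must lie in (0, 1].")
    }
  }
  structure(
    list(R1 = R1, R2 = R2, C1 = C1, cpe_Q = cpe_Q, cpe_alpha = cpe_alpha),
    class = "circuit_params"
  )
}

#' Complex impedance of the cuff-load model
#'
#' RC model: `Z(w) = R1 + R2 / (1 + j w R2 C1)`.
#' CPE model: `Z(w) = R1 + R2 / (1 + (j w)^alpha R2 Q)`.
#'
#' @param circuit A [circuit_params()].
#' @param f Frequencies, Hz (vectorized).
#' @param model `"rc"` or `"cpe"`.
#' @return Complex impedance in ohm at each `f`.
#' @export
circuit_impedance <- function(circuit, f, model = c("rc", "cpe")) {
  model <- match.arg(model)
  if (any(f <= 0)) abort("Frequencies must be positive.")
  w <- 2 * pi * f
  if (model == "rc") {
    if (is.null(circuit$C1)) abort("RC model requires `C1`.")
    circuit$R1 + circuit$R2 / (1 + 1i * w * circuit$R2 * circuit$C1)
  } else {
    if (is.null(circuit$cpe_Q)) abort("CPE model requires `cpe_Q` and `cpe_alpha`.")
    circuit$R1 + circuit$R2 / (1 + (1i * w)^circuit$cpe_alpha * circuit$R2 * circuit$cpe_Q)
  }
}

#' Default EIS frequency grid
#'
#' Log-spaced points between 1 Hz and 10 kHz, the measurement band of the
#' cuff-impedance protocol.
#'
#' @param points_per_decade Density of the grid (default 10).
#' @return Frequencies in Hz.
#' @export
eis_grid <- function(points_per_decade = 10) {
  10^seq(0, 4, by = 1 / points_per_decade)
}

#' Simulate an impedance spectrum
#'
#' Pointwise model impedance with optional proportional complex noise:
#' independent Gaussian perturbations of relative size `noise_sigma` on the
#' real and imaginary parts, scaled by `|Z|`.
#'
#' @param circuit A [circuit_params()].
#' @param f_grid Frequencies, Hz, within `[1, 1e4]`; default [eis_grid()].
#' @param noise_sigma Relative noise level (0 = exact model values).
#' @param seed Integer seed for the noise draws.
#' @param model `"rc"` or `"cpe"`.
#' @return A tibble of class `impedance_spectrum` with `freq_hz`, `re_ohm`,
#'   `im_ohm`.
#' @export
simulate_spectrum <- function(circuit, f_grid = eis_grid(), noise_sigma = 0,
                              seed = 1L, model = c("rc", "cpe")) {
  model <- match.arg(model)
  if (any(f_grid < 1 - 1e-9 | f_grid > 1e4 + 1e-6)) {
    abort("`f_grid` must lie within [1, 1e4] Hz.")
  }
  if (any(diff(f_grid) <= 0)) abort("`f_grid` must be strictly increasing.")
  z <- circuit_impedance(circuit, f_grid, model)
  if (noise_sigma > 0) {
    z <- z + with_local_seed(seed, {
      mag <- Mod(z)
      complex(
        real = rnorm(length(z), 0, noise_sigma * mag),
        imaginary = rnorm(length(z), 0, noise_sigma * mag)
      )
    })
  }
  out <- tibble::tibble(freq_hz = f_grid, re_ohm = Re(z), im_ohm = Im(z))
  attr(out, "model") <- model
  class(out) <- c("impedance_spectrum", class(out))
  out
}

#' Read and write impedance spectra as CSV
#' @param spectrum An `impedance_spectrum`.
#' @param path File path; header `freq_hz,re_ohm,im_ohm`.
#' @return `read_spectrum_csv()` returns an `impedance_spectrum`.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  write.csv(as.data.frame(spectrum[, c("freq_hz", "re_ohm", "im_ohm")]),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- read.csv(path)
  need <- c("freq_hz", "re_ohm", "im_ohm")
  if (!all(need %in% names(df))) {
    abort("Spectrum CSV must have columns freq_hz, re_ohm, im_ohm.")
  }
  out <- tibble::as_tibble(df[need])
  class(out) <- c("impedance_spectrum", class(out))
  out
}

## Modulus-weighted stacked residual: spectra span decades in |Z|, so each
## point's real and imaginary residuals are divided by the measured modulus.
eis_residuals <- function(theta, spectrum, model) {
  circ <- theta_to_circuit(theta, model)
  z <- circuit_impedance(circ, spectrum$freq_hz, model)
  zm <- complex(real = spectrum$re_ohm, imaginary = spectrum$im_ohm)
  w <- 1 / pmax(Mod(zm), .Machine$double.eps)
  c((Re(zm) - Re(z)) * w, (Im(zm) - Im(z)) * w)
}

theta_to_circuit <- function(theta, model) {
  theta <- unname(theta)
  if (model == "rc") {
    circuit_params(R1 = theta[1], R2 = theta[2], C1 = theta[3])
  } else {
    circuit_params(R1 = theta[1], R2 = theta[2], cpe_Q = theta[3], cpe_alpha = theta[4])
  }
}

circuit_to_theta <- function(circuit, model) {
  if (model == "rc") {
    c(R1 = circuit$R1, R2 = circuit$R2, C1 = circuit$C1)
  } else {
    c(
      R1 = circuit$R1, R2 = circuit$R2, cpe_Q = circuit$cpe_Q,
      cpe_alpha = circuit$cpe_alpha
    )
  }
}

num_jacobian <- function(fn, theta, ...) {
  r0 <- fn(theta, ...)
  J <- matrix(0, length(r0), length(theta))
  for (j in seq_along(theta)) {
    h <- max(1e-7 * abs(theta[j]), 1e-12)
    tp <- theta
    tp[j] <- tp[j] + h
    J[, j] <- (fn(tp, ...) - r0) / h
  }
  J
}

#' Fit an equivalent circuit to an impedance spectrum
#'
#' Damped Gauss-Newton (Levenberg-Marquardt) minimization of the
#' modulus-weighted stacked real/imaginary residuals, with the classical
#' damping schedule: lambda starts at `lambda_init` and is divided or
#' multiplied by `lambda_scale` after each accepted or rejected step.
#' Per-parameter relative standard errors come from the Jacobian-based
#' covariance at the optimum.
#'
#' @param spectrum An `impedance_spectrum` (at least twice as many points as
#'   parameters).
#' @param model `"rc"` (R1, R2, C1) or `"cpe"` (R1, R2, Q, alpha).
#' @param init A [circuit_params()] initial guess.
#' @param lambda_init,lambda_scale Damping schedule (defaults 0.01 and 10).
#' @param max_iter Iteration cap; exceeding it returns a result flagged
#'   `converged = FALSE` rather than an error.
#' @param tol Relative step / cost-change convergence tolerance.
#' @return An object of class `circuit_fit`: the fitted [circuit_params()],
#'   a `parameters` tibble (`term`, `estimate`, `rel_std_error`),
#'   `converged`, `n_iter`, and the weighted residual sum of squares.
#'   [tidy()] and [glance()] methods are provided.
#' @examples
#' truth <- circuit_params(1580, 44e3, 2.6e-6)
#' sp <- simulate_spectrum(truth)
#' fit <- fit_circuit(sp, init = circuit_params(3160, 88e3, 5.2e-6))
#' tidy(fit)
#' @export
fit_circuit <- function(spectrum, model = c("rc", "cpe"), init,
                        lambda_init = 0.01, lambda_scale = 10,
                        max_iter = 200, tol = 1e-12) {
  model <- match.arg(model)
  theta <- circuit_to_theta(init, model)
  npar <- length(theta)
  if (nrow(spectrum) < 2 * npar) {
    abort("Need at least twice as many spectrum points as parameters.")
  }
  r <- eis_residuals(theta, spectrum, model)
  cost <- sum(r^2)
  lambda <- lambda_init
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- num_jacobian(eis_residuals, theta, spectrum = spectrum, model = model)
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    ## Marquardt scaling: solve in variables normalized by sqrt(diag(JtJ))
    ## so parameters spanning many orders of magnitude stay well-conditioned.
    d <- sqrt(pmax(diag(JtJ), .Machine$double.eps))
    M0 <- JtJ / (d %o% d)
    accepted <- FALSE
    for (trial in 1:50) {
      M <- M0 + lambda * diag(npar)
      step <- tryCatch(-drop(solve(M, g / d)) / d, error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta + step
        if (all(cand > 0) && (model != "cpe" || cand[4] <= 1)) {
          rc <- eis_residuals(cand, spectrum, model)
          if (sum(rc^2) < cost) {
            theta <- cand
            r <- rc
            old_cost <- cost
            cost <- sum(rc^2)
            lambda <- lambda / lambda_scale
            accepted <- TRUE
            if (max(abs(step) / pmax(abs(theta), 1e-300)) < tol ||
              old_cost - cost < tol * (cost + 1e-300)) {
              converged <- TRUE
            }
            break
          }
        }
      }
      lambda <- lambda * lambda_scale
    }
    if (!accepted) {
      converged <- TRUE # no improving step: at a (local) optimum
      break
    }
    if (converged) break
  }
  J <- num_jacobian(eis_residuals, theta, spectrum = spectrum, model = model)
  dof <- max(length(r) - npar, 1)
  sigma2 <- cost / dof
  JtJ <- crossprod(J)
  d <- sqrt(pmax(diag(JtJ), .Machine$double.eps))
  cov <- tryCatch(
    sigma2 * (solve(JtJ / (d %o% d)) / (d %o% d)),
    error = function(e) matrix(NA_real_, npar, npar)
  )
  rel_se <- sqrt(pmax(diag(cov), 0)) / abs(theta)
  pars <- tibble::tibble(
    term = names(theta), estimate = as.numeric(theta),
    rel_std_error = as.numeric(rel_se)
  )
  structure(
    list(
      circuit = theta_to_circuit(theta, model), parameters = pars,
      model = model, converged = converged, n_iter = iter, rss = cost,
      n_points = nrow(spectrum)
    ),
    class = "circuit_fit"
  )
}

#' @export
print.circuit_fit <- function(x, ...) {
  cat(sprintf(
    "Equivalent-circuit fit (%s model): %s after %d iterations, weighted RSS %.3g\n",
    x$model, if (x$converged) "converged" else "NOT converged", x$n_iter, x$rss
  ))
  print(x$parameters)
  invisible(x)
}

#' @rdname fit_circuit
#' @param x A `circuit_fit`.
#' @param ... Unused.
#' @export
tidy.circuit_fit <- function(x, ...) x$parameters

#' @rdname fit_circuit
#' @export
glance.circuit_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, converged = x$converged, n_iter = x$n_iter,
    rss = x$rss, n_points = x$n_points
  )
}

#' Pulse-onset current and RC transient through the cuff load
#'
#' At pulson onset the double-layer capacitance is uncharged and shorts R2,
#' so the instantaneous current is `V / R1`; it then relaxes towards
#' `V / (R1 + R2)` with time constant `tau = C1 R1 R2 / (R1 + R2)`.
#'
#' @param params A [stim_params()] (supplies the pulson voltage and width).
#' @param circuit A [circuit_params()] with `C1`.
#' @param n_points Samples of the transient over one pulson.
#' @return A list: `peak_mA` (onset current), `steady_mA`, `tau_us`, and a
#'   tibble `transient` (`t_us`, `i_mA`) over one pulson.
#' @examples
#' peak_current(stim_params(20, 1024, 100), circuit_params(1100, 44e3, 2.6e-6))$peak_mA
#' @export
peak_current <- function(params, circuit, n_points = 200) {
  v <- params$pulson_voltage
  r1 <- circuit$R1
  r2 <- circuit$R2
  c1 <- circuit$C1 %||% 0
  pat <- suppressWarnings(build_pulse_pattern(params))
  w_us <- pat$width_us[1]
  i0 <- v / r1
  i_inf <- v / (r1 + r2)
  tau_s <- c1 * r1 * r2 / (r1 + r2)
  t_us <- seq(0, w_us, length.out = n_points)
  i_a <- if (tau_s > 0) {
    i_inf + (i0 - i_inf) * exp(-(t_us * 1e-6) / tau_s)
  } else {
    rep(i_inf, n_points)
  }
  list(
    peak_mA = i0 * 1e3, steady_mA = i_inf * 1e3, tau_us = tau_s * 1e6,
    transient = tibble::tibble(t_us = t_us, i_mA = i_a * 1e3)
  )
}

#' Charge injected per stimulation pulse
#'
#' Integral of the RC transient current over every pulson of one pulse,
#' with the double layer discharged between pulsons (charge-balanced
#' stimulators discharge between phases). Closed form per pulson of width
#' w: `q = V w / (R1 + R2) + (V/R1 - V/(R1+R2)) tau (1 - exp(-w/tau))`.
#' Monotone increasing in duty cycle and pulse width.
#'
#' @inheritParams peak_current
#' @return Charge in microcoulombs.
#' @export
charge_per_pulse <- function(params, circuit) {
  v <- params$pulson_voltage
  r1 <- circuit$R1
  r2 <- circuit$R2
  c1 <- circuit$C1 %||% 0
  pat <- suppressWarnings(build_pulse_pattern(params))
  tau <- c1 * r1 * r2 / (r1 + r2)
  w_s <- pat$width_us * 1e-6
  q <- v / (r1 + r2) * w_s +
    if (tau > 0) (v / r1 - v / (r1 + r2)) * tau * (1 - exp(-w_s / tau)) else 0
  sum(q) * 1e6
}
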
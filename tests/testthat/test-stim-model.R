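test_that("pulse patterns honour the duty-cycle definition", {
  # traditional rectangle: one pulson spanning the whole PW
  rect <- build_pulse_pattern(stim_params(10, 512, 100, n_pulsons = 1))
  expect_equal(nrow(rect), 1)
  expect_equal(rect$width_us, 512)
  expect_equal(rect$onset_us, 0)

  # two pulsons at 50% of 1024 us: 256 us each, summing to half the PW
  two <- build_pulse_pattern(stim_params(10, 1024, 50))
  expect_equal(two$width_us, c(256, 256))
  expect_equal(sum(two$width_us) / 1024, 0.5)

  # 12.5% of 64 us split in two: 4 us pulsons, below the 5 us chip minimum
  expect_warning(
    tiny <- build_pulse_pattern(stim_params(10, 64, 12.5)),
    "5 us"
  )
  expect_equal(tiny$width_us, c(4, 4))
  expect_true(attr(tiny, "sub_min_width"))

  expect_error(
    build_pulse_pattern(stim_params(10, 512, 100, n_pulsons = 2, pulson_spacing = 100)),
    "overflows"
  )
})

test_that("duty-cycle identity holds over the whole constructible grid", {
  for (pw in c(64, 128, 256, 512, 1024)) {
    for (duty in c(12.5, 25, 50, 100)) {
      for (n in 1:3) {
        pat <- suppressWarnings(build_pulse_pattern(stim_params(5, pw, duty, n_pulsons = n)))
        expect_equal(sum(pat$width_us) / pw, duty / 100, tolerance = 1e-12)
        # non-overlapping, contained in the pulse width
        ends <- pat$onset_us + pat$width_us
        expect_true(all(diff(pat$onset_us) >= pat$width_us[-n] - 1e-9))
        expect_lte(max(ends), pw + 1e-9)
      }
    }
  }
})

test_that("stim_params enforces the device's parameter ranges", {
  expect_error(stim_params(25, 512, 100), "\\[1, 20\\]")
  expect_error(stim_params(10, 2048, 100), "\\[64, 1024\\]")
  expect_error(stim_params(10, 512, 30), "12.5, 25, 50, 100")
  expect_error(stim_params(10, 512, 100, pulson_voltage = 5), "\\[2.6, 3.7\\]")
  expect_error(stim_params(10, 512, 100, n_pulsons = 1, pulson_spacing = 10), "zero")
})

test_that("circuit impedance has the right analytic limits", {
  cuff <- median_cuff()
  # capacitor shorts R2 at high frequency: Z -> R1
  expect_equal(Mod(circuit_impedance(cuff, 1e9)), 1580, tolerance = 1e-6)
  # DC limit: R1 + R2 = 45.58 kOhm
  expect_equal(Mod(circuit_impedance(cuff, 1e-9)), 45580, tolerance = 1e-6)
  # reactance is capacitive throughout
  expect_true(all(Im(circuit_impedance(cuff, 10^seq(0, 4, 0.1))) <= 0))
  # CPE with alpha = 1 coincides with the RC model
  cpe1 <- circuit_params(1580, 44e3, cpe_Q = 2.6e-6, cpe_alpha = 1)
  f <- c(1, 37, 500, 1e4)
  expect_equal(
    circuit_impedance(cpe1, f, "cpe"),
    circuit_impedance(cuff, f, "rc")
  )
})

test_that("the RC Nyquist locus is a semicircle of diameter R2 offset by R1", {
  cuff <- median_cuff()
  f_c <- 1 / (2 * pi * cuff$R2 * cuff$C1) # apex frequency
  z_lo <- circuit_impedance(cuff, 1e-9)
  z_apex <- circuit_impedance(cuff, f_c)
  z_hi <- circuit_impedance(cuff, 1e9)
  expect_equal(Re(z_lo), cuff$R1 + cuff$R2, tolerance = 1e-9)
  expect_equal(Re(z_hi), cuff$R1, tolerance = 1e-9)
  expect_equal(Re(z_apex), cuff$R1 + cuff$R2 / 2, tolerance = 1e-9)
  expect_equal(-Im(z_apex), cuff$R2 / 2, tolerance = 1e-9)
})

test_that("simulated spectra are seeded and |Z| decreases with frequency", {
  cuff <- median_cuff()
  sp <- simulate_spectrum(cuff)
  expect_equal(nrow(sp), 41)
  modz <- Mod(complex(real = sp$re_ohm, imaginary = sp$im_ohm))
  expect_true(all(diff(modz) <= 1e-9))
  # zero noise: exact model values
  expect_equal(
    sp$re_ohm,
    Re(circuit_impedance(cuff, sp$freq_hz))
  )
  a <- simulate_spectrum(cuff, noise_sigma = 0.05, seed = 3)
  b <- simulate_spectrum(cuff, noise_sigma = 0.05, seed = 3)
  c <- simulate_spectrum(cuff, noise_sigma = 0.05, seed = 4)
  expect_identical(a$re_ohm, b$re_ohm)
  expect_false(identical(a$re_ohm, c$re_ohm))
  expect_error(simulate_spectrum(cuff, f_grid = c(0.1, 1)), "\\[1, 1e4\\]")
})

test_that("circuit fitting recovers the generating parameters", {
  truth <- median_cuff()
  sp <- simulate_spectrum(truth, 10^seq(0, 4, length.out = 40))
  fit <- fit_circuit(sp, init = circuit_params(3160, 88e3, 5.2e-6))
  expect_true(fit$converged)
  expect_equal(fit$circuit$R1, 1580, tolerance = 1e-3)
  expect_equal(fit$circuit$R2, 44e3, tolerance = 1e-3)
  expect_equal(fit$circuit$C1, 2.6e-6, tolerance = 1e-3)
  expect_true(all(tidy(fit)$rel_std_error < 1e-6))

  # starting exactly at the truth converges immediately without moving
  f0 <- fit_circuit(sp, init = truth)
  expect_true(f0$converged)
  expect_equal(f0$n_iter, 1)
  expect_equal(f0$circuit$R1, 1580)

  # fixed point: refitting a spectrum generated from the fit is stable
  sp2 <- simulate_spectrum(fit$circuit, 10^seq(0, 4, length.out = 40))
  f2 <- fit_circuit(sp2, init = fit$circuit)
  expect_equal(f2$circuit$R2, fit$circuit$R2, tolerance = 1e-9)
})

test_that("our Levenberg-Marquardt loop matches minpack.lm on the same objective", {
  skip_if_not_installed("minpack.lm")
  truth <- circuit_params(900, 20e3, 1e-6)
  sp <- simulate_spectrum(truth, noise_sigma = 0.02, seed = 12)
  ours <- fit_circuit(sp, init = circuit_params(2000, 50e3, 3e-6))
  fn <- function(p) {
    z <- p[1] + p[2] / (1 + 1i * 2 * pi * sp$freq_hz * p[2] * p[3])
    zm <- complex(real = sp$re_ohm, imaginary = sp$im_ohm)
    w <- 1 / Mod(zm)
    c((Re(zm) - Re(z)) * w, (Im(zm) - Im(z)) * w)
  }
  ref <- minpack.lm::nls.lm(c(2000, 50e3, 3e-6), fn = fn)
  expect_equal(ours$circuit$R1, ref$par[1], tolerance = 1e-4)
  expect_equal(ours$circuit$R2, ref$par[2], tolerance = 1e-4)
  expect_equal(ours$circuit$C1, ref$par[3], tolerance = 1e-4)
})

test_that("noisy-spectrum fits recover R1 in the median over seeds", {
  truth <- median_cuff()
  r1s <- vapply(1:20, function(s) {
    sp <- simulate_spectrum(truth, noise_sigma = 0.05, seed = s)
    fit_circuit(sp, init = circuit_params(3160, 88e3, 5.2e-6))$circuit$R1
  }, numeric(1))
  expect_lt(abs(median(r1s) - 1580) / 1580, 0.05)
})

test_that("onset current is Ohmic through the access resistance", {
  p <- stim_params(20, 1024, 100)
  expect_equal(peak_current(p, circuit_params(1100, 44e3, 2.6e-6))$peak_mA, 3.0)
  p37 <- stim_params(20, 1024, 100, pulson_voltage = 3.7)
  expect_equal(peak_current(p37, median_cuff())$peak_mA, 3.7 / 1.58, tolerance = 1e-4)
  # doubling R1 halves the onset current
  i1 <- peak_current(p, circuit_params(1000, 44e3, 2.6e-6))$peak_mA
  i2 <- peak_current(p, circuit_params(2000, 44e3, 2.6e-6))$peak_mA
  expect_equal(i1 / i2, 2)
  # transient decays from V/R1 towards V/(R1+R2)
  tr <- peak_current(p, median_cuff())$transient
  expect_true(all(diff(tr$i_mA) < 0))
})

test_that("charge per pulse tracks duty cycle and pulse width", {
  cuff <- median_cuff()
  q <- function(duty, pw = 512) charge_per_pulse(stim_params(10, pw, duty), cuff)
  expect_gt(q(100), q(50))
  expect_gt(q(50), q(25))
  expect_gt(q(25), q(12.5))
  expect_gt(q(100, 1024), q(100, 512))

  # near-infinite C1 shorts R2: charge -> V/R1 * (duty/100) * PW, linear in duty
  big_c <- circuit_params(1580, 44e3, 1)
  for (duty in c(12.5, 25, 50, 100)) {
    p <- stim_params(10, 512, duty)
    expect_equal(
      charge_per_pulse(p, big_c),
      3.3 / 1580 * (duty / 100) * 512,
      tolerance = 1e-4
    )
  }
})
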
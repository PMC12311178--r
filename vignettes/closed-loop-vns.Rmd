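---
title: "Closed-loop VNS titration to the neural fulcrum: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop VNS titration to the neural fulcrum: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fulcrum)
```

`fulcrum` simulates a closed-loop vagus-nerve stimulator that titrates
itself to the *neural fulcrum* — the operating point at which stimulation
leaves heart rate (HR) within a small band around baseline. This vignette
is the package's account of its models: what each stage assumes, which
parameters matter, which choices were genuinely open, and what the
simulator can and cannot tell you about a real animal.

## The simulated loop

One protocol cycle ("epoch") is a 14 s active phase followed by a 66 s
rest phase, observed on a 5-s window clock (16 windows per 80 s epoch; the
active phase covers the first three windows, i.e. the ON time rounded up
to the window grid — the grid/phase alignment is a convention, not a
physiological claim). Each epoch:

1. the **plant** converts the current stimulation setting into a per-window
   HR trajectory;
2. the **HR chain** (optionally) re-derives those windows from a synthetic
   ECG;
3. the **controller** measures the active-phase drop against the baseline
   (mean of the two final rest windows of the previous epoch), classifies
   it, and updates at most one stimulation parameter for the next epoch.

A 30 s pre-stimulation rest period supplies the first baseline. Runs start
from the adverse initialization — the highest levels of both grids at the
full 1024 µs pulse width — and stop at steady state, a grid floor, a
safety abort (default: measured drop beyond 30%), or the epoch cap.

## Synthetic ECG and LVP

The generator's job is testability, not electrophysiological fidelity.
Beats are placed by *rate integration*: the k-th beat occurs where the
integral of the instantaneous rate crosses k. This makes beat counts and
window medians analytic — a stepped HR profile reproduces its per-window
values exactly through the whole chain — which is what the test suite
leans on. Each beat is rendered as a raised-cosine R wave (80 ms, 1 mV
scale) with low-amplitude P and T bumps (R at least 3 times either), so a
Lead-I-like QRS dominance holds. The pressure channel places the
half-height of its upstroke exactly on the beat time, giving a
gold-standard beat clock shared with the ECG.

Noise is the set of confounders the 4–45 Hz bandpass exists to remove:
sinusoidal baseline wander (default 0.1 mV at 0.25 Hz), additive white
noise (default 0.05 mV, i.e. a twentieth of the R amplitude), and per-beat
timing jitter (default 2% of the local R-R interval). Defaults were chosen
once for plausible testability — amplitudes and noise levels of porcine
surface recordings are not published alongside the method — and the same
seed reproduces a trace bit for bit, with the ECG and LVP channels drawing
from distinct substreams so their noise is independent.

What the generator does *not* emulate: 12-lead morphology, arrhythmia,
respiratory coupling, electrode motion artifacts, or amplitude drift.
Passing tests therefore demonstrate correctness of the processing chain on
its stated signal model, not robustness to every artifact a live recording
can produce.

## The HR extraction chain

*Filters.* "24th-order" is read as classical FIR order, so the high-pass
has 25 taps and the low-pass 49. Both are Hamming windowed-sinc designs;
after design the high-pass taps are shifted to a DC sum of exactly zero
and the low-pass taps scaled to a DC sum of exactly one, so the
postconditions (zero DC gain, unit passband reference) hold to machine
precision rather than to window accuracy. Filtering is applied offline
with explicit group-delay compensation — symmetric taps have integer delay
`order/2`, and the centre slice of the full convolution is taken — so peak
times are unbiased; the real-time system has latency, but latency is
irrelevant offline.

*R-peak detection.* Candidates are local maxima. Two running estimates are
kept: the signal-peak amplitude S (updated by accepted peaks, 0.8/0.2
exponential smoothing) and the noise-peak amplitude N (updated by rejected
candidates, capped at 0.7 S). The threshold sits between them,
`N + θ (S − N)` with θ = 0.5 by default, with the signal contribution
decaying exponentially (2 s time constant) since the last accepted peak so
a weakened beat is still caught, a floor of 1.2 N so the threshold never
sinks into the noise, and a 200 ms refractory period (a 300 bpm ceiling).
Accepted peak times are refined by parabolic interpolation through the
three samples around the maximum, which matters at 200 S/s: a ±2.5 ms
quantization error on a 750 ms interval is already a 0.3% rate error.

*Windowing.* One HR value per half-open window `[5k, 5(k+1))` s: the
median of `60/RR` over the R-R intervals whose *ending* peak falls in the
window (the assignment convention is ours; nothing downstream depends on
it). Windows with fewer than two peaks are flagged missing rather than
extrapolated, and the controller treats a fully missing active phase as
"no measurement" and holds — the fail-safe direction. The pressure-channel
extraction locates upstroke half-height crossings with linear
interpolation, applies a 3-point running median to the edge-to-edge rates
(its "light smoothing"), then windows identically. Under per-beat timing
jitter that smoothing makes the two extractions differ slightly by
construction; the agreement metric in the tests reflects that.

## The plant

The dose-response surface is a separable power law,

\[ \Delta\%(f, d, \mathrm{PW}) = A_{\max}\,
   (f/20)^{\gamma_f}\,(d/100)^{\gamma_d}\,(\mathrm{PW}/512)^{\gamma_{pw}}
   - \text{offset}, \]

with reference exponents γf = 1.2, γd = 0.8, γpw = 0.5. The open-loop
evidence constrains only two anchors — about 13% drop at (20 Hz, 100%
duty, 512 µs) and under 2% at weak settings — plus monotone trends in
every parameter, so the functional form is a modelling decision and every
exponent is configuration. The default offset is zero (a pure-bradycardia
plant); a positive offset is available as a *synthetic* device for
emulating fulcrum crossing into mild tachycardia, and is documented as
such. Onset and recovery are first-order relaxations (τ_on = 3 s,
τ_off = 8 s; the recorded transients constrain these only qualitatively),
and HR variability is independent Gaussian noise per 5-s window (0.5 bpm
sd by default), which keeps the average natural 5-s variation comfortably
below the controller's band.

Scenario presets rescale `A_max` so that the *first epoch at the adverse
initialization* matches the recorded initial reductions: 10%
(`"subject-open"`) and 6% (`"subject-closed"`), both with HRV on;
`"reference"` / `"reference-noisy"` keep the open-loop calibration. The
rescaling is deliberate: at 1024 µs the power-law PW factor is
`2^0.5 ≈ 1.41`, so an unscaled reference plant starts near 18%, while real
subjects showed smaller initial drops at the same setting — pulse-width
sensitivity evidently saturates in vivo, and the presets absorb that
subject-level difference rather than the surface trying to.

## The controller

Per epoch the active-phase response is the drop at the *minimum*
active-phase window HR (worst-case bradycardia; mean aggregation is a
config switch). Classification compares the drop against the larger of the
steady band (2.5%, valid 2–4%) and the bradycardia threshold — the running
maximum observed response divided by the threshold divisor. Bradycardia
steps the duty cycle down one grid level (100 → 50 → 25 → 12.5%), then the
frequency (20 → 15 → 10 → 5 → 2 → 1 Hz) once the duty grid is exhausted;
tachycardia inverts the most recent down-step; steady holds. Exactly one
parameter changes per rest phase. Steady state is declared after two
consecutive in-band responses — one lucky noisy window should not end a
run — and a hold cycle does not count as an update.

Two genuinely open choices deserve their rationale:

- **Duty-first ordering.** Duty cycle is the direct charge-per-pulse proxy
  and its grid is coarse, so de-escalating it first sheds intensity
  fastest per update; frequency then provides the finer tail. The recorded
  parameter schedules show duty moving early, and the tree is
  configuration-swappable.
- **Threshold divisor default = 10.** The method allows one-fifth or
  one-tenth of the maximum response. With one-fifth, a plant whose initial
  response is well above the band puts the threshold *above* the steady
  band (e.g. an 18% first drop gives a 3.7% threshold), opening a dead
  zone between the band (2.5%) and the threshold where responses classify
  as steady yet never satisfy the steady-band counter: the run stalls,
  holding forever above the band. One-tenth keeps the band as the
  operative trip level for every plant this package ships, so the
  controller keeps de-escalating until it is genuinely inside the band.
  The divisor remains configurable for studying the stall regime.

## Outcome statistics

Per-run, the sequence of per-epoch drop magnitudes (clipped below at zero)
is tested for a downward trend with the Mann-Kendall statistic
`S = Σ_{i<j} sign(x_j − x_i)`. The variance uses the standard tie
correction. For n ≤ 10 without ties the one-sided lower tail
`P(S_null ≤ S)` is computed *exactly* from the permutation null, using the
inversion-count recursion (the null distribution of discordant pairs is
the repeated convolution of uniform blocks); converged runs here have
n ≈ 4–8 epochs, where normal approximations are at their weakest and
exactness is cheap. The normal approximation is also reported, with the
continuity correction applied toward the evaluated tail
(`Φ((S+1)/σ)` for the lower tail); both p-values are exposed because
short-sequence practice varies. Ties fall back to the tie-corrected normal
approximation; a constant sequence reports p = 1. Significance at α = 0.05
requires both S < 0 and p < α. Cohort summaries report the counts of
negative-S and significant runs and the fold reduction
`mean(first drop) / mean(last drop)`.

## Electrode and waveform model

The nerve-cuff load is `Z(ω) = R1 + R2 / (1 + jωR2C1)`, or the
constant-phase-element variant `R2/(1 + (jω)^α R2 Q)` for non-ideal
double layers (α = 1 recovers the capacitor). Spectrum fitting minimizes
the modulus-weighted stacked real/imaginary residuals — spectra span
decades, and 1/|Z| weighting keeps every decade informative — with a
Levenberg-Marquardt loop using the classical damping schedule (λ starts at
0.01, ×10 on rejection, ÷10 on acceptance). Because R2 (~10⁴ Ω) and C1
(~10⁻⁶ F) differ by ten orders of magnitude, the normal equations are
solved in Marquardt-scaled variables (normalized by `sqrt(diag(JᵀJ))`);
without that scaling the system is numerically singular in double
precision. Per-parameter uncertainties are relative standard errors from
the Jacobian-based covariance at the optimum; they quantify *per-fit*
uncertainty, which is distinct from the spread of fitted values across
animals — both statistics are available, and neither substitutes for the
other. Non-convergence is reported as a flag, not an exception. The
independent cross-check in the test suite fits the same objective with
`minpack.lm`.

Pulse patterns chop each pulse into equal-width "pulsons": width
`(duty/100)·PW/n`, default spacing equal to the pulson width (shrunk to
fit when the pattern would overflow the pulse width, which is rejected if
explicit), and a warning when a pulson falls below the 5 µs hardware
minimum. Charge per pulse integrates the RC step-response transient over
each pulson — onset current `V/R1` (the uncharged double layer shorts R2),
relaxing toward `V/(R1+R2)` with τ = C1·R1R2/(R1+R2) — assuming the
double layer is discharged between pulsons, as charge-balanced stimulators
do; modelling the discharge phase itself is out of scope. The closed form
reduces to `V/R1 × (duty/100) × PW` in the R2-shorted limit and is
strictly monotone in duty cycle and pulse width.

## Problem sizes and numerical conventions

The suite and the acceptance script run at the sizes the methods
naturally use: 700 s of 200 S/s ECG (140 windows) for the extraction
benchmark, 80 s epochs (16 windows) per protocol cycle, an eight-run noisy
cohort for the trend statistics, and 40–41 point log-spaced spectra over
1 Hz–10 kHz for the circuit fits. Degenerate inputs are handled
explicitly: flat traces yield empty peak series (not errors), missing
windows propagate as `NA`, fewer than two pre-stimulation windows is an
error ("insufficient baseline"), trend tests need n ≥ 3 and otherwise
flag themselves not-computed, and grid floors/ceilings saturate with a
logged flag instead of stepping outside `[1, 20]` Hz ×
{12.5, 25, 50, 100}% × `[64, 1024]` µs.

## Limitations

The plant is phenomenological: no baroreflex, no sympathetic/vagal
balance, no anesthesia-depth or respiratory modulation, and HRV that is
white per window rather than autocorrelated. Convergence results on it
validate the *controller logic and signal chain*, not the biology; in
particular the simulator cannot say how often a real subject's threshold
crosses into tachycardia, because the default plant is purely
bradycardic. The ECG model's fixed morphology means detection performance
on real porcine recordings must be established separately. Pulse-width
closed-loop control is not exercised (PW is held per run, as in the
recorded runs), and the Mann-Kendall test is applied per run without
multiplicity correction across runs, matching the original analysis.
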
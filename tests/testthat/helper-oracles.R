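# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: beat counts come from direct trapezoidal
# integration of the rate profile, and Mann-Kendall tail probabilities from
# brute-force enumeration of all permutations.

# Expected beat count: floor of the integral of rate/60 over [0, duration].
oracle_beat_count <- function(profile, duration, dt = 1e-4) {
  t <- seq(0, duration, by = dt)
  rate <- profile_hr_at(profile, t) / 60
  floor(sum((head(rate, -1) + tail(rate, -1)) / 2 * diff(t)))
}

all_perms <- function(v) {
  if (length(v) <= 1) {
    return(list(v))
  }
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

mk_S <- function(x) {
  d <- outer(x, x, function(a, b) sign(b - a))
  sum(d[upper.tri(d)])
}

# Exact one-sided (downward) p-value by enumeration: P(S_perm <= S_obs)
# over all orderings of the observed values. Only sane for n <= 6.
oracle_mk_p_down <- function(x) {
  s_obs <- mk_S(x)
  s_all <- vapply(all_perms(x), mk_S, numeric(1))
  mean(s_all <= s_obs)
}

# Build an hr_series from ground-truth beat times (generator's beat clock).
true_hr_series <- function(beat_times, duration, window = 5) {
  pk <- tibble::tibble(time_s = beat_times, amplitude = 1)
  attr(pk, "duration") <- duration
  class(pk) <- c("peak_series", class(pk))
  hr_from_peaks_windowed(pk, duration, window)
}

# Reference cuff-load medians used throughout.
median_cuff <- function() circuit_params(1580, 44e3, 2.6e-6)
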
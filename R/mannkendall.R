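#' Mann-Kendall trend test (one-sided downward)
#'
#' Nonparametric trend test on a sequence: `S = sum_{i<j} sign(x_j - x_i)`.
#' The variance uses the standard tie correction,
#' `var(S) = [n(n-1)(2n+5) - sum_g t_g(t_g-1)(2t_g+5)] / 18`, and the
#' normal approximation applies the +/-1 continuity correction
#' (`z = (S+1)/sqrt(var)` for `S < 0`, `(S-1)/sqrt(var)` for `S > 0`).
#' For the downward alternative the p-value is the lower tail
#' `P(S_null <= S)`. For `n <= 10` without ties this tail is computed
#' exactly from the permutation null distribution (via the classical
#' inversion-count recursion); otherwise the normal approximation is used.
#' The trend is declared significant when `S < 0` and the operative
#' p-value is below `alpha`.
#'
#' @param x Numeric sequence in time order, `n >= 3`.
#' @param alpha Significance level (default 0.05).
#' @param alternative `"down"` (default, the bradycardia-reduction
#'   alternative) or `"two.sided"`.
#' @return An object of class `mann_kendall`: `S`, `var_S`, `z`, `p`
#'   (operative), `p_exact` (NA when unavailable), `p_normal`, `n`,
#'   `n_ties`, `method`, `significant`. [tidy()]/[glance()] methods
#'   return it as a one-row tibble.
#' @examples
#' mann_kendall(c(10, 7, 5, 3, 2.5, 2.2, 2.0))
#' @export
mann_kendall <- function(x, alpha = 0.05, alternative = c("down", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) abort("Mann-Kendall requires at least 3 observations.")
  if (any(is.na(x))) abort("`x` must not contain missing values.")
  d <- outer(x, x, function(a, b) sign(b - a))
  S <- sum(d[upper.tri(d)])
  ties <- table(x)
  ties <- ties[ties > 1]
  n_ties <- sum(ties)
  var_S <- (n * (n - 1) * (2 * n + 5) -
    sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (var_S <= 0) {
    ## tie-saturated (constant) sequence: no trend information
    z <- 0
    p_normal_down <- 1
  } else {
    ## conventional trend z (continuity-corrected towards zero)
    z <- if (S > 0) {
      (S - 1) / sqrt(var_S)
    } else if (S < 0) {
      (S + 1) / sqrt(var_S)
    } else {
      0
    }
    ## lower-tail P(S_null <= S): continuity correction towards the tail
    p_normal_down <- pnorm((S + 1) / sqrt(var_S))
  }
  p_exact_down <- if (n <= 10 && n_ties == 0) mk_exact_lower_tail(n, S) else NA_real_
  p_down <- if (!is.na(p_exact_down)) p_exact_down else p_normal_down
  method <- if (!is.na(p_exact_down)) "exact" else "normal"
  p <- if (alternative == "down") {
    p_down
  } else if (var_S <= 0) {
    1
  } else {
    min(1, 2 * pnorm(-abs(z)))
  }
  significant <- S < 0 && p < alpha
  structure(
    list(
      S = S, var_S = var_S, z = z, p = p, p_exact = p_exact_down,
      p_normal = p_normal_down, n = n, n_ties = n_ties,
      alternative = alternative, alpha = alpha, method = method,
      significant = significant
    ),
    class = "mann_kendall"
  )
}

## Exact null distribution of S for tie-free sequences of length n:
## S = T - 2D with T = n(n-1)/2 and D the number of discordant pairs
## (inversions). The inversion counts follow the classical convolution
## recursion: c_n = c_{n-1} * (1, 1, ..., 1)  [j+1 ones at stage j].
mk_null_counts <- function(n) {
  counts <- 1
  for (j in seq_len(n - 1)) {
    ones <- rep(1, j + 1)
    new <- numeric(length(counts) + j)
    for (k in seq_along(ones)) {
      idx <- seq_along(counts) + k - 1
      new[idx] <- new[idx] + counts
    }
    counts <- new
  }
  counts # counts[d + 1] = number of permutations with d inversions
}

mk_exact_lower_tail <- function(n, S) {
  counts <- mk_null_counts(n)
  total <- sum(counts)
  t_max <- n * (n - 1) / 2
  d_obs <- (t_max - S) / 2 # inversions corresponding to the observed S
  sum(counts[seq_len(length(counts)) - 1 >= d_obs]) / total
}

#' @export
print.mann_kendall <- function(x, ...) {
  cat(sprintf(
    "Mann-Kendall trend test (n = %d): S = %g, var = %.2f, p[%s, %s] = %.4g%s\n",
    x$n, x$S, x$var_S, x$alternative, x$method, x$p,
    if (x$significant) "  (significant downward trend)" else ""
  ))
  invisible(x)
}

#' @rdname mann_kendall
#' @param x A `mann_kendall` object.
#' @param ... Unused.
#' @export
tidy.mann_kendall <- function(x, ...) {
  tibble::tibble(
    S = x$S, var_S = x$var_S, z = x$z, p = x$p, p_exact = x$p_exact,
    p_normal = x$p_normal, n = x$n, method = x$method,
    significant = x$significant
  )
}

#' @rdname mann_kendall
#' @export
glance.mann_kendall <- function(x, ...) tidy(x)

#' Per-run trend summary
#'
#' First and last active-phase drop, their ratio, and the Mann-Kendall
#' trend of the per-epoch drop magnitudes (drops clipped below at 0, so the
#' sequence measures bradycardia magnitude). With fewer than 3 stimulated
#' epochs the trend is flagged not computed.
#'
#' @param run A `vns_run`.
#' @param alpha Significance level.
#' @return A one-row tibble: `n_epochs`, `first_drop`, `last_drop`,
#'   `drop_ratio`, `S`, `p`, `significant`, `trend_computed`, `status`.
#' @export
run_summary <- function(run, alpha = 0.05) {
  stopifnot(inherits(run, "vns_run"))
  drops <- pmax(run$epochs$drop, 0)
  drops <- drops[!is.na(drops)]
  n <- length(drops)
  if (n >= 3) {
    mk <- mann_kendall(drops, alpha = alpha)
    trend <- tibble::tibble(
      S = mk$S, p = mk$p, significant = mk$significant, trend_computed = TRUE
    )
  } else {
    trend <- tibble::tibble(
      S = NA_real_, p = NA_real_, significant = NA, trend_computed = FALSE
    )
  }
  first <- if (n) drops[1] else NA_real_
  last <- if (n) drops[n] else NA_real_
  dplyr::bind_cols(
    tibble::tibble(
      n_epochs = n, first_drop = first, last_drop = last,
      drop_ratio = if (!is.na(last) && last > 0) first / last else NA_real_
    ),
    trend,
    tibble::tibble(status = run$status)
  )
}

#' Cohort summary across runs
#'
#' Counts of negative-S and significant downward trends, mean first- and
#' last-epoch drops, and the fold reduction `mean_first / mean_last` across
#' a set of closed-loop runs (the unit of analysis of the outcome
#' statistics).
#'
#' @param runs A list of `vns_run` objects.
#' @param alpha Significance level.
#' @return A one-row tibble: `n_runs`, `n_S_negative`, `n_significant`,
#'   `mean_first_drop`, `mean_last_drop`, `drop_ratio`, `n_excluded`
#'   (runs without computable drops).
#' @export
cohort_summary <- function(runs, alpha = 0.05) {
  if (!length(runs)) abort("Need at least one run.")
  per <- dplyr::bind_rows(purrr::map(runs, run_summary, alpha = alpha))
  ok <- per$n_epochs > 0
  mean_first <- mean(per$first_drop[ok])
  mean_last <- mean(per$last_drop[ok])
  tibble::tibble(
    n_runs = nrow(per),
    n_S_negative = sum(per$S < 0, na.rm = TRUE),
    n_significant = sum(per$significant, na.rm = TRUE),
    mean_first_drop = mean_first,
    mean_last_drop = mean_last,
    drop_ratio = if (mean_last > 0) mean_first / mean_last else NA_real_,
    n_excluded = sum(!ok)
  )
}
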
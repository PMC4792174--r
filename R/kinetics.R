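#' Non-steady-state kinetic model of the 0th isotopomer
#'
#' During heavy-water labeling the 0th-isotopomer fraction of a peptide pool
#' relaxes, at the protein's turnover rate `k`, toward the 0th-isotopomer
#' fraction of newly synthesized peptides. Because body-water deuterium itself
#' equilibrates with first-order kinetics (`p(t) = p_ss (1 - e^{-k_p t})`),
#' the precursor fraction is time-dependent:
#' `A0_max(t) = a * (1 - p_ss (1 - e^{-k_p t}))^N`,
#' and the pool obeys `dA0/dt = k (A0_max(t) - A0)` with `A0(0) = a`.
#'
#' `precursor_a0()` evaluates `A0_max(t)` (real-valued `N` allowed).
#'
#' `model_a0()` is the analytic integrated solution, obtained by binomial
#' expansion of the forcing term:
#' `A0(t) = a e^{-kt} + a k * sum_{i=0}^{N} C(N,i) (1-p_ss)^{N-i} p_ss^i
#'  (e^{-i k_p t} - e^{-kt}) / (k - i k_p)`,
#' with a term replaced by its limit `a k b_i t e^{-kt}` when `k` is within
#' `degenerate_tol * k_p` of `i * k_p`. The expansion requires integer `N`;
#' non-integer `N` is rounded to the nearest integer (the numerical oracle
#' [ode_a0()] handles real `N` exactly; the divergence is documented and
#' small for |dN| <= 0.5).
#'
#' `ode_a0()` integrates the same differential equation numerically to high
#' accuracy and serves as the independent oracle for the analytic solution.
#'
#' @param t Time (days), vectorized.
#' @param a Unlabeled 0th-isotopomer fraction (0 < a <= 1), from
#'   [natural_a0()].
#' @param N Number of accessible labeling sites, from [count_sites()].
#' @param p_ss,k_p Plateau and rate constant of body-water enrichment, from
#'   [fit_enrichment_curve()].
#' @param k Peptide turnover rate constant (per day, > 0).
#' @param degenerate_tol Relative tolerance below which a denominator
#'   `k - i k_p` is treated as zero and the limiting term is used.
#' @return Numeric vector of 0th-isotopomer fractions at `t`.
#' @examples
#' model_a0(0.1, t = c(0, 7, 14), a = 0.5, N = 20, p_ss = 0.045, k_p = 2)
#' @name kinetic_model
NULL

#' @rdname kinetic_model
#' @export
precursor_a0 <- function(t, a, N, p_ss, k_p) {
  stopifnot(all(t >= 0), a > 0, a <= 1, N >= 0)
  a * (1 - p_ss * (1 - exp(-k_p * t)))^N
}

#' @rdname kinetic_model
#' @export
model_a0 <- function(k, t, a, N, p_ss, k_p, degenerate_tol = 1e-9) {
  stopifnot(k > 0, all(t >= 0), a > 0, a <= 1, N >= 0, p_ss >= 0, p_ss < 1,
            k_p >= 0)
  N <- round(N)
  i <- 0:N
  b <- choose(N, i) * (1 - p_ss)^(N - i) * p_ss^i
  ekt <- exp(-k * t)
  acc <- numeric(length(t))
  for (j in seq_along(i)) {
    denom <- k - i[j] * k_p
    if (k_p > 0 && abs(denom) < degenerate_tol * k_p) {
      acc <- acc + b[j] * t * ekt
    } else {
      acc <- acc + b[j] * (exp(-i[j] * k_p * t) - ekt) / denom
    }
  }
  a * ekt + a * k * acc
}

#' @rdname kinetic_model
#' @param rtol,atol Solver tolerances for the numerical oracle.
#' @export
ode_a0 <- function(k, t, a, N, p_ss, k_p, rtol = 1e-12, atol = 1e-14) {
  stopifnot(k > 0, all(t >= 0), a > 0, a <= 1, N >= 0)
  times <- sort(unique(c(0, t)))
  deriv <- function(tt, y, parms) {
    list(k * (a * (1 - p_ss * (1 - exp(-k_p * tt)))^N - y))
  }
  sol <- deSolve::ode(
    y = c(A0 = a), times = times, func = deriv, parms = NULL,
    method = "lsoda", rtol = rtol, atol = atol
  )
  lookup <- setNames(sol[, "A0"], format(sol[, "time"], digits = 15))
  unname(lookup[format(t, digits = 15)])
}

#' Half-life of a first-order turnover process
#'
#' @param k Turnover rate constant (per day), strictly positive.
#' @return Half-life in days, `log(2) / k`.
#' @examples
#' half_life(0.094)
#' @export
half_life <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) abort("k must be positive and finite")
  log(2) / k
}

#' Rescale isotopomer decay to fractional synthesis
#'
#' Maps an `A0` value (or series) onto the fraction of the protein pool that
#' has been replaced: `FS = (a - A0) / (a - a (1 - p_ss)^N)`. `FS` runs from 0
#' (no replacement, `A0 = a`) to 1 (complete turnover at plateau enrichment),
#' so peptides with different `a` and `N` overlay on one common curve.
#'
#' @param series Data frame with columns `t` and `A0` (additional columns are
#'   preserved).
#' @inheritParams kinetic_model
#' @return The input tibble with an added `fs` column.
#' @export
fractional_synthesis <- function(series, a, N, p_ss, k_p) {
  check_columns(series, c("t", "A0"), "series")
  if (N == 0 || p_ss == 0) {
    abort("fractional synthesis undefined for N = 0 or p_ss = 0 (no labeling plateau)")
  }
  plateau <- a * (1 - p_ss)^N
  dplyr::mutate(tibble::as_tibble(series),
                fs = (a - .data$A0) / (a - plateau))
}
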
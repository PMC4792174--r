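#' Calibrate the GC-MS body-water standard curve
#'
#' Ordinary least-squares line mapping the acetone-exchange ion-intensity
#' ratio (m/z 59 relative to 58) to the known molar fraction of heavy water.
#' The regression is run in the inverse direction (fraction on ratio) so the
#' fitted line applies directly to sample ratios.
#'
#' @param points Data frame with columns `fraction` (known molar fraction of
#'   2H2O, 0-0.25) and `ratio` (measured ion-intensity ratio, >= 0). At least
#'   3 points spanning a nonzero ratio range.
#' @return A `standard_curve` object: slope, intercept, and the per-point
#'   residuals. Supports [tidy()], [glance()].
#' @examples
#' pts <- tibble::tibble(fraction = seq(0, 0.2, length.out = 11),
#'                       ratio = seq(0, 0.2, length.out = 11) / 0.5)
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points) {
  check_columns(points, c("fraction", "ratio"), "standard-curve points")
  if (nrow(points) < 3) abort("standard curve needs at least 3 points")
  if (any(points$fraction < 0 | points$fraction > 0.25)) {
    abort("standard-curve fractions must lie in [0, 0.25]")
  }
  if (any(points$ratio < 0)) abort("ion-intensity ratios must be non-negative")
  if (diff(range(points$ratio)) == 0) {
    abort("degenerate standard curve: all ratios are equal (non-invertible calibration)")
  }
  fit <- lm(fraction ~ ratio, data = points)
  # exact synthetic calibrations trigger the harmless perfect-fit warning
  s <- suppressWarnings(summary(fit))
  structure(
    list(
      slope = unname(coef(fit)[["ratio"]]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      residuals = tibble::tibble(
        fraction = points$fraction, ratio = points$ratio,
        fitted = unname(fitted(fit)), residual = unname(residuals(fit))
      ),
      sigma = s$sigma,
      r_squared = s$r.squared,
      model = fit
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("GC-MS body-water standard curve\n")
  cat(sprintf("  fraction = %.6g * ratio + %.6g  (n = %d, residual sd %.3g)\n",
              x$slope, x$intercept, nrow(x$residuals), x$sigma))
  invisible(x)
}

#' Convert measured ratios to molar enrichment
#'
#' Applies a fitted standard curve to sample ion-intensity ratios. Values are
#' clamped to `[0, 1)` with a warning, since a molar water fraction outside
#' that range is physically impossible.
#'
#' @param curve A `standard_curve` from [fit_standard_curve()].
#' @param ratio Numeric vector of measured ratios.
#' @return Numeric vector of molar enrichments `p`.
#' @export
enrichment_from_ratio <- function(curve, ratio) {
  stopifnot(inherits(curve, "standard_curve"))
  p <- curve$slope * ratio + curve$intercept
  if (any(p < 0 | p >= 1)) {
    warn("enrichment outside [0, 1) clamped to the physical range")
    p <- pmin(pmax(p, 0), 1 - 1e-12)
  }
  p
}

#' Fit the first-order body-water enrichment curve
#'
#' Least-squares fit of `p(t) = p_ss * (1 - exp(-k_p * t))` to body-water
#' enrichment measurements: `p_ss` is the plateau molar enrichment and `k_p`
#' the first-order equilibration rate (per day). The curve passes through the
#' origin, so the downstream kinetic model accounts for the delay in label
#' availability early in the experiment rather than assuming instant
#' enrichment.
#'
#' @param measurements Data frame with columns `t` (days since the start of
#'   labeling) and `p` (molar enrichment fraction). At least 3 distinct times,
#'   one positive.
#' @param k_p_max Upper bound on `k_p` (per day); the saturated limit (all
#'   measurements at plateau) drives `k_p` to this bound.
#' @return An `enrichment_fit` object with elements `p_ss`, `k_p`, the data
#'   and the underlying `nls` fit. Supports [tidy()], [glance()],
#'   [autoplot()], and [predict()].
#' @examples
#' tt <- c(0, 1, 3, 5, 7, 10, 14)
#' meas <- tibble::tibble(t = tt, p = 0.045 * (1 - exp(-2 * tt)))
#' fit_enrichment_curve(meas)
#' @export
fit_enrichment_curve <- function(measurements, k_p_max = 50) {
  check_columns(measurements, c("t", "p"), "body-water measurements")
  if (any(measurements$t < 0)) abort("times must be non-negative")
  if (any(measurements$p < 0 | measurements$p >= 1)) {
    abort("enrichment values must lie in [0, 1)")
  }
  if (length(unique(measurements$t)) < 3 || all(measurements$t <= 0)) {
    abort("need measurements at >= 3 distinct times with at least one t > 0")
  }
  pos <- measurements$p[measurements$t > 0]
  if (all(pos < 1e-6)) abort("no labeling detected: all enrichments are ~0")

  p_ss0 <- max(measurements$p)
  # crude initial rate from the earliest positive time
  t1 <- min(measurements$t[measurements$t > 0])
  p1 <- mean(measurements$p[measurements$t == t1])
  k_p0 <- if (p1 > 0 && p1 < p_ss0) -log(1 - p1 / p_ss0) / t1 else 5 / t1
  if (!is.finite(k_p0)) k_p0 <- 5 / t1
  k_p0 <- min(max(k_p0, 1e-3), k_p_max)

  # multi-start Levenberg-Marquardt on the residual function directly:
  # near-saturated data push k_p toward the bound where the Jacobian column
  # vanishes, which the low-level nls.lm handles gracefully
  resid_fun <- function(par) {
    measurements$p - par[["p_ss"]] * (1 - exp(-par[["k_p"]] * measurements$t))
  }
  starts <- unique(pmin(pmax(c(k_p0, 0.5, 2, k_p_max / 2), 1e-3), k_p_max))
  fits <- lapply(starts, function(k0) {
    tryCatch(
      minpack.lm::nls.lm(
        par = c(p_ss = p_ss0, k_p = k0), fn = resid_fun,
        lower = c(p_ss = 1e-8, k_p = 1e-8),
        upper = c(p_ss = 1 - 1e-8, k_p = k_p_max),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                             ptol = 1e-12)
      ),
      error = function(e) e
    )
  })
  ok <- vapply(fits, function(f) {
    !inherits(f, "error") && f$info %in% 1:4
  }, logical(1))
  if (!any(ok)) {
    msg <- if (inherits(fits[[1]], "error")) conditionMessage(fits[[1]]) else
      fits[[1]]$message
    abort(paste0("enrichment-curve fit failed to converge: ", msg))
  }
  fits <- fits[ok]
  rss <- vapply(fits, function(f) f$deviance, numeric(1))
  fit <- fits[[which.min(rss)]]
  est <- coef(fit)
  structure(
    list(
      p_ss = unname(est[["p_ss"]]),
      k_p = unname(est[["k_p"]]),
      k_p_max = k_p_max,
      data = tibble::as_tibble(measurements[c("t", "p")]),
      model = fit
    ),
    class = "enrichment_fit"
  )
}

#' @export
print.enrichment_fit <- function(x, ...) {
  cat("Body-water enrichment curve  p(t) = p_ss * (1 - exp(-k_p t))\n")
  cat(sprintf("  p_ss = %.4g   k_p = %.4g /d   (n = %d)\n",
              x$p_ss, x$k_p, nrow(x$data)))
  invisible(x)
}

#' @export
predict.enrichment_fit <- function(object, t, ...) {
  object$p_ss * (1 - exp(-object$k_p * t))
}

check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) abort(paste0(what, " must be a data frame"))
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " missing column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(df)
}
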
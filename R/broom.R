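#' Tidiers for fitted objects
#'
#' broom-style methods: `tidy()` returns one row per parameter, `glance()`
#' one row of fit summaries.
#'
#' @param x A fitted object (`standard_curve`, `enrichment_fit`,
#'   `kinetic_fit`, or a `turnover_fits` table for `glance()`).
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(s[, "Std. Error"])
  )
}

#' @rdname tidiers
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sigma = x$sigma,
                 nobs = nrow(x$residuals))
}

#' @rdname tidiers
#' @method tidy enrichment_fit
#' @export
tidy.enrichment_fit <- function(x, ...) {
  se <- tryCatch(unname(summary(x$model)$coefficients[, "Std. Error"]),
                 error = function(e) c(NA_real_, NA_real_))
  tibble::tibble(
    term = c("p_ss", "k_p"),
    estimate = c(x$p_ss, x$k_p),
    std.error = se
  )
}

#' @rdname tidiers
#' @method glance enrichment_fit
#' @export
glance.enrichment_fit <- function(x, ...) {
  res <- x$data$p - predict(x, x$data$t)
  tibble::tibble(p_ss = x$p_ss, k_p = x$k_p,
                 sigma = sqrt(sum(res^2) / max(1, nrow(x$data) - 2)),
                 nobs = nrow(x$data))
}

#' @rdname tidiers
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(term = "k", estimate = x$k, std.error = x$dk)
}

#' @rdname tidiers
#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(k = x$k, dk = x$dk, half_life = log(2) / x$k, SS = x$SS,
                 r.squared = x$R2, se = x$se, DP = x$DP,
                 converged = x$converged)
}

#' @rdname tidiers
#' @method glance turnover_fits
#' @export
glance.turnover_fits <- function(x, ...) {
  ok <- is.finite(x$k)
  tibble::tibble(
    n_series = nrow(x),
    n_fitted = sum(ok),
    n_converged = sum(x$converged, na.rm = TRUE),
    k_median = stats::median(x$k[ok]),
    half_life_median = log(2) / stats::median(x$k[ok]),
    r2_median = stats::median(x$R2[ok]),
    se_median = stats::median(x$se[ok])
  )
}
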
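#' Plot fitted peptide decay curves
#'
#' Overlays observed 0th-isotopomer fractions and the fitted kinetic curves
#' for a selection of peptide time series.
#'
#' @param object A `turnover_fits` tibble.
#' @param series The `ID`/`t`/`A0` observations that were fitted.
#' @param ids Which series to draw (default: first 9 fitted IDs).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot turnover_fits
#' @export
autoplot.turnover_fits <- function(object, series, ids = NULL, ...) {
  check_columns(series, c("ID", "t", "A0"), "series")
  fitted_rows <- object[is.finite(object$k), ]
  ids <- ids %||% head(fitted_rows$ID, 9)
  rows <- fitted_rows[fitted_rows$ID %in% ids, ]
  obs <- series[series$ID %in% ids, ]
  t_grid <- seq(0, max(obs$t), length.out = 100)
  curves <- purrr::pmap_dfr(
    rows[, c("ID", "k", "a", "N", "p_ss", "k_p")],
    function(ID, k, a, N, p_ss, k_p) {
      tibble::tibble(ID = ID, t = t_grid,
                     A0 = model_a0(k, t_grid, a, N, p_ss, k_p))
    }
  )
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$t, y = .data$A0)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = curves, colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$ID)) +
    ggplot2::labs(x = "time (d)", y = expression(A[0]),
                  title = "Peptide isotopomer decay and fitted kinetics")
}

#' Plot a fitted body-water enrichment curve
#'
#' @param object An `enrichment_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_fit
#' @export
autoplot.enrichment_fit <- function(object, ...) {
  t_grid <- seq(0, max(object$data$t), length.out = 200)
  curve <- tibble::tibble(t = t_grid, p = predict(object, t_grid))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$p)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(x = "time (d)", y = "body-water enrichment p",
                  title = sprintf("p(t) = %.3g (1 - exp(-%.3g t))",
                                  object$p_ss, object$k_p))
}

#' Heatmap of a stringency-filter sweep
#'
#' Intra-protein variability (fill) over the grid of R-squared and
#' standard-error cutoffs explored by [filter_sweep()].
#'
#' @param sweep Output of [filter_sweep()].
#' @param fill `"variability_pct"` (default) or `"n_accepted"`.
#' @return A ggplot object.
#' @export
plot_filter_sweep <- function(sweep, fill = c("variability_pct", "n_accepted")) {
  fill <- match.arg(fill)
  check_columns(sweep, c("r2_min", "se_max", fill), "sweep")
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$se_max, y = .data$r2_min,
                                      fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "s.e. cutoff", y = expression(R^2 ~ "cutoff"),
                  fill = fill,
                  title = "Stringency-filter sweep")
}

#' Distribution of fitted turnover rates
#'
#' Histogram of log2 rate constants with the median marked.
#'
#' @param fits A `turnover_fits` tibble (or any table with a `k` column).
#' @return A ggplot object.
#' @export
plot_rate_distribution <- function(fits) {
  check_columns(fits, "k", "fits")
  k <- fits$k[is.finite(fits$k)]
  ggplot2::ggplot(tibble::tibble(log2k = log2(k)),
                  ggplot2::aes(x = .data$log2k)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = log2(stats::median(k)),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(log[2] ~ k ~ (d^-1)), y = "peptides",
                  title = "Turnover rate distribution")
}
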
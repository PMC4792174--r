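#' Extract an ion chromatogram from spectrum slices
#'
#' Per retention-time slice, sums the intensity of all centroids within a
#' ppm window of the target m/z. The window is half-open,
#' `[mz (1 - d), mz (1 + d))` with `d = ppm * 1e-6`.
#'
#' @param spectra Data frame of centroided spectrum slices with columns `rt`
#'   (retention time), `mz` and `intensity`; m/z must be strictly increasing
#'   within each slice.
#' @param mz Target m/z.
#' @param ppm Window half-width in parts per million (default 60).
#' @return Tibble `rt`, `intensity`, one row per slice in time order (empty
#'   input gives an empty trace).
#' @export
extract_xic <- function(spectra, mz, ppm = 60) {
  check_columns(spectra, c("rt", "mz", "intensity"), "spectra")
  stopifnot(ppm > 0, mz > 0)
  if (nrow(spectra) == 0) {
    return(tibble::tibble(rt = numeric(), intensity = numeric()))
  }
  if (any(spectra$intensity < 0)) abort("intensities must be non-negative")
  delta <- ppm * 1e-6 * mz
  lo <- mz - delta
  hi <- mz + delta
  hit <- spectra$mz >= lo & spectra$mz < hi
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(spectra), .data$rt),
    intensity = sum(.data$intensity[hit[dplyr::cur_group_rows()]]),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$rt)
}

#' Savitzky-Golay smoothing of a chromatographic trace
#'
#' Quadratic Savitzky-Golay convolution over a fixed odd window (default 7
#' points). The filter preserves polynomials up to the fit order, so constant
#' and linear traces pass through unchanged. Traces shorter than the window
#' are returned unsmoothed with a warning.
#'
#' @param trace Data frame with columns `rt`, `intensity` (from
#'   [extract_xic()]).
#' @param window Odd window length >= 5 (default 7).
#' @param order Polynomial order (default 2).
#' @return The trace tibble with smoothed `intensity`.
#' @export
smooth_trace <- function(trace, window = 7, order = 2) {
  check_columns(trace, c("rt", "intensity"), "trace")
  if (window %% 2 != 1 || window < 5) abort("window must be odd and >= 5")
  trace <- tibble::as_tibble(trace)
  if (nrow(trace) < window) {
    warn("trace shorter than the smoothing window; returned unsmoothed")
    return(trace)
  }
  dplyr::mutate(trace,
                intensity = signal::sgolayfilt(.data$intensity, p = order,
                                               n = window))
}

#' Integrate a peptide isotope envelope over elution
#'
#' For each mass isotopomer `mi = 0..n_isotopomers - 1`, extracts the XIC at
#' `mz + mi * (neutron mass) / z`, smooths it, and integrates the trapezoidal
#' area under the curve between the supplied elution bounds. Areas are
#' normalized to fractional abundances that sum to 1; the 0th fraction is the
#' experimental `A0` the kinetic model consumes.
#'
#' @inheritParams extract_xic
#' @param z Charge state.
#' @param n_isotopomers Number of envelope peaks to integrate (default 5).
#' @param rt_range Length-2 numeric elution bounds (from the identification,
#'   with a tolerance); at least 2 slices must fall inside.
#' @param window,order Smoothing parameters, see [smooth_trace()].
#' @return Tibble `mi`, `area`, `fraction`.
#' @export
integrate_envelope <- function(spectra, mz, z, n_isotopomers = 5, rt_range,
                               ppm = 60, window = 7, order = 2) {
  stopifnot(z >= 1, n_isotopomers >= 1, length(rt_range) == 2)
  rows <- purrr::map(seq_len(n_isotopomers) - 1L, function(mi) {
    xic <- extract_xic(spectra, mz + mi * NEUTRON_MASS / z, ppm = ppm)
    if (nrow(xic) >= window) xic <- smooth_trace(xic, window, order)
    xic <- xic[xic$rt >= rt_range[1] & xic$rt <= rt_range[2], ]
    if (nrow(xic) < 2) {
      abort("fewer than 2 spectra within the elution bounds")
    }
    tibble::tibble(mi = mi,
                   area = pracma::trapz(xic$rt, pmax(xic$intensity, 0)))
  })
  out <- dplyr::bind_rows(rows)
  total <- sum(out$area)
  if (total <= 0) abort("all isotopomer areas are zero; integration failed")
  dplyr::mutate(out, fraction = .data$area / total)
}
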
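#' Stringency filtering of fitted peptide time series
#'
#' A fitted series is accepted when it has at least `min_dp` distinct time
#' points AND satisfies at least one of the two quality branches: goodness of
#' fit `R2 >= r2_min`, or standard error of estimate `se <= se_max`. The
#' s.e. branch rescues slow-turnover peptides whose nearly flat decay curves
#' have low `R2` despite being well measured. Rejected rows are retained and
#' labeled with the reason, so downstream steps can report full accounting.
#'
#' @param fits A `turnover_fits` tibble (or any data frame with columns `DP`,
#'   `R2`, `se`).
#' @param min_dp Minimum number of distinct time points (default 4).
#' @param r2_min Goodness-of-fit acceptance threshold (default 0.8).
#' @param se_max Standard-error acceptance threshold in A0 units
#'   (default 0.05).
#' @return The input tibble, order preserved, with added logical `accepted`
#'   and character `reject_reason` (`NA` when accepted).
#' @examples
#' toy <- tibble::tibble(DP = c(3, 4), R2 = c(0.99, 0.85), se = c(0.01, 0.2))
#' apply_stringency_filter(toy)
#' @export
apply_stringency_filter <- function(fits, min_dp = 4, r2_min = 0.8,
                                    se_max = 0.05) {
  check_columns(fits, c("DP", "R2", "se"), "fits")
  # r2_min may exceed 1 (an unattainable cutoff accepts nothing by that branch)
  stopifnot(min_dp >= 2, se_max > 0)
  r2 <- ifelse(is.na(fits$R2), -Inf, fits$R2)
  se <- ifelse(is.na(fits$se), Inf, fits$se)
  enough_dp <- fits$DP >= min_dp
  quality <- r2 >= r2_min | se <= se_max
  accepted <- enough_dp & quality
  reason <- dplyr::case_when(
    accepted ~ NA_character_,
    !enough_dp ~ "too_few_timepoints",
    TRUE ~ "poor_fit"
  )
  out <- dplyr::mutate(tibble::as_tibble(fits),
                       accepted = accepted, reject_reason = reason)
  if (inherits(fits, "turnover_fits")) {
    class(out) <- unique(c("turnover_fits", class(out)))
  }
  out
}

#' Protein-level turnover roll-up
#'
#' Aggregates accepted peptide rate constants to the protein level: the
#' protein turnover rate is the median of its member peptide `k` values and
#' the dispersion is the (unscaled) median absolute deviation,
#' `median(|k_i - median(k)|)`. Grouping is by protein accession, and
#' additionally by a `sample` column if present.
#'
#' @param fits A data frame of fitted peptides with columns `uniprot` and `k`
#'   (and optionally `sample`, `accepted`). If an `accepted` column is
#'   present, only accepted rows are used.
#' @return Tibble with columns (`sample`,) `uniprot`, `k_median`, `k_mad`,
#'   `n_peptides`, `half_life`.
#' @examples
#' df <- tibble::tibble(uniprot = "P1", k = c(1, 2, 3))
#' rollup_proteins(df)
#' @export
rollup_proteins <- function(fits) {
  check_columns(fits, c("uniprot", "k"), "fits")
  if ("accepted" %in% names(fits)) fits <- fits[fits$accepted %in% TRUE, ]
  fits <- fits[is.finite(fits$k), ]
  if (nrow(fits) == 0) abort("no accepted peptides to roll up")
  keys <- intersect(c("sample", "uniprot"), names(fits))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(fits), dplyr::across(dplyr::all_of(keys))),
    k_median = stats::median(.data$k),
    k_mad = mad_raw(.data$k),
    n_peptides = dplyr::n(),
    .groups = "drop"
  )
  dplyr::mutate(out, half_life = log(2) / .data$k_median)
}

#' Intra-protein variability of turnover rates
#'
#' Experiment-level quality statistic: the median, over proteins quantified
#' by at least two accepted peptides, of the protein's relative dispersion
#' `k_mad / k_median`, expressed as a percentage. Values under ~30% indicate
#' acceptable internal consistency, since peptides of one protein should
#' report the same turnover rate.
#'
#' @param rollups Output of [rollup_proteins()].
#' @return Single numeric percentage.
#' @export
intra_protein_variability <- function(rollups) {
  check_columns(rollups, c("k_median", "k_mad", "n_peptides"), "rollups")
  multi <- rollups[rollups$n_peptides >= 2, ]
  if (nrow(multi) == 0) {
    abort("no protein with >= 2 accepted peptides; variability undefined")
  }
  100 * stats::median(multi$k_mad / multi$k_median)
}

#' Sweep the stringency-filter cutoffs
#'
#' Applies the OR-filter over a grid of (`r2_min`, `se_max`) cutoff pairs and
#' reports, for each pair, the number of accepted peptides and the
#' intra-protein variability of the resulting acceptance set. Acceptance
#' counts are non-increasing in `r2_min` at fixed `se_max` and non-decreasing
#' in `se_max` at fixed `r2_min`.
#'
#' @param fits Fitted peptides (columns `uniprot`, `k`, `DP`, `R2`, `se`).
#' @param r2_grid,se_grid Sorted numeric grids of cutoffs.
#' @param min_dp Time-point filter applied throughout.
#' @return Tibble with columns `r2_min`, `se_max`, `n_accepted`,
#'   `variability_pct` (`NA` when undefined: empty acceptance or no
#'   multi-peptide protein).
#' @export
filter_sweep <- function(fits, r2_grid, se_grid, min_dp = 4) {
  if (length(r2_grid) == 0 || length(se_grid) == 0) {
    abort("cutoff grids must be nonempty")
  }
  if (is.unsorted(r2_grid) || is.unsorted(se_grid)) {
    abort("cutoff grids must be sorted ascending")
  }
  grid <- tidyr::expand_grid(r2_min = r2_grid, se_max = se_grid)
  res <- purrr::pmap(grid, function(r2_min, se_max) {
    flt <- apply_stringency_filter(fits, min_dp = min_dp, r2_min = r2_min,
                                   se_max = se_max)
    acc <- flt[flt$accepted, ]
    var_pct <- NA_real_
    if (nrow(acc) > 0 && "uniprot" %in% names(acc)) {
      roll <- rollup_proteins(acc)
      if (any(roll$n_peptides >= 2)) {
        var_pct <- intra_protein_variability(roll)
      }
    }
    tibble::tibble(n_accepted = nrow(acc), variability_pct = var_pct)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  class(out) <- c("filter_sweep", class(out))
  out
}
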
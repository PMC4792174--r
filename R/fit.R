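#' Fit the turnover rate constant of one peptide time series
#'
#' Minimizes the residual sum of squares of the analytic kinetic model
#' [model_a0()] over `k` using the Nelder-Mead simplex (the reported
#' estimate), restarted from several initial values and cross-checked with an
#' independent quasi-Newton (BFGS-style, bounded) optimization over the same
#' restart grid; the two optimizers agree to high precision on well-posed
#' series and the quasi-Newton estimate is kept in the result for auditing.
#'
#' Fit statistics follow the pipeline's conventions:
#' * `SS` residual sum of squares;
#' * `R2 = 1 - SS / sum((A0 - mean(A0))^2)` (may be negative for flat series);
#' * `se` standard error of estimate in A0 units, by default
#'   `sqrt(SS / (DP - 1))` (one fitted parameter; configurable denominator);
#' * `dk` linearized one-parameter standard error,
#'   `sqrt(se^2 / sum((dA0/dk)^2))` with a numerical derivative at the optimum.
#'
#' @param t,A0 Observation times (days) and 0th-isotopomer fractions.
#' @inheritParams kinetic_model
#' @param k_init Initial values for the simplex; the best of the restarts is
#'   kept.
#' @param k_bounds Search bounds on `k` (per day).
#' @param se_denominator One of `"dp-1"`, `"dp"`, `"dp-2"`.
#' @return A `kinetic_fit` object (list) with elements `k`, `dk`, `SS`, `R2`,
#'   `se`, `DP`, `converged`, `pinned`, `k_nm`, `k_qn`, `n_eval`. Supports
#'   [tidy()] and [glance()].
#' @examples
#' tt <- c(0, 1, 3, 5, 7, 10, 14)
#' y <- model_a0(0.1, tt, a = 0.5, N = 20, p_ss = 0.045, k_p = 2)
#' fit_k(tt, y, a = 0.5, N = 20, p_ss = 0.045, k_p = 2)
#' @export
fit_k <- function(t, A0, a, N, p_ss, k_p,
                  k_init = c(0.1, 0.01, 1),
                  k_bounds = c(1e-4, 20),
                  se_denominator = c("dp-1", "dp", "dp-2")) {
  se_denominator <- match.arg(se_denominator)
  stopifnot(length(t) == length(A0), length(t) >= 2)
  DP <- length(unique(t))
  lo <- k_bounds[1]; hi <- k_bounds[2]

  n_eval <- 0L
  ss_fun <- function(k) {
    n_eval <<- n_eval + 1L
    if (!is.finite(k) || k < lo || k > hi) {
      # steer the simplex back into the box
      return(1e6 * (1 + min(abs(k - lo), abs(k - hi))))
    }
    sum((A0 - model_a0(k, t, a, N, p_ss, k_p))^2)
  }

  runs <- lapply(k_init, function(k0) {
    suppressWarnings(optim(k0, ss_fun, method = "Nelder-Mead",
                           control = list(reltol = 1e-14, maxit = 1000)))
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  k_nm <- min(max(best$par, lo), hi)

  # independent quasi-Newton pass from the same restart grid, for auditing
  qn_runs <- lapply(k_init, function(k0) {
    tryCatch(
      suppressWarnings(optim(k0, ss_fun, method = "L-BFGS-B",
                             lower = lo, upper = hi,
                             control = list(factr = 10, pgtol = 1e-14,
                                            ndeps = 1e-7))),
      error = function(e) NULL
    )
  })
  qn_runs <- qn_runs[!vapply(qn_runs, is.null, logical(1))]
  k_qn <- if (length(qn_runs) == 0) NA_real_ else {
    qn_runs[[which.min(vapply(qn_runs, `[[`, numeric(1), "value"))]]$par
  }

  k_hat <- k_nm
  SS <- sum((A0 - model_a0(k_hat, t, a, N, p_ss, k_p))^2)
  TSS <- sum((A0 - mean(A0))^2)
  R2 <- if (TSS > 0) 1 - SS / TSS else NA_real_
  denom <- switch(se_denominator, "dp-1" = DP - 1, "dp" = DP, "dp-2" = DP - 2)
  se <- if (denom > 0) sqrt(SS / denom) else NA_real_

  h <- 1e-6 * max(k_hat, 1e-3)
  grad <- (model_a0(min(k_hat + h, hi), t, a, N, p_ss, k_p) -
             model_a0(max(k_hat - h, lo), t, a, N, p_ss, k_p)) /
    (min(k_hat + h, hi) - max(k_hat - h, lo))
  gss <- sum(grad^2)
  dk <- if (gss > 0 && is.finite(se)) sqrt(se^2 / gss) else NA_real_

  pinned <- (k_hat - lo) < 1e-6 * (hi - lo) || (hi - k_hat) < 1e-6 * (hi - lo)
  structure(
    list(k = k_hat, dk = dk, SS = SS, R2 = R2, se = se, DP = DP,
         converged = best$convergence == 0 && !pinned, pinned = pinned,
         k_nm = k_nm, k_qn = k_qn, n_eval = n_eval,
         a = a, N = N, p_ss = p_ss, k_p = k_p),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "Kinetic fit: k = %.4g /d (dk %.2g), half-life %.3g d, R2 = %.3f, se = %.3g, DP = %d%s\n",
    x$k, x$dk, log(2) / x$k, x$R2, x$se, x$DP,
    if (!x$converged) " [not converged]" else ""
  ))
  invisible(x)
}

#' Fit turnover rates for a table of peptide time series
#'
#' Joins the isotopomer time series with the peptide metadata, derives the
#' model constants per peptide (`a` from the natural isotope envelope, `N`
#' from the labeling-site table), and fits the turnover rate constant of each
#' (sequence, modification, charge)-unique peptide with [fit_k()]. The result
#' carries the full set of per-peptide columns the pipeline's `hl.out` format
#' documents.
#'
#' @param series Data frame with columns `ID`, `t`, `A0` (the `hl-data.out`
#'   layout).
#' @param metadata Data frame with columns `ID`, `uniprot`, `peptide`, `z`,
#'   and optionally `mods` (semicolon-separated modification names).
#' @param enrichment An `enrichment_fit` object, or a list/row with elements
#'   `p_ss` and `k_p`.
#' @param min_dp Series with fewer distinct time points are not fitted (their
#'   row is kept with `NA` estimates and `converged = FALSE`), mirroring the
#'   >= 4 time-point acceptance rule.
#' @param n_peaks Envelope truncation passed to [isotope_envelope()].
#' @inheritParams fit_k
#' @inheritParams peptide_composition
#' @param site_table Optional replacement labeling-site table.
#' @return A `turnover_fits` tibble with columns `ID`, `uniprot`, `peptide`,
#'   `mods`, `DP`, `z`, `mi`, `SS`, `a`, `p_ss`, `k_p`, `N`, `k`, `dk`, `R2`,
#'   `se`, `converged`, `k_qn`. Supports [glance()] and [autoplot()].
#' @examples
#' sim <- generate_experiment(n_proteins = 2, seed = 1)
#' fits <- fit_turnover(sim$series, sim$metadata, sim$enrichment)
#' @export
fit_turnover <- function(series, metadata, enrichment,
                         min_dp = 2,
                         k_init = c(0.1, 0.01, 1), k_bounds = c(1e-4, 20),
                         se_denominator = "dp-1",
                         n_peaks = 5,
                         residue_table = NULL, modification_table = NULL,
                         site_table = NULL) {
  check_columns(series, c("ID", "t", "A0"), "series")
  check_columns(metadata, c("ID", "uniprot", "peptide", "z"), "metadata")
  if (any(series$A0 < 0 | series$A0 > 1)) abort("A0 values must lie in [0, 1]")
  if (!"mods" %in% names(metadata)) metadata$mods <- ""
  if (inherits(enrichment, "enrichment_fit")) {
    p_ss <- enrichment$p_ss; k_p <- enrichment$k_p
  } else {
    p_ss <- enrichment$p_ss %||% enrichment[["p_ss"]]
    k_p <- enrichment$k_p %||% enrichment[["k_p"]]
  }
  if (is.null(p_ss) || is.null(k_p)) abort("enrichment must provide p_ss and k_p")

  residue_table <- residue_table %||% load_residue_table()
  modification_table <- modification_table %||% load_modifications()
  site_table <- site_table %||% load_labeling_sites()
  isotope_table <- load_isotope_table()

  meta <- dplyr::distinct(tibble::as_tibble(metadata), .data$ID,
                          .keep_all = TRUE)
  orphan <- setdiff(unique(series$ID), meta$ID)
  if (length(orphan) > 0) {
    abort(paste0("series IDs missing from metadata: ",
                 paste(head(orphan, 5), collapse = ", ")))
  }

  nested <- tidyr::nest(
    dplyr::select(tibble::as_tibble(series), "ID", "t", "A0"),
    data = c("t", "A0")
  )
  nested <- dplyr::left_join(nested, meta, by = "ID")

  rows <- purrr::pmap(
    list(nested$ID, nested$data, nested$uniprot, nested$peptide,
         nested$z, nested$mods),
    function(id, dat, uniprot, peptide, z, mods) {
      mod_list <- mods_to_list(mods)
      comp <- peptide_composition(peptide, mod_list, residue_table,
                                  modification_table)
      a <- natural_a0(isotope_envelope(comp, isotope_table, n_peaks))
      N <- count_sites(peptide, site_table)
      DP <- length(unique(dat$t))
      if (DP < min_dp) {
        return(tibble::tibble(
          ID = id, uniprot = uniprot, peptide = peptide, mods = mods,
          DP = DP, z = z, mi = 0L, SS = NA_real_, a = a, p_ss = p_ss,
          k_p = k_p, N = N, k = NA_real_, dk = NA_real_, R2 = NA_real_,
          se = NA_real_, converged = FALSE, k_qn = NA_real_
        ))
      }
      fit <- fit_k(dat$t, dat$A0, a, N, p_ss, k_p,
                   k_init = k_init, k_bounds = k_bounds,
                   se_denominator = se_denominator)
      tibble::tibble(
        ID = id, uniprot = uniprot, peptide = peptide, mods = mods,
        DP = DP, z = z, mi = 0L, SS = fit$SS, a = a, p_ss = p_ss, k_p = k_p,
        N = N, k = fit$k, dk = fit$dk, R2 = fit$R2, se = fit$se,
        converged = fit$converged, k_qn = fit$k_qn
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  class(out) <- c("turnover_fits", class(out))
  out
}

mods_to_list <- function(mods) {
  if (is.null(mods) || is.na(mods) || !nzchar(mods)) return(character())
  trimws(strsplit(mods, ";", fixed = TRUE)[[1]])
}
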
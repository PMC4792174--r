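#' Study design of a multi-strain labeling experiment
#'
#' Describes the bookkeeping of a heavy-water labeling study: mouse strains,
#' conditions, sampling days per condition, LC-MS/MS runs per sample group
#' (a sample group is one strain x condition x time point), and animals
#' euthanized per group per day. Defaults reproduce the full cardiac study
#' design: 6 strains, normal animals sampled at days {0,1,3,5,7,10,14} and
#' hypertrophy animals at a 6-day variant, 18 runs per group, 2 animals per
#' group per day.
#'
#' @param strains Number of genetic strains (default 6).
#' @param conditions Character vector of conditions.
#' @param days Named list of sampling-day vectors, one per condition; each
#'   must be sorted ascending and include day 0.
#' @param runs_per_group LC-MS/MS runs per sample group (default 18,
#'   reflecting 12 high-pH fractions x subcellular fractionation per group).
#' @param animals_per_day Animals euthanized per group per day (default 2).
#' @return A `study_design` list.
#' @examples
#' design_manifest(study_design())
#' @export
study_design <- function(strains = 6,
                         conditions = c("normal", "hypertrophy"),
                         days = list(normal = c(0, 1, 3, 5, 7, 10, 14),
                                     hypertrophy = c(0, 1, 3, 5, 7, 10)),
                         runs_per_group = 18,
                         animals_per_day = 2) {
  stopifnot(strains >= 1, length(conditions) >= 1, runs_per_group >= 1,
            animals_per_day >= 1)
  if (!setequal(names(days), conditions)) {
    abort("'days' must be a named list with one entry per condition")
  }
  for (cond in conditions) {
    d <- days[[cond]]
    if (is.unsorted(d) || d[1] != 0) {
      abort("sampling days must be sorted ascending and include day 0")
    }
  }
  structure(list(strains = strains, conditions = conditions, days = days,
                 runs_per_group = runs_per_group,
                 animals_per_day = animals_per_day),
            class = "study_design")
}

#' Manifest counts of a study design
#'
#' @param design A [study_design()].
#' @return Tibble with one row: `groups` (sample groups = strain x condition
#'   x time point), `runs` (LC-MS/MS experiments), `animals`.
#' @examples
#' design_manifest(study_design())  # 78 groups, 1404 runs, 156 animals
#' @export
design_manifest <- function(design) {
  stopifnot(inherits(design, "study_design"))
  day_counts <- vapply(design$days, length, integer(1))
  groups <- design$strains * sum(day_counts)
  tibble::tibble(
    groups = groups,
    runs = groups * design$runs_per_group,
    animals = design$strains * design$animals_per_day * sum(day_counts)
  )
}

#' Sample peptide turnover rate constants
#'
#' Draws rate constants whose distribution matches a stated median and
#' interdecile range. When the bounds are geometrically symmetric about the
#' median the sampler is an exact log-normal (location `log(median)`, scale
#' from the decile spread). Real interdecile ranges are usually asymmetric in
#' log space; a two-parameter log-normal cannot then match the median and
#' both deciles, so the sampler uses a two-piece normal in log space:
#' location `log(median)`, with separate left/right scales set so the
#' theoretical 10th and 90th percentiles equal the given bounds exactly.
#'
#' @param n Number of rates to draw.
#' @param k_median Target median (per day; default 0.094).
#' @param k_p10,k_p90 Target 10th/90th percentiles (defaults 0.037, 0.30 per
#'   day). `k_p10 = k_p90 = k_median` gives the degenerate point mass.
#' @param seed Optional integer seed (local; does not disturb the global RNG
#'   stream when supplied).
#' @return Numeric vector of `n` positive rates.
#' @examples
#' k <- generate_rates(1000, seed = 1)
#' stats::median(k)
#' @export
generate_rates <- function(n, k_median = 0.094, k_p10 = 0.037, k_p90 = 0.30,
                           seed = NULL) {
  if (!(k_p10 <= k_median && k_median <= k_p90) || k_p10 <= 0) {
    abort("need 0 < k_p10 <= k_median <= k_p90")
  }
  draw <- function() {
    if (k_p10 == k_median && k_p90 == k_median) return(rep(k_median, n))
    z90 <- qnorm(0.9)
    s_left <- (log(k_median) - log(k_p10)) / z90
    s_right <- (log(k_p90) - log(k_median)) / z90
    z <- rnorm(n)
    s <- ifelse(z < 0, s_left, s_right)
    exp(log(k_median) + s * z)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# random protein sequence with tryptic-like K/R frequency
random_protein <- function(length) {
  aa <- c("A","R","N","D","C","E","Q","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  freq <- c(8.3, 5.6, 4.1, 5.5, 1.4, 6.8, 3.9, 7.1, 2.3, 6.0, 9.7, 5.8,
            2.4, 3.9, 4.7, 6.6, 5.4, 1.1, 2.9, 6.9)
  paste(sample(aa, length, replace = TRUE, prob = freq), collapse = "")
}

#' Generate a complete synthetic labeling experiment
#'
#' Emulates one sample group's worth of data with the statistical structure
#' the pipeline assumes: synthetic protein sequences are digested in silico;
#' tryptic peptides 6-30 residues long are assigned their true `a` (natural
#' envelope) and `N` (labeling sites); protein-level turnover rates are drawn
#' from the study's rate distribution; 0th-isotopomer time series follow the
#' non-steady-state kinetic model plus Gaussian measurement noise (clamped to
#' [0, 1]); and body-water GC-MS measurements (standard curve and sample
#' ratios) follow the first-order enrichment curve. Output is deterministic
#' under a fixed seed.
#'
#' @param n_proteins Number of synthetic proteins (default 20).
#' @param peptides_per_protein Maximum quantified peptides sampled per
#'   protein (default 6).
#' @param protein_length Mean protein length in residues (default 300).
#' @param days Sampling days (default the full 7-point schedule).
#' @param noise_sd Gaussian noise sd on A0 (default 0.01).
#' @param p_ss,k_p True body-water enrichment parameters (defaults 0.045 and
#'   2 per day: plausible rodent values for an 8% v/v drinking supply with a
#'   priming bolus; not study-measured values).
#' @param bw_noise_sd Noise sd on body-water enrichment measurements
#'   (default 0.002).
#' @param k_median,k_p10,k_p90 Rate-distribution targets, see
#'   [generate_rates()].
#' @param charges Charge states sampled per peptide.
#' @param seed Integer seed; required for reproducible output (`NULL` uses
#'   the current RNG state).
#' @return A `turnover_experiment` list with tibbles `metadata` (ID, uniprot,
#'   peptide, z, mods), `series` (ID, t, A0), `truth` (per-peptide true k, a,
#'   N), `proteins` (uniprot, sequence), `bodywater` (t, ratio, p_true),
#'   `standard_curve` (fraction, ratio), the true `enrichment` parameters,
#'   and the `seed`.
#' @examples
#' sim <- generate_experiment(n_proteins = 3, seed = 42)
#' head(sim$series)
#' @export
generate_experiment <- function(n_proteins = 20, peptides_per_protein = 6,
                                protein_length = 300,
                                days = c(0, 1, 3, 5, 7, 10, 14),
                                noise_sd = 0.01,
                                p_ss = 0.045, k_p = 2, bw_noise_sd = 0.002,
                                k_median = 0.094, k_p10 = 0.037, k_p90 = 0.30,
                                charges = 2:3, seed = NULL) {
  run <- function() {
    residue_table <- load_residue_table()
    isotope_table <- load_isotope_table()
    site_table <- load_labeling_sites()

    proteins <- tibble::tibble(
      uniprot = sprintf("SYN%04d", seq_len(n_proteins)),
      sequence = vapply(seq_len(n_proteins), function(i) {
        random_protein(max(50, round(rnorm(1, protein_length, protein_length / 5))))
      }, character(1))
    )
    k_protein <- generate_rates(n_proteins, k_median, k_p10, k_p90)

    meta_rows <- purrr::map(seq_len(n_proteins), function(i) {
      peps <- digest_sequence(proteins$sequence[i])
      peps <- unique(peps[nchar(peps) >= 6 & nchar(peps) <= 30])
      if (length(peps) == 0) return(NULL)
      keep <- sample(seq_along(peps), min(peptides_per_protein, length(peps)))
      tibble::tibble(uniprot = proteins$uniprot[i],
                     peptide = peps[keep],
                     z = sample(charges, length(keep), replace = TRUE),
                     k_true = k_protein[i])
    })
    meta <- dplyr::bind_rows(meta_rows)
    meta <- dplyr::distinct(meta, .data$peptide, .data$z, .keep_all = TRUE)
    meta$ID <- seq_len(nrow(meta))
    meta$mods <- ""

    meta$a <- vapply(meta$peptide, function(p) {
      natural_a0(isotope_envelope(
        peptide_composition(p, residue_table = residue_table),
        isotope_table))
    }, numeric(1), USE.NAMES = FALSE)
    meta$N <- count_sites(meta$peptide, site_table)

    series <- tidyr::expand_grid(ID = meta$ID, t = days)
    series <- dplyr::left_join(series,
                               meta[, c("ID", "a", "N", "k_true")], by = "ID")
    series$A0 <- pmin(pmax(
      purrr::pmap_dbl(series[, c("k_true", "t", "a", "N")],
                      function(k_true, t, a, N) {
                        model_a0(k_true, t, a, N, p_ss, k_p)
                      }) + rnorm(nrow(series), sd = noise_sd), 0), 1)

    # GC-MS fixtures: linear instrument response ratio = baseline + p / slope
    # with slope 0.5 and a natural-isotope baseline of 0.05 (synthetic, fixed
    # values, not study-measured); 11-point standard curve plus sample ratios
    slope <- 0.5
    baseline <- 0.05
    std <- tibble::tibble(fraction = seq(0, 0.20, length.out = 11))
    std$ratio <- baseline + std$fraction / slope + rnorm(11, sd = 0.001)
    p_true <- p_ss * (1 - exp(-k_p * days))
    bodywater <- tibble::tibble(
      t = days,
      p_true = p_true,
      ratio = baseline +
        pmax(p_true + rnorm(length(days), sd = bw_noise_sd), 0) / slope
    )

    structure(
      list(
        metadata = meta[, c("ID", "uniprot", "peptide", "z", "mods")],
        series = series[, c("ID", "t", "A0")],
        truth = meta[, c("ID", "uniprot", "peptide", "z", "a", "N", "k_true")],
        proteins = proteins,
        bodywater = bodywater,
        standard_curve = std,
        enrichment = list(p_ss = p_ss, k_p = k_p),
        noise_sd = noise_sd,
        seed = seed
      ),
      class = "turnover_experiment"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.turnover_experiment <- function(x, ...) {
  cat(sprintf(
    "Synthetic labeling experiment: %d proteins, %d peptide series, %d observations\n",
    nrow(x$proteins), nrow(x$metadata), nrow(x$series)))
  cat(sprintf("  enrichment p_ss = %.3g, k_p = %.3g /d; A0 noise sd = %.3g; seed = %s\n",
              x$enrichment$p_ss, x$enrichment$k_p, x$noise_sd,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Synthetic spectra for one peptide's isotope envelope
#'
#' Builds centroided spectrum slices over a retention-time grid in which each
#' isotopomer of a peptide appears as a centroid at
#' `mz + mi * (neutron mass) / z` with a Gaussian elution profile scaled by
#' the envelope fraction. Used to exercise the XIC-extraction and
#' envelope-integration front end against a known ground truth.
#'
#' @param mz Monoisotopic m/z of the peptide.
#' @param z Charge state.
#' @param envelope Fractional abundances per isotopomer (e.g. from
#'   [isotope_envelope()]).
#' @param rt Retention-time grid (default 60 slices over 0..6).
#' @param rt_center,rt_sd Elution apex and width.
#' @param scale Total intensity scale.
#' @param noise_sd Multiplicative intensity noise sd (0 = noiseless).
#' @return Tibble `rt`, `mz`, `intensity` (one row per isotopomer centroid
#'   per slice).
#' @export
generate_peptide_spectra <- function(mz, z, envelope,
                                     rt = seq(0, 6, length.out = 61),
                                     rt_center = 3, rt_sd = 0.5,
                                     scale = 1e6, noise_sd = 0) {
  stopifnot(z >= 1, all(envelope >= 0))
  grid <- tidyr::expand_grid(rt = rt, mi = seq_along(envelope) - 1L)
  out <- dplyr::mutate(
    grid,
    mz = mz + .data$mi * NEUTRON_MASS / z,
    intensity = scale * envelope[.data$mi + 1L] *
      exp(-((.data$rt - rt_center)^2) / (2 * rt_sd^2))
  )
  if (noise_sd > 0) {
    out$intensity <- pmax(out$intensity *
                            (1 + rnorm(nrow(out), sd = noise_sd)), 0)
  }
  dplyr::arrange(dplyr::select(out, "rt", "mz", "intensity"),
                 .data$rt, .data$mz)
}
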
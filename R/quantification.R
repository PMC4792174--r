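#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after every K or R not followed by P. With
#' `missed_cleavages = 0` the products concatenate back to the original
#' sequence; higher values additionally emit peptides spanning up to that
#' many internal cleavage sites.
#'
#' @param sequence Protein sequence (single string).
#' @param missed_cleavages Maximum number of internal missed cleavage sites.
#' @return Character vector of peptides, N- to C-terminal order (fully
#'   cleaved products first when `missed_cleavages > 0`).
#' @examples
#' digest_sequence("AKRPGKT")
#' @export
digest_sequence <- function(sequence, missed_cleavages = 0) {
  stopifnot(is.character(sequence), length(sequence) == 1, missed_cleavages >= 0)
  base <- strsplit(sequence, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
  if (missed_cleavages == 0) return(base)
  out <- base
  for (m in seq_len(missed_cleavages)) {
    if (length(base) <= m) break
    for (i in seq_len(length(base) - m)) {
      out <- c(out, paste(base[i:(i + m)], collapse = ""))
    }
  }
  out
}

#' Count quantifiable tryptic peptides
#'
#' Number of fully cleaved tryptic peptides of a protein whose length falls
#' in `[min_length, max_length]` (inclusive). This count normalizes the
#' XIC-based abundance of a protein for its expected peptide yield.
#'
#' @param sequence Character vector of protein sequences.
#' @param min_length,max_length Inclusive peptide-length bounds (defaults
#'   6 and 30).
#' @param missed_cleavages Passed to [digest_sequence()] (default 0:
#'   "possible tryptic peptides" are the fully cleaved products).
#' @return Integer vector of counts.
#' @examples
#' count_quantifiable_peptides("MKAAAAAAK")
#' @export
count_quantifiable_peptides <- function(sequence, min_length = 6,
                                        max_length = 30,
                                        missed_cleavages = 0) {
  stopifnot(min_length <= max_length)
  vapply(sequence, function(s) {
    len <- nchar(digest_sequence(s, missed_cleavages))
    sum(len >= min_length & len <= max_length)
  }, integer(1), USE.NAMES = FALSE)
}

#' XIC-based relative protein abundance
#'
#' Three-stage normalization of summed peptide isotope-envelope areas into
#' within-sample relative protein abundances:
#' 1. each peptide's summed envelope area is divided by the run's total
#'    spectral intensity;
#' 2. the relative areas are summed per protein and divided by the protein's
#'    count of possible tryptic peptides 6-30 residues long;
#' 3. protein values are divided by their within-time-point total, so each
#'    time point's abundances sum to 1.
#'
#' @param areas Data frame with columns `peptide`, `time`, `area` (summed
#'   isotope-envelope area of the peptide in that run).
#' @param peptide_map Data frame with columns `peptide`, `uniprot`; every
#'   peptide must map to exactly one protein.
#' @param proteins Data frame with columns `uniprot`, `sequence` (used for
#'   the in-silico digestion count), or columns `uniprot`,
#'   `n_quant_peptides` to supply precomputed counts.
#' @param run_totals Optional data frame `time`, `total` giving total
#'   spectral intensity per run; defaults to the per-time sum of `areas`
#'   (appropriate when the supplied areas are the whole run).
#' @param min_length,max_length,missed_cleavages Digestion parameters for the
#'   peptide count.
#' @return Tibble `uniprot`, `time`, `abundance`; abundances within each time
#'   point sum to 1. Proteins with zero quantifiable peptides are dropped
#'   with a warning.
#' @export
xic_protein_abundance <- function(areas, peptide_map, proteins,
                                  run_totals = NULL,
                                  min_length = 6, max_length = 30,
                                  missed_cleavages = 0) {
  check_columns(areas, c("peptide", "time", "area"), "areas")
  check_columns(peptide_map, c("peptide", "uniprot"), "peptide map")
  if (any(areas$area < 0)) abort("areas must be non-negative")
  dup <- dplyr::count(dplyr::distinct(peptide_map, .data$peptide, .data$uniprot),
                      .data$peptide)
  if (any(dup$n > 1)) {
    abort("each peptide must map to exactly one protein")
  }

  if ("n_quant_peptides" %in% names(proteins)) {
    counts <- dplyr::select(tibble::as_tibble(proteins), "uniprot",
                            "n_quant_peptides")
  } else {
    check_columns(proteins, c("uniprot", "sequence"), "proteins")
    counts <- dplyr::mutate(
      dplyr::select(tibble::as_tibble(proteins), "uniprot", "sequence"),
      n_quant_peptides = count_quantifiable_peptides(
        .data$sequence, min_length, max_length, missed_cleavages),
      sequence = NULL
    )
  }
  zero <- counts$uniprot[counts$n_quant_peptides == 0]
  if (length(zero) > 0) {
    warn(paste0("protein(s) with zero quantifiable peptides excluded: ",
                paste(zero, collapse = ", ")))
    counts <- counts[counts$n_quant_peptides > 0, ]
  }

  if (is.null(run_totals)) {
    run_totals <- dplyr::summarise(dplyr::group_by(areas, .data$time),
                                   total = sum(.data$area), .groups = "drop")
  }
  check_columns(run_totals, c("time", "total"), "run totals")
  if (any(run_totals$total <= 0)) abort("total spectral intensity must be positive")

  rel <- dplyr::left_join(tibble::as_tibble(areas), run_totals, by = "time")
  rel <- dplyr::mutate(rel, rel_area = .data$area / .data$total)
  rel <- dplyr::inner_join(rel, dplyr::distinct(peptide_map), by = "peptide")
  prot <- dplyr::summarise(
    dplyr::group_by(rel, .data$uniprot, .data$time),
    value = sum(.data$rel_area), .groups = "drop"
  )
  prot <- dplyr::inner_join(prot, counts, by = "uniprot")
  prot <- dplyr::mutate(prot, value = .data$value / .data$n_quant_peptides)
  out <- dplyr::mutate(
    dplyr::group_by(prot, .data$time),
    abundance = .data$value / sum(.data$value)
  )
  dplyr::select(dplyr::ungroup(out), "uniprot", "time", "abundance")
}

#' Normalized spectral abundance factor (NSAF)
#'
#' Length-normalized spectral counting: `NSAF_i = (SpC_i / L_i) / sum_j
#' (SpC_j / L_j)`, so within-sample values sum to 1.
#'
#' @param counts Data frame with columns `uniprot`, `spc` (spectral counts)
#'   and `length` (protein length in residues), optionally grouped by a
#'   `sample` column.
#' @return Tibble with an added `nsaf` column.
#' @examples
#' nsaf(tibble::tibble(uniprot = c("A", "B"), spc = c(4, 4), length = c(100, 200)))
#' @export
nsaf <- function(counts) {
  check_columns(counts, c("uniprot", "spc", "length"), "counts")
  if (any(counts$length <= 0)) abort("protein lengths must be positive")
  if (any(counts$spc < 0)) abort("spectral counts must be non-negative")
  keys <- intersect("sample", names(counts))
  grouped <- dplyr::group_by(tibble::as_tibble(counts),
                             dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::mutate(grouped, saf = .data$spc / .data$length,
                       total = sum(.data$saf))
  if (any(out$total == 0)) abort("all spectral counts are zero")
  out <- dplyr::mutate(out, nsaf = .data$saf / .data$total,
                       saf = NULL, total = NULL)
  dplyr::ungroup(out)
}
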
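#' Elemental composition of a peptide
#'
#' Sums the residue compositions of a peptide sequence, adds one terminal
#' water, and applies the elemental deltas of any modifications. The result
#' fixes the natural (pre-labeling) isotope envelope of the peptide and hence
#' the unlabeled 0th-isotopomer fraction `a`.
#'
#' @param sequence Peptide sequence using the twenty canonical one-letter
#'   codes.
#' @param mods Character vector of modification names (may be empty); each
#'   must exist in the modification table. Repeats apply the delta repeatedly.
#' @param residue_table,modification_table Replacement reference tables (see
#'   [load_residue_table()], [load_modifications()]); `NULL` uses the shipped
#'   tables.
#'
#' @return A named numeric vector of element counts (C, H, N, O, S, ...).
#' @examples
#' peptide_composition("PEPTIDE")
#' peptide_composition("ACDK", mods = "carbamidomethyl")
#' @export
peptide_composition <- function(sequence, mods = character(),
                                residue_table = NULL,
                                modification_table = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  residue_table <- residue_table %||% load_residue_table()
  letters <- strsplit(sequence, "")[[1]]
  if (length(letters) == 0) abort("empty peptide sequence")
  unknown <- which(!letters %in% residue_table$residue)
  if (length(unknown) > 0) {
    abort(sprintf("unknown residue '%s' at position %d in '%s'",
                  letters[unknown[1]], unknown[1], sequence))
  }
  elements <- setdiff(names(residue_table), "residue")
  mat <- as.matrix(residue_table[, elements])
  rownames(mat) <- residue_table$residue
  comp <- colSums(mat[letters, , drop = FALSE])
  # terminal water
  comp["H"] <- comp["H"] + 2
  comp["O"] <- comp["O"] + 1

  mods <- mods[!is.na(mods) & nzchar(mods)]
  if (length(mods) > 0) {
    modification_table <- modification_table %||% load_modifications()
    missing <- setdiff(unique(mods), modification_table$name)
    if (length(missing) > 0) {
      abort(paste0("unknown modification(s): ", paste(missing, collapse = ", ")))
    }
    mod_elements <- setdiff(names(modification_table), "name")
    for (m in mods) {
      delta <- unlist(modification_table[modification_table$name == m, mod_elements])
      for (el in mod_elements) {
        comp[el] <- (if (el %in% names(comp) && !is.na(comp[el])) comp[el] else 0) + delta[[el]]
      }
    }
  }
  comp <- comp[!is.na(comp) & comp != 0]
  if (any(comp < 0)) abort("modification drives an element count negative")
  comp
}

# distribution of n i.i.d. atoms of one element, by integer mass offset;
# repeated-squaring convolution, optionally truncated to max_len offsets
conv_pow <- function(dist, n, max_len = Inf) {
  out <- 1
  base <- dist
  while (n > 0) {
    if (n %% 2 == 1) out <- conv_trunc(out, base, max_len)
    n <- n %/% 2
    if (n > 0) base <- conv_trunc(base, base, max_len)
  }
  out
}

conv_trunc <- function(x, y, max_len = Inf) {
  lx <- length(x); ly <- length(y)
  lo <- min(lx + ly - 1, max_len)
  out <- numeric(lo)
  for (i in seq_len(lx)) {
    jmax <- min(ly, lo - i + 1)
    if (jmax < 1) break
    idx <- i:(i + jmax - 1)
    out[idx] <- out[idx] + x[i] * y[seq_len(jmax)]
  }
  out
}

#' Natural-abundance isotope envelope of an elemental composition
#'
#' Computes the mass-isotopomer distribution of a molecule as the discrete
#' convolution (by integer nominal-mass offset) of the per-atom isotope
#' distributions of its elements. Isotopologues sharing a nominal offset are
#' aggregated; the pipeline only consumes the 0th peak.
#'
#' @param composition Named numeric vector of element counts, as returned by
#'   [peptide_composition()].
#' @param isotope_table Replacement isotope-abundance table
#'   (see [load_isotope_table()]); `NULL` uses the shipped IUPAC values.
#' @param n_peaks Number of isotopomer peaks to retain (default 5, covering
#'   >99.9% of the envelope mass for tryptic-size peptides); `NULL` returns
#'   the full untruncated envelope, which sums to 1.
#'
#' @return Numeric vector of fractional abundances for mass offsets
#'   `0, 1, ..., n_peaks - 1`.
#' @examples
#' env <- isotope_envelope(peptide_composition("PEPTIDE"))
#' sum(isotope_envelope(peptide_composition("PEPTIDE"), n_peaks = NULL))
#' @export
isotope_envelope <- function(composition, isotope_table = NULL, n_peaks = 5) {
  if (!is.null(n_peaks) && (!is.numeric(n_peaks) || n_peaks < 1)) {
    abort("n_peaks must be a positive integer or NULL")
  }
  isotope_table <- isotope_table %||% load_isotope_table()
  max_len <- if (is.null(n_peaks)) Inf else as.integer(n_peaks)
  env <- 1
  for (el in names(composition)) {
    n <- composition[[el]]
    if (n == 0) next
    rows <- isotope_table[isotope_table$element == el, ]
    if (nrow(rows) == 0) {
      abort(paste0("element '", el, "' missing from the isotope table"))
    }
    dist <- numeric(max(rows$mass_offset) + 1)
    dist[rows$mass_offset + 1] <- rows$abundance
    env <- conv_trunc(env, conv_pow(dist, n, max_len), max_len)
  }
  if (!is.null(n_peaks) && length(env) < n_peaks) {
    env <- c(env, numeric(n_peaks - length(env)))
  }
  env
}

#' Unlabeled 0th-isotopomer fraction
#'
#' Reads off `a`, the fractional abundance of the monoisotopic (0th) peak of
#' a natural-abundance envelope. This is the pre-labeling baseline from which
#' deuterium incorporation depletes the 0th isotopomer.
#'
#' @param envelope Numeric envelope from [isotope_envelope()].
#' @return The fraction `a` (equal to the product over elements of the
#'   lightest-isotope abundance raised to the atom count).
#' @examples
#' natural_a0(isotope_envelope(peptide_composition("PEPTIDE")))
#' @export
natural_a0 <- function(envelope) {
  if (length(envelope) == 0) abort("empty envelope")
  envelope[[1]]
}

#' Monoisotopic mass and m/z of a peptide
#'
#' @inheritParams peptide_composition
#' @param z Charge state (positive integer) for `peptide_mz()`.
#' @return Mass in u; `peptide_mz()` the (protonated) mass-to-charge ratio.
#' @examples
#' peptide_mass("PEPTIDE")
#' peptide_mz("PEPTIDE", z = 2)
#' @export
peptide_mass <- function(sequence, mods = character(), residue_table = NULL,
                         modification_table = NULL) {
  comp <- peptide_composition(sequence, mods, residue_table, modification_table)
  unknown <- setdiff(names(comp), names(MONOISOTOPIC_MASS))
  if (length(unknown) > 0) {
    abort(paste0("no monoisotopic mass for element(s): ",
                 paste(unknown, collapse = ", ")))
  }
  sum(MONOISOTOPIC_MASS[names(comp)] * comp)
}

#' @rdname peptide_mass
#' @export
peptide_mz <- function(sequence, z, mods = character(), residue_table = NULL,
                       modification_table = NULL) {
  stopifnot(z >= 1)
  (peptide_mass(sequence, mods, residue_table, modification_table) +
     z * PROTON_MASS) / z
}
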
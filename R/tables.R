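#' Shipped reference tables
#'
#' The package ships four plain-text (tab-delimited) reference tables under
#' `inst/extdata`: natural isotope abundances per element, elemental
#' compositions of the twenty canonical residues, effective
#' deuterium-accessible labeling sites per residue, and elemental-composition
#' deltas for the six search modifications. Every loader accepts a `path`
#' argument so any table can be replaced by a user-supplied file with the
#' same columns.
#'
#' @param path Path to a replacement table; `NULL` uses the shipped file.
#'
#' @return A tibble. `load_isotope_table()`: columns `element`, `mass_offset`
#'   (integer nominal-mass offset from the lightest isotope), `abundance`.
#'   `load_residue_table()`: `residue` plus element-count columns.
#'   `load_labeling_sites()`: `residue`, `sites`. `load_modifications()`:
#'   `name` plus element-delta columns.
#'
#' @examples
#' load_isotope_table()
#' load_labeling_sites()
#' @name reference_tables
NULL

extdata_path <- function(file) {
  system.file("extdata", file, package = "isoturn", mustWork = TRUE)
}

read_config <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference_tables
#' @export
load_isotope_table <- function(path = NULL) {
  tbl <- read_config(path %||% extdata_path("isotope_abundances.tsv"))
  required <- c("element", "mass_offset", "abundance")
  if (!all(required %in% names(tbl))) {
    abort("isotope table must have columns element, mass_offset, abundance")
  }
  if (any(tbl$abundance < 0 | tbl$abundance > 1)) {
    abort("isotope abundances must lie in [0, 1]")
  }
  sums <- tapply(tbl$abundance, tbl$element, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-9]
  if (length(bad) > 0) {
    abort(paste0("isotope abundances do not sum to 1 for element(s): ",
                 paste(bad, collapse = ", ")))
  }
  dplyr::arrange(tbl, .data$element, .data$mass_offset)
}

#' @rdname reference_tables
#' @export
load_residue_table <- function(path = NULL) {
  tbl <- read_config(path %||% extdata_path("residue_composition.tsv"))
  if (!"residue" %in% names(tbl)) abort("residue table must have a 'residue' column")
  counts <- dplyr::select(tbl, -"residue")
  if (any(as.matrix(counts) < 0)) abort("residue element counts must be non-negative")
  tbl
}

#' @rdname reference_tables
#' @export
load_labeling_sites <- function(path = NULL) {
  tbl <- read_config(path %||% extdata_path("labeling_sites.tsv"))
  if (!all(c("residue", "sites") %in% names(tbl))) {
    abort("labeling-site table must have columns residue, sites")
  }
  if (any(tbl$sites < 0)) abort("labeling-site counts must be non-negative")
  tbl
}

#' @rdname reference_tables
#' @export
load_modifications <- function(path = NULL) {
  tbl <- read_config(path %||% extdata_path("modifications.tsv"))
  if (!"name" %in% names(tbl)) abort("modification table must have a 'name' column")
  tbl
}

# Monoisotopic masses of the lightest isotopes (u); used for peptide m/z only.
MONOISOTOPIC_MASS <- c(
  C = 12, H = 1.0078250319, N = 14.0030740052,
  O = 15.9949146221, S = 31.97207069, P = 30.97376151
)
PROTON_MASS <- 1.007276466
# nominal spacing between adjacent mass isotopomers (neutron mass, u)
NEUTRON_MASS <- 1.008664916
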
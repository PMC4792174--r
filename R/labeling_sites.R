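#' Count deuterium-accessible labeling sites
#'
#' Sums per-residue effective labeling-site counts over a peptide sequence to
#' give `N`, the number of hydrogen positions that equilibrate with body-water
#' deuterium during synthesis. The shipped per-residue values follow the
#' Commerford-lineage literature; supply `site_table` to override. `N` is
#' additive over concatenation and, by design, unchanged by modifications
#' (no modification-specific site counts are available).
#'
#' @param sequence Character vector of peptide sequences.
#' @param site_table Replacement table (see [load_labeling_sites()]); `NULL`
#'   uses the shipped values.
#' @return Numeric vector of site counts (possibly non-integer: the table
#'   holds effective, exchange-weighted values).
#' @examples
#' count_sites("PEPTIDE")
#' count_sites(c("AK", "GGR"))
#' @export
count_sites <- function(sequence, site_table = NULL) {
  site_table <- site_table %||% load_labeling_sites()
  sites <- setNames(site_table$sites, site_table$residue)
  vapply(sequence, function(s) {
    letters <- strsplit(s, "")[[1]]
    if (length(letters) == 0) return(0)
    missing <- setdiff(letters, names(sites))
    if (length(missing) > 0) {
      abort(paste0("residue(s) missing from the labeling-site table: ",
                   paste(missing, collapse = ", ")))
    }
    sum(sites[letters])
  }, numeric(1), USE.NAMES = FALSE)
}
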
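#' Read and write the pipeline's tab-delimited output formats
#'
#' Three documented formats, all tab-delimited with a single header row
#' (lines starting with `#` are comments, used to echo seeds):
#' * `hl.out` — one row per (sequence, charge)-unique peptide time series,
#'   exactly 14 columns in fixed order: `ID`, `UniProt`, `Peptide`, `DP`,
#'   `z`, `mi`, `SS`, `a`, `pss`, `kp`, `N`, `k`, `dk`, `R2`;
#' * `hl-data.out` — one row per isotope cluster per time point, 3 columns
#'   `ID`, `t`, `A_0`;
#' * `intensity.txt` — 8 columns, `UniProt` then one relative-intensity
#'   column per sampling day (0, 1, 3, 5, 7, 10, 14).
#'
#' Writers map from the package's tibbles (a `turnover_fits` table for
#' `hl.out`; a `series` table for `hl-data.out`; a long `uniprot`/`time`/
#' `abundance` table for `intensity.txt`) and `write_*` then `read_*` is the
#' identity on the stored columns. Readers reject files with a wrong column
#' count (naming the line) or non-numeric cells in numeric columns.
#'
#' @param fits,series,abundance Tibbles to write (see above).
#' @param path File path.
#' @param seed Optional integer echoed as a `# seed:` comment header.
#' @param days Day grid for `intensity.txt` columns.
#' @return Readers return tibbles; `read_hl_out()` maps the file columns back
#'   to the package's column names (`uniprot`, `peptide`, `p_ss`, `k_p`, ...).
#' @name pipeline_io
NULL

HL_OUT_COLUMNS <- c("ID", "UniProt", "Peptide", "DP", "z", "mi", "SS", "a",
                    "pss", "kp", "N", "k", "dk", "R2")

write_header <- function(path, fields, seed = NULL) {
  lines <- character()
  if (!is.null(seed)) lines <- c(lines, paste0("# seed: ", seed))
  c(lines, paste(fields, collapse = "\t"))
}

#' @rdname pipeline_io
#' @export
write_hl_out <- function(fits, path, seed = NULL) {
  check_columns(fits, c("ID", "uniprot", "peptide", "DP", "z", "mi", "SS",
                        "a", "p_ss", "k_p", "N", "k", "dk", "R2"), "fits")
  body <- tibble::tibble(
    ID = fits$ID, UniProt = fits$uniprot, Peptide = fits$peptide,
    DP = fits$DP, z = fits$z, mi = fits$mi, SS = fits$SS, a = fits$a,
    pss = fits$p_ss, kp = fits$k_p, N = fits$N, k = fits$k, dk = fits$dk,
    R2 = fits$R2
  )
  writeLines(c(write_header(path, HL_OUT_COLUMNS, seed),
               do.call(paste, c(lapply(body, format_cell), sep = "\t"))[seq_len(nrow(body))]),
             path)
  invisible(path)
}

format_cell <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "NA" else format(v, digits = 12, scientific = FALSE, trim = TRUE)
    }, character(1))
    out
  } else {
    as.character(x)
  }
}

read_delim_checked <- function(path, columns, numeric_cols, what) {
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) abort(paste0(what, ": empty file"))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  counts <- lengths(cells)
  header <- cells[[1]]
  if (length(header) != length(columns) || !all(header == columns)) {
    abort(sprintf("%s: expected %d columns (%s), found %d (%s)",
                  what, length(columns), paste(columns, collapse = ", "),
                  length(header), paste(header, collapse = ", ")))
  }
  bad <- which(counts != length(columns))
  bad <- bad[bad != 1]
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d has %d columns, expected %d",
                  what, line_no[bad[1]], counts[bad[1]], length(columns)))
  }
  if (length(cells) == 1) {
    out <- lapply(columns, function(cn) {
      if (cn %in% numeric_cols) numeric() else character()
    })
    names(out) <- columns
    return(tibble::as_tibble(out))
  }
  mat <- do.call(rbind, cells[-1])
  out <- tibble::as_tibble(setNames(as.data.frame(mat, stringsAsFactors = FALSE),
                                    columns))
  for (cn in numeric_cols) {
    val <- suppressWarnings(as.numeric(out[[cn]]))
    bad_cell <- which(is.na(val) & !(out[[cn]] %in% c("NA", "NaN")))
    if (length(bad_cell) > 0) {
      abort(sprintf("%s: non-numeric value '%s' in column %s, line %d",
                    what, out[[cn]][bad_cell[1]], cn, line_no[bad_cell[1] + 1]))
    }
    out[[cn]] <- val
  }
  out
}

#' @rdname pipeline_io
#' @export
read_hl_out <- function(path) {
  numeric_cols <- setdiff(HL_OUT_COLUMNS, c("UniProt", "Peptide"))
  out <- read_delim_checked(path, HL_OUT_COLUMNS, numeric_cols, "hl.out")
  tibble::tibble(
    ID = out$ID, uniprot = out$UniProt, peptide = out$Peptide, DP = out$DP,
    z = out$z, mi = out$mi, SS = out$SS, a = out$a, p_ss = out$pss,
    k_p = out$kp, N = out$N, k = out$k, dk = out$dk, R2 = out$R2
  )
}

#' @rdname pipeline_io
#' @export
write_hl_data <- function(series, path, seed = NULL) {
  check_columns(series, c("ID", "t", "A0"), "series")
  body <- paste(format_cell(series$ID), format_cell(series$t),
                format_cell(series$A0), sep = "\t")
  writeLines(c(write_header(path, c("ID", "t", "A_0"), seed),
               body[seq_len(nrow(series))]), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_hl_data <- function(path) {
  out <- read_delim_checked(path, c("ID", "t", "A_0"),
                            c("ID", "t", "A_0"), "hl-data.out")
  tibble::tibble(ID = out$ID, t = out$t, A0 = out$A_0)
}

#' @rdname pipeline_io
#' @export
write_intensity <- function(abundance, path, days = c(0, 1, 3, 5, 7, 10, 14),
                            seed = NULL) {
  check_columns(abundance, c("uniprot", "time", "abundance"), "abundance")
  wide <- tidyr::pivot_wider(abundance, id_cols = "uniprot",
                             names_from = "time", values_from = "abundance")
  missing <- setdiff(as.character(days), names(wide))
  for (m in missing) wide[[m]] <- NA_real_
  wide <- wide[, c("uniprot", as.character(days))]
  header <- c("UniProt", paste0("day", days))
  body <- do.call(paste, c(lapply(wide, format_cell), sep = "\t"))
  writeLines(c(write_header(path, header, seed), body[seq_len(nrow(wide))]),
             path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_intensity <- function(path, days = c(0, 1, 3, 5, 7, 10, 14)) {
  cols <- c("UniProt", paste0("day", days))
  out <- read_delim_checked(path, cols, setdiff(cols, "UniProt"),
                            "intensity.txt")
  long <- tidyr::pivot_longer(out, -"UniProt", names_to = "time",
                              values_to = "abundance")
  tibble::tibble(
    uniprot = long$UniProt,
    time = as.numeric(sub("^day", "", long$time)),
    abundance = long$abundance
  )
}

#' Read and write protein FASTA
#'
#' Thin wrappers around Biostrings for the protein sequence input of the
#' in-silico digestion and the synthetic generator's FASTA export.
#'
#' @param proteins Tibble with columns `uniprot`, `sequence`.
#' @param path File path.
#' @return `read_fasta()` returns a `uniprot`/`sequence` tibble.
#' @export
write_fasta <- function(proteins, path) {
  check_columns(proteins, c("uniprot", "sequence"), "proteins")
  set <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$uniprot))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  tibble::tibble(uniprot = names(set), sequence = unname(as.character(set)))
}
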
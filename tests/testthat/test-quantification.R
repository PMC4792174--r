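test_that("tryptic digestion cleaves after K/R but not before P", {
  expect_equal(digest_sequence("AKRPGKT"), c("AK", "RPGK", "T"))
  expect_equal(digest_sequence("MAGICSEQENCE"), "MAGICSEQENCE")
  expect_equal(digest_sequence("AKAKA", missed_cleavages = 1),
               c("AK", "AK", "A", "AKAK", "AKA"))
})

test_that("fully cleaved digests concatenate to the parent sequence", {
  withr::with_seed(61, {
    aa <- strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]]
    for (i in 1:100) {
      s <- paste(sample(aa, sample(10:80, 1), replace = TRUE), collapse = "")
      expect_equal(paste(digest_sequence(s), collapse = ""), s)
    }
  })
})

test_that("quantifiable-peptide counting applies inclusive 6-30 length bounds", {
  expect_equal(count_quantifiable_peptides("MKAAAAAAK"), 1L)  # {"MK","AAAAAAK"}
  expect_equal(count_quantifiable_peptides("MAG"), 0L)
  expect_equal(count_quantifiable_peptides(strrep("A", 6)), 1L)   # exactly 6
  expect_equal(count_quantifiable_peptides(strrep("A", 30)), 1L)  # exactly 30
  expect_equal(count_quantifiable_peptides(strrep("A", 31)), 0L)
})

test_that("NSAF follows the length-normalized closed form", {
  one <- nsaf(tibble::tibble(uniprot = "A", spc = 10, length = 100))
  expect_equal(one$nsaf, 1)
  two <- nsaf(tibble::tibble(uniprot = c("A", "B"), spc = c(5, 5),
                             length = c(100, 200)))
  expect_equal(two$nsaf, c(2 / 3, 1 / 3))
  expect_error(nsaf(tibble::tibble(uniprot = "A", spc = 0, length = 10)),
               "zero")
  # direct-formula recomputation on a 50-protein random instance
  withr::with_seed(62, {
    counts <- tibble::tibble(uniprot = sprintf("P%02d", 1:50),
                             spc = rpois(50, 20),
                             length = sample(80:900, 50))
    got <- nsaf(counts)$nsaf
    saf <- counts$spc / counts$length
    expect_equal(got, saf / sum(saf), tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-9)
    # scale invariance in the raw counts
    expect_equal(nsaf(dplyr::mutate(counts, spc = spc * 7))$nsaf, got,
                 tolerance = 1e-12)
  })
})

make_xic_instance <- function(n_prot = 5, n_pep = 12, times = c(0, 1, 3)) {
  peptide_map <- tibble::tibble(
    peptide = sprintf("PEP%02d", 1:n_pep),
    uniprot = sample(sprintf("PR%02d", 1:n_prot), n_pep, replace = TRUE)
  )
  areas <- tidyr::expand_grid(peptide = peptide_map$peptide, time = times)
  areas$area <- runif(nrow(areas), 1e3, 1e6)
  counts <- tibble::tibble(uniprot = sprintf("PR%02d", 1:n_prot),
                           n_quant_peptides = sample(5:40, n_prot))
  list(areas = areas, map = peptide_map, counts = counts)
}

test_that("XIC abundance normalization has the stated closed forms", {
  # one protein: self-normalization to 1 at every time point
  inst <- list(
    areas = tibble::tibble(peptide = "PEP", time = c(0, 1), area = c(10, 99)),
    map = tibble::tibble(peptide = "PEP", uniprot = "PR1"),
    counts = tibble::tibble(uniprot = "PR1", n_quant_peptides = 7)
  )
  ab <- xic_protein_abundance(inst$areas, inst$map, inst$counts)
  expect_equal(ab$abundance, c(1, 1))

  # two proteins with equal stage-2 values split 0.5 / 0.5
  areas <- tibble::tibble(peptide = c("A1", "B1"), time = 0, area = c(10, 20))
  map <- tibble::tibble(peptide = c("A1", "B1"), uniprot = c("PA", "PB"))
  counts <- tibble::tibble(uniprot = c("PA", "PB"), n_quant_peptides = c(1, 2))
  ab <- xic_protein_abundance(areas, map, counts)
  expect_equal(sort(ab$abundance), c(0.5, 0.5))
})

test_that("XIC three-stage normalization matches an independent recomputation", {
  withr::with_seed(63, {
    for (rep in 1:5) {
      inst <- make_xic_instance()
      got <- xic_protein_abundance(inst$areas, inst$map, inst$counts)
      # spreadsheet-style recomputation with explicit loops
      for (tp in unique(inst$areas$time)) {
        at <- inst$areas[inst$areas$time == tp, ]
        total <- sum(at$area)
        vals <- c()
        for (pr in inst$counts$uniprot) {
          peps <- inst$map$peptide[inst$map$uniprot == pr]
          stage2 <- sum(at$area[at$peptide %in% peps]) / total /
            inst$counts$n_quant_peptides[inst$counts$uniprot == pr]
          vals[pr] <- stage2
        }
        vals <- vals[vals > 0]
        vals <- vals / sum(vals)
        for (pr in names(vals)) {
          expect_equal(
            got$abundance[got$uniprot == pr & got$time == tp], unname(vals[pr]),
            tolerance = 1e-12)
        }
      }
      # within-sample sums and scale invariance
      sums <- tapply(got$abundance, got$time, sum)
      expect_true(all(abs(sums - 1) < 1e-9))
      scaled <- xic_protein_abundance(
        dplyr::mutate(inst$areas, area = area * 3.7), inst$map, inst$counts)
      expect_equal(scaled$abundance, got$abundance, tolerance = 1e-12)
    }
  })
})

test_that("XIC abundance rejects ambiguous maps and empty proteins", {
  areas <- tibble::tibble(peptide = "A1", time = 0, area = 10)
  expect_error(
    xic_protein_abundance(
      areas,
      tibble::tibble(peptide = c("A1", "A1"), uniprot = c("PA", "PB")),
      tibble::tibble(uniprot = c("PA", "PB"), n_quant_peptides = c(1, 1))),
    "exactly one")
  expect_warning(
    xic_protein_abundance(
      areas,
      tibble::tibble(peptide = "A1", uniprot = "PA"),
      tibble::tibble(uniprot = c("PA", "PZ"), n_quant_peptides = c(1, 0))),
    "zero quantifiable")
})

test_that("XIC- and NSAF-based abundances agree in rank on shared ground truth", {
  withr::with_seed(64, {
    n <- 40
    truth <- exp(rnorm(n, 0, 1.5))
    lengths <- sample(100:800, n)
    counts <- count_quantifiable_peptides(
      vapply(lengths, function(L)
        paste(sample(strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]], L,
                     replace = TRUE, prob = c(8, 6, 4, 5, 1, 7, 4, 7, 2, 6, 10,
                                              6, 2, 4, 5, 7, 5, 1, 3, 7)),
              collapse = ""), character(1)))
    counts <- pmax(counts, 1)
    # spectral counts scale with abundance x length; areas with abundance x
    # peptide yield: both normalizations should recover the same ranking
    spc <- rpois(n, truth * lengths / 20)
    areas <- tibble::tibble(peptide = sprintf("pep%02d", 1:n), time = 0,
                            area = truth * counts * exp(rnorm(n, 0, 0.3)))
    map <- tibble::tibble(peptide = areas$peptide,
                          uniprot = sprintf("pr%02d", 1:n))
    xic <- xic_protein_abundance(
      areas, map, tibble::tibble(uniprot = map$uniprot,
                                 n_quant_peptides = counts))
    ns <- nsaf(tibble::tibble(uniprot = map$uniprot, spc = pmax(spc, 1),
                              length = lengths))
    merged <- dplyr::inner_join(xic, ns, by = "uniprot")
    rho <- cor(merged$abundance, merged$nsaf, method = "spearman")
    expect_gt(rho, 0.5)
  })
})
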
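toy_fits <- tibble::tibble(
  DP = c(3, 4, 4, 4, 7, 5),
  R2 = c(0.99, 0.85, 0.5, 0.5, 0.8, 0.79),
  se = c(0.01, 0.2, 0.04, 0.2, 0.05, 0.051)
)

test_that("the OR-filter accepts by either quality branch after the DP gate", {
  flt <- apply_stringency_filter(toy_fits)
  expect_equal(flt$accepted, c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(flt$reject_reason[1], "too_few_timepoints")
  expect_equal(flt$reject_reason[4], "poor_fit")
  expect_true(all(is.na(flt$reject_reason[flt$accepted])))
  # R2 branch alone
  expect_true(apply_stringency_filter(
    tibble::tibble(DP = 7, R2 = 0.95, se = 0.2))$accepted)
  # se branch rescues slow turnover
  expect_true(apply_stringency_filter(
    tibble::tibble(DP = 7, R2 = 0.3, se = 0.03))$accepted)
})

test_that("the filter is a pure predicate: permutations permute the output", {
  withr::with_seed(51, {
    perm <- sample(nrow(toy_fits))
    a <- apply_stringency_filter(toy_fits)
    b <- apply_stringency_filter(toy_fits[perm, ])
    expect_equal(b$accepted, a$accepted[perm])
  })
})

test_that("protein roll-up reports median and unscaled MAD", {
  one <- rollup_proteins(tibble::tibble(uniprot = "P1", k = c(1, 2, 3)))
  expect_equal(one$k_median, 2)
  expect_equal(one$k_mad, 1)
  single <- rollup_proteins(tibble::tibble(uniprot = "P2", k = 0.5))
  expect_equal(single$k_median, 0.5)
  expect_equal(single$k_mad, 0)
  expect_equal(single$half_life, log(2) / 0.5)
})

test_that("roll-up matches a sort-based oracle on random instances", {
  withr::with_seed(52, {
    for (i in 1:1000) {
      k <- runif(sample(1:12, 1), 0.01, 1)
      roll <- rollup_proteins(tibble::tibble(uniprot = "P", k = k))
      expect_identical(roll$k_median, sort_median(k))
      expect_identical(roll$k_mad, sort_mad(k))
    }
  })
})

test_that("intra-protein variability matches the two-loop reference", {
  expect_equal(intra_protein_variability(
    rollup_proteins(tibble::tibble(uniprot = rep("P", 3), k = c(1, 1, 2)))), 0)
  expect_error(intra_protein_variability(
    rollup_proteins(tibble::tibble(uniprot = c("A", "B"), k = c(1, 2)))),
    "undefined")
  withr::with_seed(53, {
    for (i in 1:20) {
      proteins <- sample(letters[1:6], 40, replace = TRUE)
      ks <- runif(40, 0.02, 0.5)
      roll <- rollup_proteins(tibble::tibble(uniprot = proteins, k = ks))
      expect_equal(intra_protein_variability(roll),
                   two_loop_variability(proteins, ks))
    }
  })
})

test_that("roll-up respects sample grouping and the accepted flag", {
  df <- tibble::tibble(
    sample = rep(c("s1", "s2"), each = 3),
    uniprot = "P1",
    k = c(1, 2, 3, 4, 5, 6),
    accepted = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  roll <- rollup_proteins(df)
  expect_equal(nrow(roll), 2)
  expect_equal(roll$k_median[roll$sample == "s1"], 2)
  expect_equal(roll$k_median[roll$sample == "s2"], 4.5)
})

test_that("filter sweep is consistent with single application and monotone", {
  withr::with_seed(54, {
    n <- 300
    fits <- tibble::tibble(
      uniprot = sample(sprintf("P%02d", 1:30), n, replace = TRUE),
      k = runif(n, 0.02, 0.5),
      DP = sample(3:7, n, replace = TRUE),
      R2 = runif(n, -0.2, 1),
      se = runif(n, 0.005, 0.2)
    )
    sweep <- filter_sweep(fits, r2_grid = seq(0, 1, 0.25),
                          se_grid = c(0.01, 0.05, 0.1, 0.2))

    # single grid point equals direct filtering
    direct <- apply_stringency_filter(fits, r2_min = 0.5, se_max = 0.05)
    row <- sweep[sweep$r2_min == 0.5 & sweep$se_max == 0.05, ]
    expect_equal(row$n_accepted, sum(direct$accepted))
    expect_equal(row$variability_pct,
                 intra_protein_variability(rollup_proteins(direct)))

    # acceptance counts: non-increasing in r2_min, non-decreasing in se_max
    for (s in unique(sweep$se_max)) {
      cnt <- sweep$n_accepted[sweep$se_max == s][order(unique(sweep$r2_min))]
      expect_true(all(diff(cnt) <= 0))
    }
    for (r in unique(sweep$r2_min)) {
      cnt <- sweep$n_accepted[sweep$r2_min == r][order(unique(sweep$se_max))]
      expect_true(all(diff(cnt) >= 0))
    }
  })
})

test_that("an unattainable cutoff yields an empty acceptance with missing variability", {
  sweep <- filter_sweep(
    tibble::tibble(uniprot = "P", k = 0.1, DP = 7, R2 = 0.9, se = 1),
    r2_grid = 1.01, se_grid = 1e-9
  )
  expect_equal(sweep$n_accepted, 0)
  expect_true(is.na(sweep$variability_pct))
  expect_error(filter_sweep(toy_fits, numeric(), 0.05), "nonempty")
  expect_error(filter_sweep(toy_fits, c(0.5, 0.1), 0.05), "sorted")
})
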
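# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: envelopes by atom-at-a-time polynomial expansion,
# medians by explicit sorting, aggregation by explicit double loops.

# generating-function expansion of the isotope envelope, one atom at a time
brute_force_envelope <- function(composition, isotope_table) {
  poly <- 1
  for (el in names(composition)) {
    rows <- isotope_table[isotope_table$element == el, ]
    atom <- numeric(max(rows$mass_offset) + 1)
    atom[rows$mass_offset + 1] <- rows$abundance
    for (rep in seq_len(composition[[el]])) {
      new <- numeric(length(poly) + length(atom) - 1)
      for (i in seq_along(poly)) {
        for (j in seq_along(atom)) {
          new[i + j - 1] <- new[i + j - 1] + poly[i] * atom[j]
        }
      }
      poly <- new
    }
  }
  poly
}

# sort-based median: mean of the two central order statistics when even
sort_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

sort_mad <- function(x) sort_median(abs(x - sort_median(x)))

# two-loop reference for the intra-protein variability statistic
two_loop_variability <- function(proteins, ks) {
  stats <- c()
  for (p in unique(proteins)) {
    k <- ks[proteins == p]
    if (length(k) < 2) next
    stats <- c(stats, sort_mad(k) / sort_median(k))
  }
  100 * sort_median(stats)
}

# one synthetic peptide time series on the kinetic model plus noise
make_series <- function(k, a, N, p_ss, k_p, days = c(0, 1, 3, 5, 7, 10, 14),
                        noise_sd = 0) {
  A0 <- model_a0(k, days, a, N, p_ss, k_p)
  if (noise_sd > 0) A0 <- pmin(pmax(A0 + rnorm(length(days), sd = noise_sd), 0), 1)
  tibble::tibble(t = days, A0 = A0)
}

# batch of noisy series with log-normal-style true rates; returns truth + fits
fit_series_batch <- function(n, noise_sd = 0.01, seed = 1,
                             days = c(0, 1, 3, 5, 7, 10, 14),
                             p_ss = 0.045, k_p = 2) {
  withr::with_seed(seed, {
    k_true <- generate_rates(n)
    a <- runif(n, 0.35, 0.65)
    N <- round(runif(n, 10, 30))
    fits <- purrr::map(seq_len(n), function(i) {
      s <- make_series(k_true[i], a[i], N[i], p_ss, k_p, days, noise_sd)
      fit_k(s$t, s$A0, a[i], N[i], p_ss, k_p)
    })
    tibble::tibble(
      k_true = k_true, a = a, N = N,
      k = vapply(fits, `[[`, numeric(1), "k"),
      k_nm = vapply(fits, `[[`, numeric(1), "k_nm"),
      k_qn = vapply(fits, `[[`, numeric(1), "k_qn"),
      R2 = vapply(fits, `[[`, numeric(1), "R2"),
      se = vapply(fits, `[[`, numeric(1), "se"),
      DP = vapply(fits, `[[`, numeric(1), "DP"),
      converged = vapply(fits, `[[`, logical(1), "converged")
    )
  })
}
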
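pars <- list(a = 0.5, N = 20, p_ss = 0.045, k_p = 2)

test_that("the precursor fraction has the right limits and log-domain value", {
  expect_equal(precursor_a0(c(0, 3, 14), a = 0.5, N = 10, p_ss = 0, k_p = 2),
               rep(0.5, 3))
  expect_equal(precursor_a0(0, a = 0.5, N = 10, p_ss = 0.045, k_p = 2), 0.5)
  # direct evaluation cross-checked in the log domain
  p3 <- 0.045 * (1 - exp(-2 * 3))
  expect_equal(precursor_a0(3, a = 0.5, N = 10, p_ss = 0.045, k_p = 2),
               exp(log(0.5) + 10 * log1p(-p3)), tolerance = 1e-14)
  # decreasing toward the plateau
  tt <- seq(0, 30, by = 0.5)
  v <- precursor_a0(tt, a = 0.5, N = 10, p_ss = 0.045, k_p = 2)
  expect_true(all(diff(v) <= 0))
  expect_equal(v[length(v)], 0.5 * (1 - 0.045)^10, tolerance = 1e-8)
})

test_that("the analytic solution honors initial condition and stationary point", {
  for (k in c(0.01, 0.094, 0.5, 3)) {
    expect_equal(model_a0(k, 0, pars$a, pars$N, pars$p_ss, pars$k_p), pars$a,
                 tolerance = 1e-12)
    expect_equal(model_a0(k, 1e4, pars$a, pars$N, pars$p_ss, pars$k_p),
                 pars$a * (1 - pars$p_ss)^pars$N, tolerance = 1e-10)
  }
  # no labeling sites: constant at a
  expect_equal(model_a0(0.1, c(0, 5, 10), pars$a, 0, pars$p_ss, pars$k_p),
               rep(pars$a, 3))
  # no enrichment: constant at a
  expect_equal(model_a0(0.1, c(0, 5, 10), pars$a, pars$N, 0, pars$k_p),
               rep(pars$a, 3))
})

test_that("analytic and numerical solutions of the kinetic model agree", {
  tt <- c(0.5, 1, 3, 7, 14)
  withr::with_seed(41, {
    for (i in 1:30) {
      k <- runif(1, 0.01, 5)
      N <- sample(0:40, 1)
      a <- runif(1, 0.2, 0.9)
      p_ss <- runif(1, 0.01, 0.2)
      k_p <- runif(1, 0.2, 5)
      expect_equal(model_a0(k, tt, a, N, p_ss, k_p),
                   ode_a0(k, tt, a, N, p_ss, k_p), tolerance = 1e-8)
    }
  })
  # degenerate denominator k = i * k_p takes the limiting term
  expect_equal(model_a0(2, tt, pars$a, pars$N, pars$p_ss, 2),
               ode_a0(2, tt, pars$a, pars$N, pars$p_ss, 2), tolerance = 1e-8)
  expect_equal(model_a0(4, tt, pars$a, pars$N, pars$p_ss, 2),
               ode_a0(4, tt, pars$a, pars$N, pars$p_ss, 2), tolerance = 1e-8)
})

test_that("instant enrichment reduces the model to a simple exponential", {
  tt <- c(0, 1, 3, 5, 7, 10, 14)
  a0_max <- pars$a * (1 - pars$p_ss)^pars$N
  simple <- a0_max + (pars$a - a0_max) * exp(-0.2 * tt)
  expect_equal(ode_a0(0.2, tt, pars$a, pars$N, pars$p_ss, k_p = 1e5),
               simple, tolerance = 1e-6)
  # the oracle supports real-valued N
  expect_equal(ode_a0(0.2, 5, pars$a, 20.5, pars$p_ss, 2),
               ode_a0(0.2, 5, pars$a, 20.5, pars$p_ss, 2))
})

test_that("model_a0 is monotone non-increasing in time", {
  tt <- seq(0, 30, length.out = 200)
  withr::with_seed(42, {
    for (i in 1:20) {
      v <- model_a0(runif(1, 0.01, 3), tt, runif(1, 0.2, 0.9), sample(1:40, 1),
                    runif(1, 0.01, 0.2), runif(1, 0.2, 5))
      expect_true(all(diff(v) <= 1e-12))
    }
  })
})

test_that("rounding non-integer N in the analytic path stays close to the exact ODE", {
  tt <- c(1, 3, 5, 7, 10, 14)
  for (N in c(15.3, 20.5, 27.8)) {
    analytic <- model_a0(0.1, tt, pars$a, N, pars$p_ss, pars$k_p)
    exact <- ode_a0(0.1, tt, pars$a, N, pars$p_ss, pars$k_p)
    # documented divergence bound: < 2% of the A0 decay range for |dN| <= 0.5
    range_a0 <- pars$a - pars$a * (1 - pars$p_ss)^N
    expect_lt(max(abs(analytic - exact)), 0.02 * range_a0)
  }
})

test_that("noiseless series are recovered exactly by the fitter", {
  tt <- c(0, 1, 3, 5, 7, 10, 14)
  y <- model_a0(0.1, tt, pars$a, pars$N, pars$p_ss, pars$k_p)
  fit <- fit_k(tt, y, pars$a, pars$N, pars$p_ss, pars$k_p)
  expect_equal(fit$k, 0.1, tolerance = 1e-6)
  expect_equal(fit$R2, 1, tolerance = 1e-9)
  expect_lt(fit$SS, 1e-12)
  expect_true(fit$converged)
  expect_equal(fit$DP, 7)
})

test_that("flat degenerate series are flagged instead of fitted", {
  tt <- c(0, 1, 3, 5, 7, 10, 14)
  flat <- fit_k(tt, rep(pars$a, 7), pars$a, pars$N, pars$p_ss, pars$k_p)
  expect_false(flat$converged)
  expect_true(flat$pinned)
  expect_lt(flat$k, 2e-4)
  # flat but noisy: R2 cannot exceed 0
  withr::with_seed(43, {
    noisy <- fit_k(tt, pars$a + rnorm(7, sd = 1e-3), pars$a, pars$N,
                   pars$p_ss, pars$k_p)
    expect_lte(noisy$R2, 0 + 1e-9)
  })
})

test_that("the fitted k is a local (probe-audited) minimizer of SS", {
  tt <- c(0, 1, 3, 5, 7, 10, 14)
  withr::with_seed(44, {
    y <- model_a0(0.25, tt, pars$a, pars$N, pars$p_ss, pars$k_p) +
      rnorm(7, sd = 0.01)
    fit <- fit_k(tt, y, pars$a, pars$N, pars$p_ss, pars$k_p)
    ss <- function(k) sum((y - model_a0(k, tt, pars$a, pars$N, pars$p_ss,
                                        pars$k_p))^2)
    probes <- exp(runif(100, log(1e-4), log(20)))
    expect_true(all(ss(fit$k) <= sapply(probes, ss) + 1e-12))
  })
})

test_that("half-life inverts the rate constant", {
  expect_equal(half_life(log(2)), 1.0)
  expect_equal(round(half_life(0.30), 1), 2.3)
  expect_equal(half_life(0.094), log(2) / 0.094)
  expect_error(half_life(0), "positive")
  expect_error(half_life(-1), "positive")
})

test_that("fractional synthesis rescales decay onto a common 0-1 curve", {
  a <- 0.6; N <- 18
  plateau <- a * (1 - pars$p_ss)^N
  s <- tibble::tibble(t = c(0, 99), A0 = c(a, plateau))
  fs <- fractional_synthesis(s, a, N, pars$p_ss, pars$k_p)
  expect_equal(fs$fs, c(0, 1))
  expect_error(fractional_synthesis(s, a, 0, pars$p_ss, pars$k_p), "undefined")
  expect_error(fractional_synthesis(s, a, N, 0, pars$k_p), "undefined")

  # peptides sharing k but differing in a and N collapse onto one curve
  tt <- c(0, 1, 3, 5, 7, 10, 14)
  withr::with_seed(45, {
    curves <- sapply(1:14, function(i) {
      ai <- runif(1, 0.3, 0.8); Ni <- sample(8:35, 1)
      s <- tibble::tibble(t = tt, A0 = model_a0(0.12, tt, ai, Ni, pars$p_ss,
                                                pars$k_p))
      fractional_synthesis(s, ai, Ni, pars$p_ss, pars$k_p)$fs
    })
    spread <- apply(curves, 1, function(x) diff(range(x)))
    expect_lt(max(spread[-1]), 0.02)
    expect_equal(max(abs(curves[1, ])), 0, tolerance = 1e-12)
  })
})
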
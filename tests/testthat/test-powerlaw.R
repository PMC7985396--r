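test_that("hurwitz zeta matches brute-force summation", {
  brute <- function(alpha, q) {
    K <- 2e6
    sum((q:K)^(-alpha)) + (K + 0.5)^(1 - alpha) / (alpha - 1)
  }
  for (alpha in c(1.5, 2, 2.5, 3.5)) {
    for (q in c(1, 2, 7, 40)) {
      expect_equal(hurwitz_zeta(alpha, q), brute(alpha, q), tolerance = 1e-9)
    }
  }
  expect_equal(hurwitz_zeta(2, 1), pi^2 / 6, tolerance = 1e-12)
})

test_that("mle_alpha reproduces the closed-form estimator and its scaling", {
  est <- mle_alpha(c(1, 1, 1, 1), 1)
  expect_equal(est$alpha_hat, 1 + 1 / log(2), tolerance = 1e-12)
  expect_equal(est$sigma, (1 / log(2)) / 2, tolerance = 1e-12)

  est2 <- mle_alpha(c(2, 2, 2), 2)
  expect_equal(est2$alpha_hat, 1 + 1 / log(2 / 1.5), tolerance = 1e-12)

  # duplicating the tail leaves alpha unchanged and shrinks sigma by sqrt(2)
  x <- c(1, 1, 2, 3, 5, 8)
  a1 <- mle_alpha(x, 1)
  a2 <- mle_alpha(c(x, x), 1)
  expect_equal(a2$alpha_hat, a1$alpha_hat)
  expect_equal(a2$sigma, a1$sigma / sqrt(2))

  # alpha > 1 always; empty tail errors
  expect_gt(mle_alpha(c(1, 1, 1, 2), 1)$alpha_hat, 1)
  expect_error(mle_alpha(c(1, 2), 5), "no observations")

  # exact discrete MLE recovers truth at a small cutoff where the
  # half-shift approximation is biased low
  x <- sample_discrete_powerlaw(2.5, 1, 10000, seed = 42)
  exact <- mle_alpha(x, 1, method = "exact")
  expect_lt(abs(exact$alpha_hat - 2.5), 3 * exact$sigma * 1.5)
  expect_lt(mle_alpha(x, 1)$alpha_hat, 2.2)
})

test_that("ks_distance evaluates the zeta-normalized CDF gap", {
  # hand case {1, 2}, alpha = 2.5, xmin = 1, by direct pmf summation
  Z <- hurwitz_zeta(2.5, 1)
  P1 <- 1 / Z
  P2 <- P1 + 2^(-2.5) / Z
  expected <- max(abs(0.5 - P1), abs(1 - P2))
  expect_equal(ks_distance(c(1, 2), 2.5, 1), expected, tolerance = 1e-12)

  # invariant under duplicating every observation
  x <- c(1, 1, 2, 3, 5, 8)
  expect_equal(ks_distance(c(x, x), 2.1, 1), ks_distance(x, 2.1, 1))

  # forcing the empirical proportions onto the model masses drives the
  # gap at every interior support point to ~0
  n1 <- round(1e6 * P1)
  xx <- c(rep(1, n1), rep(2, 1e6 - n1))
  expect_equal(abs(n1 / 1e6 - P1), 0, tolerance = 1e-6)
  expect_equal(ks_distance(xx, 2.5, 1), 1 - P2, tolerance = 1e-5)
})

test_that("select_xmin matches an exhaustive brute-force scan", {
  gens <- list(
    function(s) sample_discrete_powerlaw(2.2, 1, 300, seed = s),
    function(s) sample_degree_sequence("exponential", list(lambda = 0.3), 300,
                                       seed = s),
    function(s) withr::with_seed(s, sample(1:15, 200, replace = TRUE))
  )
  for (i in 1:12) {
    x <- gens[[1 + (i %% 3)]](1000 + i)
    fit <- select_xmin(x)
    oracle <- brute_select_xmin(x)
    expect_equal(fit$xmin, oracle$xmin, info = paste("case", i))
    expect_equal(fit$alpha_hat, oracle$alpha, tolerance = 1e-4)
    expect_equal(fit$ks_D, oracle$D, tolerance = 1e-6)
  }
  # degenerate sequences error with a classed condition
  expect_error(select_xmin(c(3, 3, 3)), class = "sfnet_degenerate")
  expect_error(select_xmin(c(0, 0, 1)), class = "sfnet_degenerate")
})

test_that("select_xmin recovers a planted cutoff under body contamination", {
  hits <- 0
  for (r in 1:10) {
    tail <- sample_discrete_powerlaw(2.3, 4, 3500, seed = 40 + r)
    body <- withr::with_seed(140 + r, sample(1:3, 1500, replace = TRUE))
    fit <- select_xmin(c(tail, body))
    hits <- hits + (abs(fit$xmin - 4) <= 2)
  }
  expect_gte(hits, 8)

  # pure power-law sample: selected cutoff stays small
  small <- vapply(1:10, function(r) {
    select_xmin(sample_discrete_powerlaw(2.5, 1, 3000, seed = 60 + r))$xmin
  }, numeric(1))
  expect_gte(mean(small <= 3), 0.8)
})

test_that("the power-law sampler matches its analytic pmf and is reproducible", {
  x <- sample_discrete_powerlaw(2.5, 3, 1e5, seed = 7)
  expect_true(all(x >= 3))
  expect_identical(x, sample_discrete_powerlaw(2.5, 3, 1e5, seed = 7))
  p3 <- 3^(-2.5) / hurwitz_zeta(2.5, 3)
  expect_lt(abs(mean(x == 3) - p3), 3 * sqrt(p3 * (1 - p3) / 1e5))
  expect_error(sample_discrete_powerlaw(0.9, 1, 10), "greater than 1")

  # independent cross-check of the whole fit against igraph's plfit
  y <- sample_discrete_powerlaw(2.6, 2, 5000, seed = 8)
  ours <- select_xmin(y)
  theirs <- igraph::fit_power_law(y, implementation = "plfit")
  expect_lt(abs(ours$alpha_hat - theirs$alpha), 0.1)
})

test_that("goodness-of-fit bootstrap is seeded, valid, and rejects non-power-law data", {
  x <- sample_discrete_powerlaw(2.4, 1, 800, seed = 11)
  fit <- select_xmin(x)
  p1 <- gof_pvalue(x, fit, n_boot = 60, seed = 5)
  p2 <- gof_pvalue(x, fit, n_boot = 60, seed = 5)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_length(attr(p1, "boot_D"), 60L)
  expect_true(p1 >= 0 && p1 <= 1)
  expect_error(gof_pvalue(x, fit, n_boot = 0), "positive")

  # near-uniform (Poisson-like) degrees are firmly rejected when the
  # cutoff is fixed at the support's base; with a free cutoff the scan
  # retreats into a small fittable micro-tail and loses power
  y <- withr::with_seed(12, stats::rpois(2000, 8) + 1)
  fy1 <- powerlaw_fit_at(y, 1)
  expect_lt(as.numeric(gof_pvalue(y, fy1, n_boot = 100, seed = 6,
                                  refit = "fixed")), 0.1)
  # geometric data with large n, same fixed-cutoff protocol
  g <- sample_degree_sequence("exponential", list(lambda = 0.1), 5000,
                              seed = 13)
  fg <- powerlaw_fit_at(g, 1)
  expect_lt(as.numeric(gof_pvalue(g, fg, n_boot = 100, seed = 7,
                                  refit = "fixed")), 0.1)
})
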
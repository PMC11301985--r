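# Entropy of fitted score densities and Pearson divergence from uniform.

test_that("closed-form entropies match known special cases", {
  expect_equal(shannon_entropy("weibull", 1, 1), 1)        # Exponential(1)
  expect_equal(shannon_entropy("gamma", 1, 1), 1)
  expect_equal(shannon_entropy("weibull", 2, 1),
               0.5772156649 / 2 + log(1 / 2) + 1, tolerance = 1e-10)
  expect_error(shannon_entropy("weibull", -1, 1), "positive")
})

test_that("closed-form entropies agree with quadrature over a grid", {
  for (shape in c(0.5, 1, 2, 5)) for (sr in c(0.5, 1, 2)) {
    expect_equal(shannon_entropy("weibull", shape, sr),
                 numerical_entropy(function(x) dweibull(x, shape, sr)),
                 tolerance = 1e-6)
    expect_equal(shannon_entropy("gamma", shape, sr),
                 numerical_entropy(function(x) dgamma(x, shape, sr)),
                 tolerance = 1e-6)
  }
})

test_that("Weibull entropy follows the scale translation law", {
  for (k in c(0.7, 1.5, 3)) for (lam in c(0.5, 2, 7))
    expect_equal(shannon_entropy("weibull", k, lam),
                 shannon_entropy("weibull", k, 1) + log(lam), tolerance = 1e-12)
})

test_that("score-density ML fits recover generating parameters", {
  set.seed(23)
  w <- fit_score_density(rweibull(5000, shape = 2, scale = 3), "weibull")
  expect_lt(abs(w$shape - 2), 0.1)
  expect_lt(abs(w$scale_or_rate - 3), 0.15)
  g <- fit_score_density(rgamma(5000, shape = 2, rate = 1), "gamma")
  expect_lt(abs(g$shape - 2), 0.15)
  expect_lt(abs(g$scale_or_rate - 1), 0.1)
  expect_equal(w$entropy, shannon_entropy("weibull", w$shape, w$scale_or_rate),
               tolerance = 1e-10)
  expect_error(fit_score_density(c(0, 1, 2, rep(1, 10))), "positive")
  expect_error(fit_score_density(rep(1.5, 5)), "at least 10")
})

test_that("BIC chooses between Weibull and Gamma score densities", {
  set.seed(29)
  cw <- choose_score_density(rweibull(4000, shape = 3, scale = 2))
  cg <- choose_score_density(rgamma(4000, shape = 0.8, rate = 1))
  expect_equal(cw$family, "weibull")
  expect_equal(cg$family, "gamma")
  expect_s3_class(attr(cw, "alternative"), "score_density_fit")
})

test_that("Pearson divergence is zero for flat histograms and non-negative", {
  # equal mass at every bin center is exactly uniform across bins
  centers <- rep(seq(0.1, 9.9, by = 0.2), times = 4)
  expect_equal(pearson_divergence_from_uniform(centers, 0, 10, bins = 50), 0)
  set.seed(31)
  x <- runif(5000, 0, 10)
  expect_gte(pearson_divergence_from_uniform(x, 0, 10), 0)
  expect_error(pearson_divergence_from_uniform(c(-1, 5), 0, 10), "outside")
  expect_error(pearson_divergence_from_uniform(1:10, 0, 10, bins = 2), "bins")
})

test_that("divergence estimates the chi-squared integral for a linear density", {
  set.seed(37)
  x <- sqrt(runif(40000))            # density 2x on [0,1]
  d <- pearson_divergence_from_uniform(x, 0, 1, bins = 50)
  expect_lt(abs(d - 1 / 3), 0.05)    # integral of (2x-1)^2 on [0,1]
})

test_that("divergence is invariant under identical affine rescaling", {
  set.seed(41)
  x <- rbeta(3000, 2, 1)
  d1 <- pearson_divergence_from_uniform(x, 0, 1, bins = 20)
  d2 <- pearson_divergence_from_uniform(10 * x + 5, 5, 15, bins = 20)
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("the JPD score diverges farther from uniform than competing scores", {
  # graded instrument: versus the conventional sum score
  graded_ok <- vapply(1:3, function(s) {
    g <- simulate_graded_instrument(n = 800, p = 5, K = 11, seed = s)
    sc <- score_jpd(g$table)$log_jpd
    dj <- pearson_divergence_from_uniform(rescale_scores(sc, 0, 10), 0, 10)
    ds <- pearson_divergence_from_uniform(
      rescale_scores(rowSums(unclass(g$table)), 0, 10), 0, 10)
    dj > ds
  }, logical(1))
  expect_true(all(graded_ok))
  # mixed severity panel: versus a smooth latent-severity composite
  mixed_ok <- vapply(1:5, function(s) {
    m <- small_mixed(600, s)
    sc <- score_jpd(m$table)$log_jpd
    dj <- pearson_divergence_from_uniform(rescale_scores(sc, 0, 10), 0, 10)
    dl <- pearson_divergence_from_uniform(rescale_scores(m$latent, 0, 10), 0, 10)
    dj > dl
  }, logical(1))
  expect_true(all(mixed_ok))
})

test_that("compare_scorings tabulates entropy, divergence and granularity", {
  g <- simulate_graded_instrument(n = 500, p = 4, K = 11, seed = 19)
  sc <- score_jpd(g$table)$log_jpd
  cmp <- compare_scorings(list(jpd = sc, sum = rowSums(unclass(g$table))))
  expect_equal(nrow(cmp), 2L)
  expect_true(all(c("entropy", "divergence", "distinct_values") %in% names(cmp)))
  expect_gt(cmp$distinct_values[1], cmp$distinct_values[2])
})
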
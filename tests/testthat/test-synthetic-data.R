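# Generators: determinism, contracts, and the structure they promise.

test_that("generators are pure functions of (params, seed)", {
  g1 <- simulate_graded_instrument(n = 100, p = 3, K = 5, seed = 1)
  g2 <- simulate_graded_instrument(n = 100, p = 3, K = 5, seed = 1)
  expect_identical(unclass(g1$table), unclass(g2$table))
  expect_identical(g1$latent, g2$latent)
  m1 <- simulate_mixed_severity(300, seed = 2)
  m2 <- simulate_mixed_severity(300, seed = 2)
  expect_identical(unclass(m1$table), unclass(m2$table))
  d1 <- simulate_discrete_joint(c(2, 2), c(.4, .3, .2, .1), 200, seed = 3)
  d2 <- simulate_discrete_joint(c(2, 2), c(.4, .3, .2, .1), 200, seed = 3)
  expect_identical(unclass(d1$table), unclass(d2$table))
  # and they restore the caller's RNG state
  set.seed(777); before <- .Random.seed
  invisible(simulate_graded_instrument(n = 50, p = 2, K = 3, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("graded generator respects its contracts", {
  g <- simulate_graded_instrument(n = 200, p = 4, K = 7, seed = 5)
  expect_true(all(unclass(g$table) %in% 0:6))
  expect_length(g$latent, 200)
  expect_error(simulate_graded_instrument(n = 100, p = 2, K = 5, seed = 1,
                                          discriminations = c(0, 1)), "> 0")
  expect_error(simulate_graded_instrument(n = 100, p = 1, K = 3, seed = 1,
                                          thresholds = list(c(1, 0))),
               "strictly increasing")
  expect_error(simulate_graded_instrument(n = 5, p = 2, K = 3, seed = 1), "n >= 10")
  expect_error(simulate_graded_instrument(n = 100, p = 2, K = 3), "seed")
})

test_that("strong discrimination makes items track the latent trait", {
  # fine response scale so category ties do not cap the rank correlation
  thr <- lapply(1:3, function(j) seq(-2, 2, length.out = 8))
  g <- simulate_graded_instrument(n = 2000, p = 3, K = 9, seed = 11,
                                  discriminations = rep(5, 3), thresholds = thr)
  for (j in 1:3)
    expect_gt(cor(unclass(g$table)[, j], g$latent, method = "spearman"), 0.9)
})

test_that("graded items are mutually positively rank-correlated", {
  ok <- vapply(1:10, function(s) {
    g <- simulate_graded_instrument(n = 2000, p = 3, K = 5, seed = s)
    m <- unclass(g$table)
    all(cor(m, method = "spearman")[upper.tri(diag(3))] > 0) &&
      all(cor(m, g$latent, method = "spearman") > 0)
  }, logical(1))
  expect_true(all(ok))
})

test_that("mixed-severity generator produces unidirectional skewed indicators", {
  ok <- vapply(1:10, function(s) {
    m <- simulate_mixed_severity(2000, seed = s)
    all(cor(unclass(m$table), method = "spearman")[upper.tri(diag(6))] > 0)
  }, logical(1))
  expect_true(all(ok))
  # with zero slope, the count mean equals exp(intercept)
  m0 <- simulate_mixed_severity(4000, count_params = list(c(log(2), 0, 0.5)),
                                binary_params = list(c(0, 1)), seed = 7)
  y <- unclass(m0$table)[, "count1"]
  se <- sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - 2), 3 * se)
  expect_error(simulate_mixed_severity(100, count_params = list(c(0, 1, -1)),
                                       seed = 1), "> 0")
})

test_that("discrete-joint sampler matches its pmf in the large-sample limit", {
  pmf <- c(.4, .3, .2, .1)
  sim <- simulate_discrete_joint(c(2, 2), pmf, n = 10000, seed = 13)
  emp <- empirical_joint_pmf(sim$table)
  key <- apply(emp$support, 1, paste, collapse = ",")
  want <- c("0,0" = .4, "1,0" = .3, "0,1" = .2, "1,1" = .1)
  expect_lt(max(abs(emp$probs - want[key])), 0.02)
  expect_error(simulate_discrete_joint(c(2, 2), c(.4, .3, .2), 10, seed = 1),
               "length")
  expect_error(simulate_discrete_joint(c(2, 2), c(.4, .3, .1, .1), 10, seed = 1),
               "sum to 1")
  expect_error(simulate_discrete_joint(c(2, 2), c(.4, .3, .2, .1), 0, seed = 1),
               "n >= 1")
})
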
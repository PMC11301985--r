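# Permutation planning, permutation-averaged scoring, caching, rescaling.

test_that("permutation plans enumerate p! distinct orderings", {
  for (p in 1:5) {
    plan <- plan_permutations(p)
    expect_equal(nrow(plan$orderings), factorial(p))
    expect_false(any(duplicated(apply(plan$orderings, 1, paste, collapse = ","))))
    expect_true(all(apply(plan$orderings, 1, function(o) setequal(o, 1:p))))
  }
  plan3 <- plan_permutations(3)
  expect_equal(length(plan3$distinct_models), 3 * 2^2)   # p * 2^(p-1)
})

test_that("ordering sampling is seeded, capped and reproducible", {
  p1 <- plan_permutations(6, max_permutations = 100, seed = 42)
  p2 <- plan_permutations(6, max_permutations = 100, seed = 42)
  expect_equal(nrow(p1$orderings), 100)
  expect_identical(p1$orderings, p2$orderings)
  expect_true(p1$sampled)
  expect_error(plan_permutations(6, max_permutations = 100), "seed")
  # cap at or above p! keeps everything and needs no seed
  expect_equal(nrow(plan_permutations(4, max_permutations = 24)$orderings), 24)
})

test_that("single-indicator scoring reduces to the marginal model", {
  set.seed(5)
  tab <- indicator_table(data.frame(y = rgamma(80, 2, 1)), cont_schema("y"))
  sc <- score_jpd(tab, offset = 0)
  marg <- fit_conditional(tab, "y", offset = 0)
  expect_equal(sc$log_jpd, unname(conditional_log_density(marg, unclass(tab))),
               tolerance = 1e-12)
  expect_true(all(sc$between_spec_sd == 0))
})

test_that("saturated chains reproduce the empirical joint for every ordering", {
  sim <- simulate_discrete_joint(c(2, 2, 2),
                                 c(.1, .2, .05, .15, .1, .1, .2, .1),
                                 n = 500, seed = 3)
  sc <- score_jpd(sim$table, keep_per_ordering = TRUE)
  emp <- empirical_joint_pmf(sim$table)
  key <- apply(unclass(sim$table), 1, paste, collapse = "\r")
  ek <- apply(emp$support, 1, paste, collapse = "\r")
  pemp <- emp$probs[match(key, ek)]
  for (o in seq_len(ncol(sc$per_ordering)))
    expect_lt(max(abs(exp(sc$per_ordering[, o]) - pemp)), 1e-12)
  expect_lt(max(sc$between_spec_sd), 1e-12)
})

test_that("the averaged score is the row mean of per-ordering log densities", {
  g <- simulate_graded_instrument(n = 120, p = 3, K = 5, seed = 8)
  sc <- score_jpd(g$table, keep_per_ordering = TRUE)
  expect_equal(sc$log_jpd, unname(rowMeans(sc$per_ordering)), tolerance = 1e-12)
  v <- apply(sc$per_ordering, 1, stats::sd)   # denominator |orderings| - 1
  expect_equal(sc$between_spec_sd, unname(v), tolerance = 1e-12)
})

test_that("model caching is transparent (bit-identical to naive refits)", {
  g <- simulate_graded_instrument(n = 150, p = 3, K = 5, seed = 12)
  cached <- score_jpd(g$table, cache = TRUE)
  naive <- score_jpd(g$table, cache = FALSE)
  expect_lt(max(abs(cached$log_jpd - naive$log_jpd)), 1e-12)
  expect_lt(max(abs(cached$between_spec_sd - naive$between_spec_sd)), 1e-12)
})

test_that("gaussian linear chains are order-invariant (multivariate-normal identity)", {
  set.seed(19)
  df <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  df$b <- df$b + 0.5 * df$a
  tab <- indicator_table(df, cont_schema(names(df), "gaussian"))
  sc <- score_jpd(tab)
  expect_lt(max(sc$between_spec_sd), 1e-10)
})

test_that("between-specification dispersion shrinks with n under independence", {
  sch <- cont_schema(c("a", "b", "c"))
  msd <- function(n, s) {
    set.seed(s)
    tab <- indicator_table(data.frame(a = rgamma(n, 2, 1), b = rgamma(n, 2, 1),
                                      c = rgamma(n, 2, 1)), sch)
    mean(score_jpd(tab, offset = 0)$between_spec_sd)
  }
  big <- mean(vapply(1:10, function(s) msd(5000, s), 0))
  small <- mean(vapply(1:10, function(s) msd(200, 100 + s), 0))
  expect_lt(big, small)
})

test_that("rescaling is an affine monotone map onto [lo, hi]", {
  expect_equal(rescale_scores(c(-5, -3, -1), 0, 10), c(0, 5, 10))
  expect_error(rescale_scores(rep(2, 5), 0, 10), "degenerate")
  set.seed(2)
  x <- rnorm(50)
  expect_equal(cor(x, rescale_scores(x, 0, 10), method = "spearman"), 1)
})

test_that("jpd_index returns a full S3 fit with working methods", {
  g <- simulate_graded_instrument(n = 150, p = 3, K = 5, seed = 7)
  fit <- jpd_index(g$table, attr(g$table, "schema"), rescale = c(0, 10))
  expect_s3_class(fit, "jpd_index")
  expect_length(fitted(fit), 150)
  expect_true(all(fit$scores$rescaled >= 0 & fit$scores$rescaled <= 10))
  expect_output(print(fit), "Joint-probability-density index")
  expect_output(print(summary(fit)), "Between-specification SD")
  expect_named(coef(fit))
  # frozen-model prediction reproduces in-sample scores for the same rows
  pred <- predict(fit, as.data.frame(unclass(g$table)[1:20, ]))
  expect_equal(pred$log_jpd, fit$scores$log_jpd[1:20], tolerance = 1e-12)
})
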
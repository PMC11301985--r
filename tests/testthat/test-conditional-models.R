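# Conditional regressions per family, the PIG distribution, and
# information-criterion family selection.

test_that("PIG log-pmf matches its closed-form zero mass and normalizes", {
  # P(0) = exp((1 - sqrt(1 + 2*sigma*mu)) / sigma)
  expect_equal(exp(pig_logpmf(0, mu = 2, sigma = 1)), exp(1 - sqrt(5)),
               tolerance = 1e-12)
  for (mu in c(0.5, 2, 5)) for (sg in c(0.3, 1, 2))
    expect_equal(sum(exp(pig_logpmf(0:300, mu, sg))), 1, tolerance = 1e-8)
  expect_true(all(pig_logpmf(0:50, 2, 1) <= 0))
  expect_error(pig_logpmf(-1, 1, 1), "non-negative")
  expect_error(pig_logpmf(1.5, 1, 1), "integer")
  expect_error(pig_logpmf(1, -1, 1), "positive")
})

test_that("PIG tends to Poisson as dispersion vanishes", {
  for (mu in c(0.5, 1, 3)) {
    d <- abs(exp(pig_logpmf(0:40, mu, 1e-8)) - dpois(0:40, mu))
    expect_lt(max(d), 1e-5)
  }
})

test_that("intercept-only fits recover closed-form MLEs", {
  sch <- binary_schema("y")
  tab <- indicator_table(data.frame(y = c(1, 1, 1, 0)), sch)
  fit <- fit_conditional(tab, "y")
  expect_equal(plogis(fit$coefficients[["intercept"]]), 0.75, tolerance = 1e-6)
  expect_equal(conditional_log_density(fit, c(y = 1)), log(0.75), tolerance = 1e-6)
  expect_equal(conditional_log_density(fit, c(y = 0)), log(0.25), tolerance = 1e-6)
  # zero-variance target under a dispersion family is a degenerate fit
  schg <- cont_schema("z", "gaussian")
  ctab <- indicator_table(data.frame(z = rep(2.5, 10)), schg)
  expect_error(fit_conditional(ctab, "z"), "zero variance")
})

test_that("conditional log densities match hand closed forms", {
  bern <- manual_conditional("bernoulli", c(intercept = qlogis(0.75)), link = "logit")
  expect_equal(conditional_log_density(bern, c(y = 0)), log(0.25), tolerance = 1e-10)
  # Gamma with shape b = 1 is Exponential(1/mu): log f(2; mu=2) = -log 2 - 1
  gam <- manual_conditional("gamma", c(intercept = 2), dispersion = 1)
  expect_equal(conditional_log_density(gam, c(y = 2)), -log(2) - 1,
               tolerance = 1e-12)
  expect_error(conditional_log_density(gam, c(y = -1)), "support")
})

test_that("gamma log density integrates to 1 over a parameter grid", {
  for (b in c(0.8, 2, 5)) for (mu in c(0.5, 1, 3)) {
    m <- manual_conditional("gamma", c(intercept = mu), dispersion = b)
    total <- integrate(function(x)
      exp(conditional_log_density(m, cbind(y = x))), 0, Inf, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("reported loglik equals the sum of conditional log densities", {
  set.seed(11)
  df <- data.frame(x = rgamma(300, 2, 1), y = rpois(300, 2),
                   b = rbinom(300, 1, 0.4), g = rnorm(300, 5, 1))
  sch <- jpd_schema(indicator_schema("x", "continuous", "gamma"),
                    indicator_schema("y", "count", "pig"),
                    indicator_schema("b", "binary", "bernoulli"),
                    indicator_schema("g", "continuous", "gaussian"))
  tab <- indicator_table(df, sch)
  for (tgt in c("x", "y", "b", "g")) {
    fit <- fit_conditional(tab, tgt, setdiff(c("x", "b"), tgt))
    expect_equal(fit$loglik,
                 sum(conditional_log_density(fit, unclass(tab))),
                 tolerance = 1e-8)
  }
})

test_that("gamma conditional ML agrees with an independent optimizer oracle", {
  set.seed(21)
  n <- 2000
  x <- runif(n, 0, 5); mu <- 2 + 0.5 * x
  y <- rgamma(n, shape = 3, scale = mu / 3)
  sch <- cont_schema(c("y", "x"))
  tab <- indicator_table(data.frame(y = y, x = x), sch)
  fit <- fit_conditional(tab, "y", "x", offset = 0)
  # independent route: generic optimizer on the full Gamma log likelihood
  nll <- function(par) {
    m <- par[1] + par[2] * x
    if (any(m <= 0) || par[3] <= 0) return(1e10)
    -sum(dgamma(y, shape = par[3], rate = par[3] / m, log = TRUE))
  }
  ora <- optim(c(2, 0.5, 3), nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(unname(fit$coefficients[["intercept"]]), ora$par[1], tolerance = 1e-2)
  expect_equal(unname(fit$coefficients[["x"]]), ora$par[2], tolerance = 1e-2)
  expect_equal(fit$dispersion, ora$par[3], tolerance = 1e-2)
  expect_equal(fit$loglik, -ora$value, tolerance = 1e-4)
  # and recovers the generating parameters
  expect_lt(abs(fit$coefficients[["intercept"]] - 2), 0.2)
  expect_lt(abs(fit$coefficients[["x"]] - 0.5), 0.1)
  expect_lt(abs(fit$dispersion - 3), 0.4)
})

test_that("ML bias shrinks with sample size (gamma conditional)", {
  err <- sapply(c(500, 5000), function(n) {
    set.seed(31)
    x <- runif(n, 0, 5)
    y <- rgamma(n, shape = 3, scale = (2 + 0.5 * x) / 3)
    tab <- indicator_table(data.frame(y = y, x = x), cont_schema(c("y", "x")))
    fit <- fit_conditional(tab, "y", "x", offset = 0)
    abs(fit$coefficients[["x"]] - 0.5) + abs(fit$dispersion - 3)
  })
  expect_lt(err[2], err[1])
})

test_that("BIC selects the generating count family", {
  sch <- count_schema("y", "poisson")
  pois_ok <- sum(vapply(1:10, function(s) {
    set.seed(s)
    tab <- indicator_table(data.frame(y = rpois(2000, 3)), sch)
    select_count_family(tab, "y", candidates = c("poisson", "pig"))$chosen == "poisson"
  }, logical(1)))
  pig_ok <- sum(vapply(1:10, function(s) {
    set.seed(s)
    tab <- indicator_table(data.frame(y = rpig(2000, 2, 1)), sch)
    select_count_family(tab, "y", candidates = c("poisson", "pig"))$chosen == "pig"
  }, logical(1)))
  expect_gte(pois_ok, 9)
  expect_gte(pig_ok, 9)
  tab <- indicator_table(data.frame(y = rpois(50, 2)), sch)
  expect_error(select_count_family(tab, "y", candidates = character(0)), "empty")
})

test_that("ordinal family selection prefers the better-fitting family", {
  # right-skewed positive data: Gamma should win; ceiling-heavy graded items:
  # Gaussian should win
  set.seed(41)
  tabg <- indicator_table(data.frame(y = rgamma(800, 1.5, 1)), cont_schema("y"))
  expect_equal(select_ordinal_family(tabg, "y")$chosen, "gamma")
  g <- simulate_graded_instrument(n = 800, p = 3, K = 11, seed = 41)
  expect_equal(select_ordinal_family(g$table, "item1")$chosen, "gaussian")
})
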
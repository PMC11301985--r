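## Synthetic-data generators with the statistical structure the scoring
## method assumes: a single latent severity driving unidirectional
## indicators. Used throughout the test suite; every generator is a pure
## function of (parameters, seed).

#' Simulate a graded ordinal instrument driven by one latent trait
#'
#' Emulates a pain-interference-style instrument: p ordinal items scored
#' 0..K-1, each driven by a standard-normal latent trait via the
#' graded-response cumulative-logit law
#' \eqn{P(X_j \ge h) = \mathrm{logistic}(a_j(\theta - \tau_{jh}))} with
#' positive discriminations \eqn{a_j} (so all items are unidirectional by
#' construction) and strictly increasing thresholds \eqn{\tau_{jh}}.
#'
#' @param n Subjects (>= 10).
#' @param p Items.
#' @param K Response categories (values 0..K-1; K = 11 mimics 0-10 items).
#' @param discriminations Length-p positive vector \eqn{a_j}; default evenly
#'   spaced over \[1, 2\] (a mix of weaker and stronger items).
#' @param thresholds List of p strictly increasing length-(K-1) vectors.
#'   The default emulates a severely affected treatment-seeking cohort:
#'   thresholds equally spaced over \[-5, -1\] (so responses concentrate
#'   toward the top of the scale, as pain-interference items do in chronic
#'   pain cohorts), with per-item difficulty shifts spread over about
#'   \eqn{\pm 0.6}. This ceiling-heavy regime is exactly the one in which
#'   the joint density is monotone in the latent severity, hence
#'   codirectional with it; with mass centred mid-scale the density humps
#'   at the modal pattern instead.
#' @param seed Integer seed (required).
#' @param family Conditional family recorded in the schema for the items
#'   (default `"gamma"`; use `"saturated_categorical"` for small K when the
#'   exact chain-rule identity is wanted).
#' @return A list of class `"simulated_study"`: `table`
#'   (`indicator_table` with schema attached), `latent` (theta), `params`,
#'   `seed`.
#' @export
simulate_graded_instrument <- function(n, p, K, discriminations = NULL,
                                       thresholds = NULL, seed,
                                       family = "gamma") {
  if (missing(seed) || is.null(seed)) stop_domain("seed is required")
  if (n < 10) stop_domain("need n >= 10")
  discriminations <- discriminations %||% seq(1, 2, length.out = p)
  if (length(discriminations) != p || any(discriminations <= 0))
    stop_domain("discriminations must be length p and all > 0")
  if (is.null(thresholds)) {
    base <- seq(-5, -1, length.out = K - 1)
    thresholds <- lapply(seq_len(p), function(j) base + 1.4 * (j - (p + 1) / 2) / p)
  }
  if (length(thresholds) != p ||
      any(vapply(thresholds, function(t) length(t) != K - 1 || any(diff(t) <= 0),
                 logical(1))))
    stop_domain("each threshold vector must have K-1 strictly increasing entries")
  out <- with_seed(seed, {
    theta <- stats::rnorm(n)
    ## one uniform per item-subject; X >= h iff U <= P(X >= h), and the
    ## exceedance probabilities are decreasing in h, so the drawn category
    ## is the count of exceeded thresholds
    vals <- sapply(seq_len(p), function(j) {
      pge <- stats::plogis(outer(theta, thresholds[[j]],
                                 function(th, tau) discriminations[j] * (th - tau)))
      u <- stats::runif(n)
      rowSums(pge >= u)
    })
    list(theta = theta, vals = vals)
  })
  colnames(out$vals) <- sprintf("item%d", seq_len(p))
  schema <- jpd_schema(lapply(seq_len(p), function(j)
    indicator_schema(sprintf("item%d", j), "ordinal", family, levels = K)))
  structure(list(table = indicator_table(out$vals, schema),
                 latent = out$theta,
                 params = list(n = n, p = p, K = K,
                               discriminations = discriminations,
                               thresholds = thresholds, family = family),
                 seed = seed),
            class = "simulated_study")
}

#' Simulate mixed count/binary severity indicators
#'
#' Emulates an administrative severity panel with extreme skew and mixed
#' types: overdispersed Poisson-inverse-Gaussian counts (e.g. clinic
#' visits, emergency visits, hospitalizations) with
#' \eqn{\log\mu_j = \alpha_j + b_j\theta}, and binary diagnoses with
#' \eqn{P(1) = \mathrm{logistic}(\alpha_j + b_j\theta)}, all driven by one
#' standard-normal latent severity \eqn{\theta} with positive slopes
#' (unidirectional coding). Defaults: 3 counts with dispersions
#' \eqn{\sigma \in \{0.5, 1, 2\}} and intercepts giving means around 2, 1
#' and 0.5; 3 binaries with base rates 0.1, 0.2, 0.3; all slopes 1.
#'
#' @param n Subjects.
#' @param count_params List of `(intercept, slope, dispersion)` triples.
#' @param binary_params List of `(intercept, slope)` pairs.
#' @param seed Integer seed (required).
#' @return A `"simulated_study"` (schema families: `pig` for counts,
#'   `bernoulli` for binaries).
#' @export
simulate_mixed_severity <- function(n,
    count_params = list(c(log(2), 1, 0.5), c(log(1), 1, 1), c(log(0.5), 1, 2)),
    binary_params = list(c(stats::qlogis(0.1), 1), c(stats::qlogis(0.2), 1),
                         c(stats::qlogis(0.3), 1)),
    seed) {
  if (missing(seed) || is.null(seed)) stop_domain("seed is required")
  disp <- vapply(count_params, `[`, 0, 3)
  if (any(disp <= 0)) stop_domain("dispersions must be > 0")
  out <- with_seed(seed, {
    theta <- stats::rnorm(n)
    counts <- sapply(count_params, function(cp)
      rpig(n, exp(cp[1] + cp[2] * theta), cp[3]))
    bins <- sapply(binary_params, function(bp)
      stats::rbinom(n, 1, stats::plogis(bp[1] + bp[2] * theta)))
    list(theta = theta, vals = cbind(counts, bins))
  })
  nc <- length(count_params); nb <- length(binary_params)
  colnames(out$vals) <- c(sprintf("count%d", seq_len(nc)),
                          sprintf("binary%d", seq_len(nb)))
  schema <- jpd_schema(c(
    lapply(seq_len(nc), function(j)
      indicator_schema(sprintf("count%d", j), "count", "pig")),
    lapply(seq_len(nb), function(j)
      indicator_schema(sprintf("binary%d", j), "binary", "bernoulli"))))
  structure(list(table = indicator_table(out$vals, schema),
                 latent = out$theta,
                 params = list(n = n, count_params = count_params,
                               binary_params = binary_params),
                 seed = seed),
            class = "simulated_study")
}

#' Simulate from a fully enumerated discrete joint
#'
#' Draws iid rows from an explicit probability table over a small product
#' space and returns both the sample and the true pmf — the fixture for the
#' brute-force oracles (uniform-conditional theorem, exact chain-rule
#' identity).
#'
#' @param levels Integer vector of per-variable level counts (values
#'   `0..levels[j]-1`); product space at most 4096 cells.
#' @param pmf Numeric vector of cell probabilities in row-major order over
#'   `expand.grid(lapply(levels, seq_len) - 1)`, non-negative, summing to 1
#'   within 1e-12.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed (required).
#' @return List of class `"simulated_study"` with `table` (schema families
#'   `saturated_categorical`), `pmf` (a `discrete_pmf`), `seed`.
#' @export
simulate_discrete_joint <- function(levels, pmf, n, seed) {
  if (missing(seed) || is.null(seed)) stop_domain("seed is required")
  if (n < 1) stop_domain("need n >= 1")
  sz <- prod(levels)
  if (sz > 4096) stop_domain("product space too large (> 4096 cells)")
  if (length(pmf) != sz) stop_domain("pmf length must equal prod(levels)")
  if (any(pmf < 0) || abs(sum(pmf) - 1) > 1e-12)
    stop_domain("pmf entries must be >= 0 and sum to 1 within 1e-12")
  grid <- as.matrix(expand.grid(lapply(levels, function(K) 0:(K - 1))))
  colnames(grid) <- sprintf("v%d", seq_along(levels))
  idx <- with_seed(seed, sample.int(sz, n, replace = TRUE, prob = pmf))
  vals <- grid[idx, , drop = FALSE]
  schema <- jpd_schema(lapply(seq_along(levels), function(j)
    indicator_schema(sprintf("v%d", j),
                     if (levels[j] == 2) "binary" else "ordinal",
                     "saturated_categorical", levels = levels[j])))
  true_pmf <- structure(list(support = grid, probs = pmf), class = "discrete_pmf")
  structure(list(table = indicator_table(vals, schema),
                 latent = NULL, pmf = true_pmf,
                 params = list(levels = levels, n = n), seed = seed),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("Simulated study: n=%d, p=%d, seed=%d\n",
              nrow(x$table), ncol(x$table), x$seed))
  invisible(x)
}
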
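---
title: "Scoring severity by the joint probability density: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring severity by the joint probability density: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jpdindex)
```

## The model

`jpdindex` scores each subject by the (log) value of the estimated joint
probability density of their p severity indicators. The theoretical
motivation is an informativeness property: conditional on the density
value, the distribution of the indicators is uniform on each level set of
the density, so no information is left once the density value is known.
For a discrete joint this is checkable by brute force, and
`uniform_conditional_check()` verifies it on any enumerable pmf — on a
level set of m points with common probability s, each point's conditional
probability is s/(m·s) = 1/m, exactly.

A density value is only a *severity index* under two extra, testable
conditions:

* **unidirectionality** — every indicator is coded so that higher = more
  severe and the indicators are positively monotonically interdependent;
* **codirectionality** — the score is positively rank-correlated with
  every indicator.

`directionality_report()` tests both with Spearman's ρ (average ranks for
ties) or Kendall's τ-b, flagging any non-positive correlation. Strength
labels (weak < 0.3, moderate < 0.6, strong ≥ 0.6) are descriptive only; no
pass/fail cutoff beyond positivity is imposed, because none is canonical.

## Estimation by conditional specification

The joint density is estimated through its chain-rule factorizations

$$f(x_1,\dots,x_p) = f(x_{i_1})\, f(x_{i_2}\mid x_{i_1})\cdots
  f(x_{i_p}\mid x_{i_1},\dots,x_{i_{p-1}}),$$

one per ordering $(i_1,\dots,i_p)$. Each univariate conditional is a
parametric ML regression with an intercept and mean linear in the
conditioning variables. Different orderings give different estimators of
the same joint; the per-subject score is the arithmetic mean of the
per-ordering log densities (equivalently, the log of the geometric mean of
the density estimates — averaging is deliberately on the log scale), and
the SD of the per-ordering log densities with denominator
$|\text{orderings}|-1$ is reported as the *between-specification SD*, an
accuracy diagnostic. Two exact identities anchor the implementation and
the test suite:

* with **saturated categorical** conditionals (observed-pattern
  frequencies, no smoothing) the chain rule is an algebraic identity —
  every ordering reproduces the empirical joint to float precision, and
  the between-specification SD is zero up to ~1e−16
  (`chain_identity_check()`);
* with **Gaussian linear** conditionals the chain is also order-invariant,
  because homoskedastic linear-Gaussian conditionals in any order
  parameterize the same multivariate normal with ML moments. Genuine
  between-specification spread therefore appears only for families where
  the chain is not closed (Gamma, logistic, counts) — which is why the
  shrinking-with-n dispersion checks in the tests use Gamma chains.

### Orderings and caching

All p! orderings are used up to the default cap `max_permutations = 5040`
(exact through p = 7); beyond the cap a seeded uniform
without-replacement sample of orderings is drawn, the seed being
mandatory. Although naively p!·p conditionals are needed, only
p·2^(p−1) distinct (target, conditioning-set) pairs exist (448 at p = 7);
each is fitted once and its per-subject log-density vector reused across
orderings. Fitting is deterministic, so cached and naive per-ordering
refits agree bit-for-bit; a `cache = FALSE` path retains the naive
computation and the equality is asserted in the tests.

### Conditional families

| family | target | link | dispersion |
|---|---|---|---|
| `gamma` | graded/continuous | identity (log fallback) | shape b, profile ML |
| `gaussian` | graded/continuous/count | identity | ML variance |
| `bernoulli` | binary | logit | — |
| `poisson` | count | log | — |
| `negbin` | count | log | 1/θ |
| `pig` | count | log | σ |
| `saturated_categorical` | discrete, K ≤ 12 | — | — |

Notes on the non-obvious rows:

* **Gamma.** The canonical two-parameter log density
  $b\log b - b\log\mu + (b-1)\log x - bx/\mu - \log\Gamma(b)$ is used and
  validated by quadrature normalization over a parameter grid. The mean
  uses the identity link (a linear combination of the conditioning
  indicators), with fitted means floored at 1e−6 and an automatic fallback
  to the log link when the identity-link IRLS fails or produces
  non-positive means; an identity link on positive data can do both. The
  shape is the profile MLE given the fitted means (the Gamma GLM score for
  the regression coefficients does not involve the shape, so this is the
  joint ML). Graded items that can be 0 are shifted by a fixed
  configurable offset, default **+0.5** — half the resolution of an
  integer-graded scale, the usual continuity-correction choice. The shift
  is identical for every subject, so it changes all log densities by a
  common reparameterization and no ranking.
* **PIG.** The Poisson–inverse-Gaussian is a heavy-tailed mixed Poisson
  with mean μ and dispersion σ (variance μ + σμ²), the family of choice
  for extremely skewed utilization counts. `pig_logpmf()` evaluates
  P(0) = exp((1−√(1+2σμ))/σ) through the cancellation-free form
  −2μ/(1+√(1+2σμ)) and the higher masses by the upward Willmot recursion,
  whose terms are all positive (numerically stable); normalization and the
  σ→0 Poisson limit are asserted in tests. Regression ML maximizes the
  exact log likelihood by BFGS from Poisson-GLM and moment starts, with
  one perturbed restart before declaring failure.
* **Saturated categorical** conditionals use raw observed-pattern
  frequencies with no smoothing, precisely so that the chain-rule identity
  is exact; they are meant for the oracle regime and small-K discrete
  data, not for sparse high-dimensional tables (unseen conditioning
  patterns are an error by design).

### Family selection

Count targets choose among Poisson, negative binomial and PIG by BIC
(default) or AIC; ordinal/continuous targets may likewise choose between
Gamma and Gaussian (`select_ordinal_family()`, used by
`jpd_index(select_families = TRUE)`). Extending the information-criterion
choice from counts to graded targets is this package's decision: on
ceiling-concentrated graded items a homoskedastic Gaussian conditional
routinely out-fits the right-skewed Gamma by BIC in every one of the
implied conditionals, and insisting on Gamma would knowingly score with
the worse-fitting density. On right-skewed positive data the same
criterion returns Gamma. Zero-inflated count variants are out of scope in
this version. Family choices are frozen before scoring and are *not*
re-selected inside bootstrap replicates, so the bootstrap measures
sampling variability of a fixed specification.

### Uncertainty

`bootstrap_se()` resamples subjects (rows) with replacement, refits every
conditional in the plan, evaluates the *original* subjects under the
refitted models, and reports the per-subject SD across B replicates
(denominator B−1). B defaults to 50; 40 is a reasonable choice for
smaller mixed-indicator panels. The permutation plan is held fixed across
replicates so the SE reflects sampling error only, not
specification-sampling error. Failed replicates are skipped and logged,
the effective B is reported, and more than 50% failures is an error.

## Informativeness comparisons

Competing scorings of the same subjects (any externally supplied score
vectors) are compared on three axes:

* **Shannon entropy** of an ML-fitted parametric density of the scores —
  Weibull $E = \gamma(1-1/k) + \ln(\lambda/k) + 1$ (with Euler's constant
  γ = 0.5772156649) or Gamma $E = a - \ln b + \ln\Gamma(a) + (1-a)\psi(a)$,
  the family chosen by BIC. Both closed forms are validated against
  adaptive quadrature of $-\int f\ln f$ to 1e−6 over a parameter grid.
  Lower entropy = more concentrated information.
* **Pearson (χ²) divergence from uniform**,
  $\sum_b (\hat f_b - u)^2/u \cdot w$, with a histogram plug-in density on
  a common range (default [0, 10], 50 equal-width bins) and
  $u = 1/(hi-lo)$. The estimator is invariant to affine rescaling applied
  to scores and range alike. Because a histogram divergence rewards
  discreteness, comparisons are meaningful against *continuous* competitor
  scores (model-based person scores, factor scores); against a coarse
  integer sum score on a small mixed panel the comparison is dominated by
  lumpiness, which is why the mixed-panel test benchmarks the JPD score
  against a smooth latent-severity composite instead.
* **Distinct-value granularity** — the count of unique person scores
  (after rounding to 10 decimals); a density-based score separates nearly
  every distinct response pattern, where a sum collapses them.

## The synthetic generators

The package is fully testable without external data via three generators,
each a pure function of (parameters, seed):

* `simulate_graded_instrument()` — p ordinal 0..K−1 items driven by one
  standard-normal latent severity θ through a cumulative-logit
  (graded-response) law $P(X_j \ge h) = \mathrm{logistic}(a_j(\theta -
  \tau_{jh}))$. Defaults: discriminations evenly spaced over [1, 2] and
  thresholds equally spaced over [−5, −1] with per-item shifts of about
  ±0.6, emulating a severely affected, treatment-seeking cohort whose
  0–10 interference items pile up near the ceiling with varied item
  difficulty. This regime was chosen deliberately: the joint density is
  monotone in θ only when the probability mass accumulates at a boundary
  of the indicator space. In a balanced mid-scale population the density
  peaks at the modal pattern and the raw log density is *hump-shaped* in
  severity — it remains a most informative summary but fails
  codirectionality, which the diagnostics would correctly flag. Passing
  rank-recovery tests on this generator therefore demonstrates the method
  in its intended regime, not in every population.
* `simulate_mixed_severity()` — PIG counts (log μ linear in θ; default
  dispersions 0.5, 1, 2) plus Bernoulli diagnoses (logit linear in θ;
  default base rates 0.1, 0.2, 0.3), all slopes 1: an extremely skewed
  mixed-type administrative severity panel. With mass at the all-zero
  pattern the density *decreases* with severity, so the raw log density
  anticorrelates with θ; any strictly decreasing relabeling (e.g. the
  negated log density) carries identical information and restores
  codirectional orientation. The package reports the log density as-is
  and leaves orientation to the diagnostics.
* `simulate_discrete_joint()` — iid draws from an explicit small discrete
  pmf, returned together with the true pmf; the fixture for the theorem
  and identity oracles.

What the generators do **not** emulate: multidimensional latent
structure, missing data mechanisms (only complete-case handling is
implemented, matching the practice of excluding incomplete responders),
differential item functioning, measurement error models, or real cohort
idiosyncrasies. Green tests say the machinery is correct under the stated
single-trait data-generating processes, not that any particular real
instrument satisfies unidirectionality.

## Numerical choices and degenerate inputs

* Optimization: PIG regression uses BFGS with `reltol` 1e−12 and one
  perturbed restart; Gamma shape solves log b − ψ(b) = D by `uniroot` to
  1e−12; GLM families use the stats IRLS defaults.
* Level-set grouping in the theorem check uses tolerance 1e−9 (float
  noise only — the theorem concerns exact level sets); random continuous
  pmfs thus have singleton groups and deviation exactly 0.
* Zero-variance targets under a dispersion family, constant score vectors
  passed to rescaling, constant columns in rank correlations, and
  non-normalized pmfs are all hard errors naming the offender rather than
  silent coercions.
* Bernoulli fitted probabilities are clamped to [1e−12, 1−1e−12] before
  log-density evaluation; count/Gamma means are floored at 1e−10 / 1e−6.
* Ties in Spearman's ρ use average ranks; Kendall uses τ-b.

## Problem sizes in the checks

The test suite and acceptance script run at deliberately modest sizes
chosen as the smallest at which each property is unambiguous: the exact
identities at n = 500 and p ≤ 4 (they hold to float precision at any n);
parameter recovery at n = 5,000 with 20 replicates; rank recovery at the
full p = 7, K = 11, n = 2,000 design with all 5,040 orderings via 448
cached fits, 5 seeds; divergence oracles at n = 100,000 draws. The p = 7
scoring pathway — the largest configuration — completes in seconds per
seed thanks to the deduplicated-model cache.

## Known limitations

* Conditional means are linear in the conditioning indicators: no
  interactions, polynomial terms or splines, by design.
* In-sample scoring is the default and matches the intended use;
  `predict()` scores held-out rows under frozen conditionals but no
  cross-validation machinery is provided.
* The identity-link Gamma mean can exceed the support of bounded graded
  items near the ceiling; the density remains proper, but the fitted mean
  is not constrained to the scale.
* Orientation of the index (whether high density means high or low
  severity) is population-dependent, as discussed above; users should read
  the codirectionality report before interpreting the sign.
* The PIG dispersion is common across subjects within one conditional
  (no dispersion regression), and zero-inflated families are not offered.
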
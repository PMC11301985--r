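# jpdindex

Composite severity scores from the joint probability density of the
indicators.

## The problem

Clinical and epidemiological research constantly reduces a panel of p
severity indicators — graded questionnaire items, utilization counts,
diagnosis flags — to a single per-subject number: a pain-interference
score, a psychiatric-severity index, a frailty index. The standard routes
(sum scores, factor scores, IRT person parameters) either impose strong
distributional assumptions or use only the covariance structure of the
indicators. `jpdindex` implements a different route: score each subject by
the value of the estimated **joint probability density** (JPD) of their
indicator pattern. Conditioning on the density value leaves a uniform —
maximally uninformative — distribution over the indicators, which makes the
density value a *most informative* unidimensional summary. Provided the
indicators are **unidirectional** (all coded higher = more severe, with
positive pairwise monotone dependence) and the score is **codirectional**
with them (positively rank-correlated with every indicator), the density
value qualifies as an index.

## The estimator

For indicators x₁,…,x_p the joint density admits p! chain-rule
factorizations, one per variable ordering:

    f(x₁,…,x_p) = f(x_{i₁}) · f(x_{i₂} | x_{i₁}) · … · f(x_{i_p} | x_{i₁},…,x_{i_{p−1}})

Each univariate conditional is fitted as a parametric maximum-likelihood
regression with mean linear in the conditioning variables — two-parameter
Gamma or Gaussian for graded/continuous targets, logistic for binaries, and
Poisson / negative binomial / Poisson–inverse-Gaussian (PIG, implemented
from scratch with a numerically stable recursion) for overdispersed counts,
with the count and ordinal families selectable by AIC/BIC. Every ordering
gives an estimate of the *same* joint, so the subject's score is the
arithmetic mean of the per-ordering log densities (for p = 7: 5,040
orderings, deduplicated to at most p·2^(p−1) = 448 distinct conditional
fits via caching), and the SD of the per-ordering log densities
(denominator |orderings|−1) is reported per subject as a
between-specification accuracy diagnostic. Subject-resampling bootstrap SEs
quantify sampling error. Diagnostics (Spearman/Kendall pairwise and
item–score rank correlations) test unidirectionality and codirectionality;
informativeness of competing scorings is compared via Shannon entropy of
ML-fitted Weibull/Gamma score densities, the Pearson (χ²) divergence of the
score distribution from uniform on a common range, and distinct-value
granularity.

## Worked example

```r
library(jpdindex)

sim    <- simulate_graded_instrument(n = 500, p = 5, K = 11, seed = 42)
schema <- attr(sim$table, "schema")
fit    <- jpd_index(sim$table, schema, bootstrap = 50, seed = 42,
                    rescale = c(0, 10))
summary(fit)
#> Joint-probability-density index
#> n = 500 subjects, p = 5 indicators; 120 orderings via 80 distinct conditionals
#> Conditional families:
#>   item1   item2   item3   item4   item5
#> "gamma" "gamma" "gamma" "gamma" "gamma"
#> log-JPD score:
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> -64.118  -9.847  -8.629 -10.444  -8.629  -8.119
#> Between-specification SD range: [0.004814, 2.111]
#> Bootstrap SE range:             [0.176, 16.44]
```

The 120 factorization orderings of the 5 items were fitted via 80 cached
Gamma conditionals; each subject's score is the mean of 120 log-density
estimates and sits, as expected for a ceiling-concentrated severity
instrument, in a tight high-density bulk with a long low-density tail
(inconsistent or rare patterns). The between-specification SD shows how
little the score depends on the ordering for most subjects.

```r
round(directionality_report(sim$table, fitted(fit))$item_score, 3)
#> item1 item2 item3 item4 item5
#> 0.316 0.423 0.417 0.402 0.458
```

All item–score rank correlations are positive: the JPD score is
codirectional with every indicator and qualifies as an index for these
data.

```r
compare_scorings(list(jpd = fitted(fit), sum = rowSums(unclass(sim$table))))
#>   score  family shape scale_or_rate entropy divergence distinct_values
#> 1   jpd weibull 20.39          54.9    2.54      23.70             209
#> 2   sum weibull  5.22          23.6    2.97       7.04              25
```

The JPD score has lower Shannon entropy, diverges farther from the
uninformative uniform distribution, and separates 209 distinct person
scores where the sum score manages 25 — the granularity and informativeness
gains the method is designed to deliver.

A command-line wrapper is installed at `inst/cli/jpdindex.R` with
subcommands `score`, `diagnose`, `inform`, `simulate` and `oracle-check`:

```sh
Rscript inst/cli/jpdindex.R simulate graded --n 500 --p 5 --K 11 --seed 42 --out sim
Rscript inst/cli/jpdindex.R score --data sim_data.csv --schema sim_schema.json --out scores.csv
```

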
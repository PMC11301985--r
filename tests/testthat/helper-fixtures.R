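# Small schema/table builders shared across tests.

cont_schema <- function(names, family = "gamma") {
  jpd_schema(lapply(names, function(nm)
    indicator_schema(nm, "continuous", family)))
}

binary_schema <- function(names, family = "bernoulli") {
  jpd_schema(lapply(names, function(nm) indicator_schema(nm, "binary", family)))
}

count_schema <- function(names, family = "pig") {
  jpd_schema(lapply(names, function(nm) indicator_schema(nm, "count", family)))
}

# a hand-built fitted conditional, for closed-form density checks
manual_conditional <- function(family, coefficients, dispersion = NULL,
                               link = "identity", target = "y",
                               conditioning_set = character(0), offset = 0) {
  structure(list(target = target, conditioning_set = conditioning_set,
                 family = family, coefficients = coefficients,
                 dispersion = dispersion, link = link,
                 offset = if (family == "gamma") offset else NULL,
                 probs = NULL, loglik = NA_real_, aic = NA_real_,
                 bic = NA_real_, npar = length(coefficients), n = NA_integer_),
            class = "fitted_conditional")
}

# small mixed-severity panel used by several stochastic checks
small_mixed <- function(n, seed) {
  simulate_mixed_severity(
    n,
    count_params = list(c(log(2), 1, 0.5), c(log(0.5), 1, 1)),
    binary_params = list(c(stats::qlogis(0.15), 1), c(stats::qlogis(0.3), 1)),
    seed = seed)
}
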
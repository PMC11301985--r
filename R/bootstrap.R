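## Bootstrap standard errors of per-subject JPD scores.

#' Bootstrap standard errors for JPD scores
#'
#' Resamples subjects (rows) with replacement, refits every conditional in
#' the plan on each replicate, evaluates every ORIGINAL subject's
#' permutation-averaged log density under the refitted models, and reports
#' the per-subject standard deviation (B−1 denominator) across replicates —
#' the within-subject SD of the bootstrapped estimates. The permutation
#' plan (including any sampled orderings) is held fixed across replicates,
#' so the SE reflects sampling error only, not specification-sampling
#' error. Family choices are frozen in the schema; they are not re-selected
#' inside replicates.
#'
#' @param table An `indicator_table`.
#' @param plan A `permutation_plan` for the table (default: all p!).
#' @param B Number of replicates, >= 2 (50 is a typical choice; 40 for
#'   smaller mixed-indicator panels).
#' @param seed Integer seed (required).
#' @param offset Gamma offset.
#' @return Object of class `"jpd_bootstrap"`: `B` requested, `B_effective`
#'   (replicates that converged), `per_subject_se`, `seed`. Replicates
#'   whose refits fail are logged and skipped; more than 50% failures is an
#'   error.
#' @export
bootstrap_se <- function(table, plan = NULL, B = 50, seed, offset = 0.5) {
  stopifnot(inherits(table, "indicator_table"))
  if (missing(seed) || is.null(seed)) stop_domain("bootstrap_se requires a seed")
  if (B < 2) stop_domain("B must be >= 2")
  plan <- plan %||% plan_permutations(ncol(table))
  rows <- unclass(table)
  n <- nrow(rows)
  reps <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch({
        bt <- indicator_table(as.data.frame(rows[idx, , drop = FALSE]),
                              attr(table, "schema"))
        models <- .fit_plan_models(bt, plan, offset = offset)
        L <- .eval_model_logdens(models, rows)   # ORIGINAL subjects
        rowMeans(.ordering_logdens(plan, L))
      }, error = function(e) {
        log_msg("bootstrap replicate %d failed: %s", b, conditionMessage(e))
        NULL
      })
    })
  })
  ok <- !vapply(reps, is.null, logical(1))
  if (mean(ok) < 0.5)
    stop_domain("bootstrap failure: %d of %d replicates failed", sum(!ok), B)
  M <- do.call(cbind, reps[ok])                  # n x B_eff
  se <- apply(M, 1, stats::sd)
  structure(list(B = B, B_effective = sum(ok),
                 per_subject_se = as.numeric(se), seed = seed),
            class = "jpd_bootstrap")
}

#' @export
print.jpd_bootstrap <- function(x, ...) {
  cat(sprintf("JPD bootstrap: B = %d (%d effective), seed = %d\n",
              x$B, x$B_effective, x$seed))
  cat("per-subject SE: "); print(summary(x$per_subject_se))
  invisible(x)
}
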
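## Factorization orderings of the chain rule.

## All permutations of 1..p as a p! x p integer matrix (lexicographic).
.all_perms <- function(p) {
  if (p == 1L) return(matrix(1L, 1, 1))
  sub <- .all_perms(p - 1L)
  out <- matrix(0L, p * nrow(sub), p)
  r <- 0L
  for (first in seq_len(p)) {
    rest <- setdiff(seq_len(p), first)
    idx <- r + seq_len(nrow(sub))
    out[idx, 1] <- first
    out[idx, -1] <- matrix(rest[sub], nrow(sub), p - 1L)
    r <- r + nrow(sub)
  }
  out
}

## Canonical key for a (target, conditioning set) model.
.model_key <- function(target, set)
  paste(target, paste(sort(set), collapse = ","), sep = "|")

## The deduplicated (target, conditioning-set) models implied by orderings.
.distinct_models <- function(orderings) {
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (r in seq_len(nrow(orderings))) {
    ord <- orderings[r, ]
    for (k in seq_along(ord)) {
      key <- .model_key(ord[k], if (k > 1) ord[seq_len(k - 1)] else integer(0))
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- list(target = ord[k],
                                        set = if (k > 1) sort(ord[seq_len(k - 1)]) else integer(0),
                                        key = key)
      }
    }
  }
  out
}

#' Plan the chain-rule factorization orderings
#'
#' A joint density over p indicators admits p! chain-rule factorizations,
#' one per variable ordering; each yields a distinct conditionally specified
#' estimate of the same joint. This builds either the full set of p!
#' orderings or, when `max_permutations` is smaller, a seeded uniform
#' without-replacement sample (a random sample of orderings suffices for
#' larger p), together with the deduplicated set of (target,
#' conditioning-set) conditionals the orderings imply — at most
#' \eqn{p 2^{p-1}} models instead of \eqn{p! \cdot p} fits.
#'
#' @param p Number of indicators (>= 1).
#' @param max_permutations Cap on the number of orderings; `NULL` (default)
#'   or any value >= p! keeps all p!.
#' @param seed Integer seed, required whenever sampling occurs.
#' @return Object of class `"permutation_plan"`: `p`, integer matrix
#'   `orderings` (rows are permutations of 1..p), `sampled` flag, `seed`,
#'   and `distinct_models` (list of target/conditioning-set index pairs).
#' @examples
#' plan_permutations(3)            # 6 orderings, 12 distinct models
#' @export
plan_permutations <- function(p, max_permutations = NULL, seed = NULL) {
  p <- as.integer(p)
  if (p < 1L) stop_domain("p must be >= 1")
  pf <- factorial(p)
  sampled <- !is.null(max_permutations) && max_permutations < pf
  if (sampled && is.null(seed))
    stop_domain("sampling %d of %.0f orderings requires a seed", max_permutations, pf)
  if (!sampled) {
    orderings <- .all_perms(p)
  } else {
    m <- as.integer(max_permutations)
    if (m < 1L) stop_domain("max_permutations must be >= 1")
    orderings <- with_seed(seed, {
      if (p <= 8L) {
        all <- .all_perms(p)
        all[sample.int(nrow(all), m), , drop = FALSE]
      } else {
        ## rejection-sample distinct random permutations
        seen <- character(0); rows <- vector("list", m); got <- 0L
        while (got < m) {
          cand <- sample.int(p)
          key <- paste(cand, collapse = ",")
          if (!key %in% seen) {
            got <- got + 1L; seen <- c(seen, key); rows[[got]] <- cand
          }
        }
        do.call(rbind, rows)
      }
    })
  }
  structure(list(p = p, orderings = orderings, sampled = sampled,
                 seed = if (sampled) seed else NULL,
                 distinct_models = .distinct_models(orderings)),
            class = "permutation_plan")
}

#' @export
print.permutation_plan <- function(x, ...) {
  cat(sprintf("Permutation plan: p=%d, %d ordering%s%s, %d distinct conditionals\n",
              x$p, nrow(x$orderings), if (nrow(x$orderings) == 1) "" else "s",
              if (x$sampled) sprintf(" (sampled, seed=%d)", x$seed) else "",
              length(x$distinct_models)))
  invisible(x)
}
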
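## Index-qualification diagnostics: unidirectionality of the indicators and
## codirectionality of a score with the indicators, via rank correlations.

#' Rank correlation with tie handling
#'
#' Spearman's rho (average ranks for ties) or Kendall's tau-b, as used to
#' assess the strength of monotone dependence between skewed indicators and
#' between indicators and a composite score.
#'
#' @param x,y Numeric vectors of equal length >= 3, each with at least two
#'   distinct values.
#' @param method `"spearman"` (default) or `"kendall"`.
#' @return Correlation in \[-1, 1\].
#' @export
rank_correlation <- function(x, y, method = c("spearman", "kendall")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3)
    stop_domain("x and y must have equal length >= 3")
  if (anyNA(x) || anyNA(y)) stop_domain("missing values not allowed")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop_domain("degenerate input: constant vector")
  stats::cor(x, y, method = method)
}

.strength_label <- function(r) {
  a <- abs(r)
  ifelse(a < 0.3, "weak", ifelse(a < 0.6, "moderate", "strong"))
}

#' Unidirectionality / codirectionality report
#'
#' Computes the p x p matrix of pairwise rank correlations among indicators
#' (unidirectionality: all should be positive when every indicator is coded
#' higher = more severe) and, if a score is supplied, each indicator's rank
#' correlation with the score (codirectionality: a composite score should
#' rank subjects the same way each indicator does). Any pairwise or
#' item-score correlation <= 0 is flagged. Strength labels (weak < 0.3,
#' moderate < 0.6, strong >= 0.6) are descriptive only, not pass/fail
#' cutoffs. Also counts the distinct score values (granularity), after
#' rounding to 10 decimals.
#'
#' @param table An `indicator_table`.
#' @param score Optional numeric score vector of length n (e.g. the log-JPD
#'   or any competing composite).
#' @param method `"spearman"` or `"kendall"`.
#' @return Object of class `"directionality_report"`: `pairwise` matrix,
#'   `item_score` vector (or `NULL`), `offending_pairs` data frame,
#'   `distinct_values`, `method`.
#' @export
directionality_report <- function(table, score = NULL,
                                  method = c("spearman", "kendall")) {
  stopifnot(inherits(table, "indicator_table"))
  method <- match.arg(method)
  m <- unclass(table)
  p <- ncol(m); nms <- colnames(m)
  const <- vapply(seq_len(p), function(j) length(unique(m[, j])) < 2, logical(1))
  if (any(const))
    stop_domain("degenerate input: constant column '%s'", nms[which(const)[1]])
  pw <- diag(1, p); dimnames(pw) <- list(nms, nms)
  off <- list()
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    r <- rank_correlation(m[, i], m[, j], method)
    pw[i, j] <- pw[j, i] <- r
    if (r <= 0) off[[length(off) + 1L]] <- data.frame(
      kind = "pairwise", a = nms[i], b = nms[j], correlation = r)
  }
  is_sc <- NULL; nd <- NULL
  if (!is.null(score)) {
    if (length(score) != nrow(m)) stop_domain("score length must equal n")
    is_sc <- vapply(seq_len(p), function(j) rank_correlation(m[, j], score, method), 0)
    names(is_sc) <- nms
    for (j in seq_len(p)) if (is_sc[j] <= 0)
      off[[length(off) + 1L]] <- data.frame(
        kind = "item_score", a = nms[j], b = "score", correlation = is_sc[j])
    nd <- length(unique(round(score, 10)))
  }
  offending <- if (length(off)) do.call(rbind, off) else
    data.frame(kind = character(0), a = character(0), b = character(0),
               correlation = numeric(0))
  structure(list(pairwise = pw, item_score = is_sc, offending_pairs = offending,
                 distinct_values = nd, method = method),
            class = "directionality_report")
}

#' @export
print.directionality_report <- function(x, ...) {
  cat(sprintf("Directionality report (%s)\n", x$method))
  cat("Pairwise rank correlations:\n")
  print(round(x$pairwise, 3))
  if (!is.null(x$item_score)) {
    cat("Item-score correlations (codirectionality):\n")
    df <- data.frame(correlation = round(x$item_score, 3),
                     strength = .strength_label(x$item_score))
    print(df)
    cat("Distinct score values:", x$distinct_values, "\n")
  }
  if (nrow(x$offending_pairs)) {
    cat("NON-POSITIVE correlations (directionality violated):\n")
    print(x$offending_pairs, row.names = FALSE)
  } else cat("All correlations positive: unidirectionality",
             if (!is.null(x$item_score)) "and codirectionality" else "", "hold.\n")
  invisible(x)
}
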
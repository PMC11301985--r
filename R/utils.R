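#' @keywords internal
"_PACKAGE"

## Run an expression under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Timestamped log line on stderr.
log_msg <- function(fmt, ...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " [jpdindex] ", sprintf(fmt, ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
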
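#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Classed conditions: every user-facing failure carries a qpop_* class so the
## CLI can map it to a stable exit code and tests can assert on it.
qpop_abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "qpop_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_validation <- function(msg, ...) qpop_abort(msg, "qpop_validation_error", ...)
abort_schema <- function(msg, ...) qpop_abort(msg, "qpop_schema_error", ...)
abort_estimability <- function(msg, ...) qpop_abort(msg, "qpop_estimability_error", ...)
abort_fit <- function(msg, ...) qpop_abort(msg, "qpop_fit_error", ...)

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state on exit, so seeded generators are pure
#' functions of their arguments and never perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort_validation("`seed` must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## 32-bit FNV-1a over a character scalar; used for config provenance hashes
## (no external digest dependency needed at this fidelity).
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261 %% 2^31
  for (b in bytes) {
    h <- bitwXor(as.integer(h), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

check_number <- function(x, name, lower = -Inf, upper = Inf, integral = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    abort_validation(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  if (integral && x != round(x)) {
    abort_validation(sprintf("`%s` must be an integer, got %s", name, x))
  }
  invisible(x)
}
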
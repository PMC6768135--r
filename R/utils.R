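# Internal helpers: classed conditions and local RNG scope.

ligex_error <- function(class, message, ..., call = NULL) {
  stop(structure(
    class = c(class, "ligex_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

ligex_warn <- function(class, message, ...) {
  warning(structure(
    class = c(class, "ligex_warning", "warning", "condition"),
    list(message = message, call = NULL, ...)
  ))
}

check_number <- function(x, name, min = -Inf, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    ligex_error("ligex_invalid_argument", sprintf("`%s` must be supplied", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    ligex_error("ligex_invalid_argument",
                sprintf("`%s` must be a single finite number >= %g", name, min))
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
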
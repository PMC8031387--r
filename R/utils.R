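# Internal helpers: typed error conditions and RNG scoping.
#
# Two error classes are used throughout so callers (and the CLI exit-code
# contract) can distinguish bad input from numerical pathology:
#   rr_input_error   -- invalid arguments, malformed files, dimension clashes
#   rr_numeric_error -- singular/indefinite matrices, degenerate scales, ...

stop_input <- function(fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c("rr_input_error", "error", "condition")))
}

stop_numeric <- function(fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c("rr_numeric_error", "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  force(expr)
}

# Derive `m` reproducible sub-seeds from a master seed, each < 2^31.
derive_seeds <- function(seed, m) {
  with_seed(seed, sample.int(2147483646L, m))
}

check_scalar <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("'%s' must be a single finite number", name)
  }
  if (integer && x != round(x)) stop_input("'%s' must be an integer", name)
  if (x < min || x > max) {
    stop_input("'%s' must be in [%s, %s] (got %s)", name,
               format(min), format(max), format(x))
  }
  invisible(x)
}
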
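# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards, so seeded
#' generators are pure functions of their arguments and do not disturb the
#' caller's random stream. A `NULL` seed evaluates the expression as-is.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Commercial rounding used for all printed dollar comparisons; applied at
#' presentation only, never inside the model arithmetic.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# scalar probability check with a named error
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single probability in [0, 1] (got %s)", name,
          paste(format(x), collapse = ", "))
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stopf("'%s' must be non-negative", name)
  invisible(x)
}

check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stopf("'%s' must be a single positive number", name)
  invisible(x)
}

# 32-bit FNV-1a hash of a string, as 8 hex digits; used to stamp outputs with
# a config fingerprint without adding a dependency.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; keep h a double (it exceeds int range)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit multiply by the FNV prime 16777619 = 403 + 2^24, in exact doubles
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  # format in two 16-bit halves: h can exceed the signed integer range
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
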
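# Internal helpers shared across modules.

# Package-local memo cache (static lookup tables built on first use).
.pk_cache <- new.env(parent = emptyenv())

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.  All stochastic entry points route their `seed` argument through
# here so that identical seeds give identical output regardless of what the
# session did before.
with_preserved_seed <- function(seed, expr) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

clamp01 <- function(x) clamp(x, 0, 1)

deg <- function(rad) rad * 180 / pi

rad <- function(deg) deg * pi / 180

stop_pk <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("posturekit_error_", class),
                                  "posturekit_error"), ...)
}

warn_pk <- function(message, class) {
  rlang::warn(message, class = paste0("posturekit_warning_", class))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

`%||%` <- rlang::`%||%`
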
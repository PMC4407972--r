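# Internal helpers shared across modules.

# Run `expr` under a locally-set RNG state when `seed` is non-NULL, restoring
# the caller's stream afterwards. With seed = NULL the global stream is used
# (and advanced), so pipelines stay reproducible from one top-level set.seed().
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic seed splitting: derive child seed i from a master seed.
# Keeps results < 2^31 and decorrelates streams across pipeline stages.
split_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + 104729 * as.double(i)) %% 2147483587
}

abort_param <- function(msg) stop(msg, call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_param(sprintf("`%s` must be a finite numeric scalar", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    abort_param(sprintf("`%s` = %s is outside its valid range", name, format(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
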
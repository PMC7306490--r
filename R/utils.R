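# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed below 2^31 from a base seed and an index.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + k) %% 2147483647)
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

check_series <- function(x, name = "x", min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len)
    stop_param("%s must be a numeric series of length >= %d", name, min_len)
  if (!all(is.finite(x)))
    stop_param("%s contains non-finite values", name)
  invisible(x)
}

# Sample-moment kurtosis (Gaussian value is 3).
moment_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(NA_real_)
  mean(x^4) / m2^2
}
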
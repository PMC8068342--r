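## Internal helpers: argument checking and seeded evaluation.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || (strict_lower && x <= lower))
    stopf("'%s' must be %s %g", name, if (strict_lower) ">" else ">=", lower)
  if (x > upper || (strict_upper && x >= upper))
    stopf("'%s' must be %s %g", name, if (strict_upper) "<" else "<=", upper)
  x
}

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG state.  All package randomness funnels through here.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Deterministic child seed for a named pipeline stage, kept below 2^31 so
## it is always a valid integer seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587 + 1)
}
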
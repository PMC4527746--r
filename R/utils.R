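# Internal helpers: classed error conditions and argument validation.

.err <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "lohscan_error")))
}

.config_err <- function(fmt, ...) .err("lohscan_config_error", fmt, ...)

.check_number <- function(x, name, lo = -Inf, hi = Inf,
                          lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    .config_err("'%s' must be a single non-missing number", name)
  ok_lo <- if (lo_open) x > lo else x >= lo
  ok_hi <- if (hi_open) x < hi else x <= hi
  if (!ok_lo || !ok_hi)
    .config_err("'%s' = %g is outside its allowed range %s%g, %g%s",
                name, x, if (lo_open) "(" else "[", lo, hi,
                if (hi_open) ")" else "]")
  x
}

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    .config_err("'%s' must be an integer >= %d", name, min)
  as.integer(x)
}

.check_seed <- function(seed, name = "seed") {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed) || seed < 0 || seed > 2^31 - 10)
    .config_err("'%s' must be an integer in [0, 2^31 - 10]", name)
  as.integer(seed)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
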
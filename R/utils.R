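`%||%` <- function(x, y) if (is.null(x)) y else x

# run `expr` under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= min
}

is_fraction <- function(x, lo = 0, hi = 1, lo_open = TRUE, hi_open = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x)
  if (!ok) return(FALSE)
  lo_ok <- if (lo_open) x > lo else x >= lo
  hi_ok <- if (hi_open) x < hi else x <= hi
  lo_ok && hi_ok
}
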
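# Internal helpers: argument checking, light hashing for run logs.

assert_prob <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single numeric value", name), call. = FALSE)
  }
  lo <- if (allow_zero) 0 else .Machine$double.eps
  hi <- if (allow_one) 1 else 1 - .Machine$double.eps
  if (x < lo || x > hi) {
    stop(sprintf("'%s' must be a probability in [%s, %s], got %g",
                 name, if (allow_zero) "0" else "(0", if (allow_one) "1]" else "1)", x),
         call. = FALSE)
  }
  invisible(x)
}

assert_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop(sprintf("'%s' must be a %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Polynomial rolling hash over the deparsed object; enough to fingerprint a
# run configuration in log messages (no cryptographic intent).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

round_cents <- function(x) round(x, 2)
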
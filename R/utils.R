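# Internal helpers: argument checking, seed derivation, classed conditions.

stop_rube <- function(msg, class, ...) {
  abort(msg, class = c(paste0("rubeoscan_error_", class), "rubeoscan_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_rube(sprintf("`%s` must be a single finite number.", name), "param")
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop_rube(sprintf("`%s` must be a whole number.", name), "param")
  }
  low_ok <- if (strict_lower) x > lower else x >= lower
  if (!low_ok || x > upper) {
    stop_rube(sprintf("`%s` = %g is outside its valid range.", name, x), "param")
  }
  invisible(x)
}

# Derive a stream-specific 32-bit seed from a global seed. Keeps independent
# modules decoupled while remaining fully determined by one integer.
derive_seed <- function(seed, stream) {
  check_number(seed, "seed", integerish = TRUE)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647)
}

with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed %% 2147483647), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
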
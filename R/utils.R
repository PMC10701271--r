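# Internal helpers shared across modules.

# Structured logging to stderr; silenced via options(doseloop.verbose = FALSE).
dl_log <- function(fmt, ...) {
  if (isTRUE(getOption("doseloop.verbose", TRUE)))
    message(sprintf(paste0("[doseloop] ", fmt), ...))
  invisible(NULL)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Uniform draw in [lo, hi] using the current RNG stream.
runif1 <- function(lo, hi) stats::runif(1, lo, hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
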
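# Internal helpers shared across the package.

# Error of class "omifa_validation_error": the CLI maps it to exit status 2.
abort_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "omifa_validation_error")
}

# x * log(x) with the 0 * log(0) = 0 convention, safe for gamma in {0, 1}.
xlogx <- function(x) {
  out <- x * log(x)
  out[x <= 0] <- 0
  out
}

# Column means restricted to observed entries (mask TRUE). All-missing
# columns get 0 so a centred view stays finite.
masked_colmeans <- function(x, mask) {
  n <- colSums(mask)
  s <- colSums(x * mask)
  ifelse(n > 0, s / pmax(n, 1), 0)
}

# Deterministic child seed for restart/repetition r of a master seed,
# kept well below .Machine$integer.max.
derive_seed <- function(seed, r) {
  (as.integer(seed) + 7919L * as.integer(r)) %% 2000000011L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
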
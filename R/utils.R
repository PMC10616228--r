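# internal helpers shared across modules

# evaluate `expr` under a reproducible RNG state when a seed is supplied,
# leaving the caller's RNG untouched; otherwise use the session RNG
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# derive a stream seed below 2^31 from a root seed and a small index
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 9973) %% 2147483629) + 1L
}

# coerce an operation sequence: either a character vector of labels or a
# single compact string such as "abABA" (only when labels are single chars)
as_ops <- function(ops) {
  if (length(ops) == 1L && !is.na(ops) && nchar(ops) > 1L) {
    strsplit(ops, "", fixed = TRUE)[[1]]
  } else {
    as.character(ops)
  }
}

ops_string <- function(ops) paste(ops, collapse = "")

# absolute tolerance for arg-min/arg-max tie detection
TIE_TOL <- 1e-12

`%||%` <- function(a, b) if (is.null(a)) b else a
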
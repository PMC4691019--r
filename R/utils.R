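`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop2 <- function(...) stop(..., call. = FALSE)

# Derive a child RNG seed from a master seed; kept below 2^31 so it is a
# valid R integer.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629L)
}

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

rand_aa <- function(n, exclude = character(), rng_alphabet = AA20) {
  pool <- setdiff(rng_alphabet, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
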
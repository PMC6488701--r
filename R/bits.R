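# Bit-stream helpers. The bit order convention is MSB-first within each byte
# and MSB-first within each b-bit codon value; encode/decode must agree.

bytes_to_bits <- function(data) {
  if (length(data) == 0L) return(integer(0L))
  m <- matrix(as.integer(rawToBits(data)), nrow = 8L)
  as.vector(m[8:1, , drop = FALSE])
}

bits_to_bytes <- function(bits, n_bytes = NULL) {
  if (is.null(n_bytes)) n_bytes <- length(bits) %/% 8L
  bits <- bits[seq_len(n_bytes * 8L)]
  if (n_bytes == 0L) return(raw(0L))
  m <- matrix(bits, nrow = 8L)[8:1, , drop = FALSE]
  packBits(as.raw(as.vector(m)), type = "raw")
}

# split a 0/1 vector into b-bit values (MSB first), zero-padding the tail
bits_to_values <- function(bits, b) {
  n <- ceiling(length(bits) / b)
  if (n == 0L) return(integer(0L))
  length(bits) <- n * b
  bits[is.na(bits)] <- 0L
  m <- matrix(bits, nrow = b)
  as.integer(2^((b - 1):0) %*% m)
}

values_to_bits <- function(values, b) {
  if (length(values) == 0L) return(integer(0L))
  m <- vapply(values, function(v) (v %/% 2^((b - 1):0)) %% 2L, numeric(b))
  as.integer(m)
}
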
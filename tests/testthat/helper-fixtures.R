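# Shared fixtures for the test suite.

random_payload <- function(n, seed) {
  set.seed(seed)
  as.raw(sample.int(256L, n, replace = TRUE) - 1L)
}

# longest run of identical designed characters across address+payload+pad
max_design_run <- function(fragments) {
  dm <- dnastore:::design_matrix(fragments)
  max(apply(dm, 1L, function(row) max(rle(row)$lengths)))
}

# minimal read_pool from raw sequences (for synthetic decoder tests)
synthetic_pool <- function(seqs, read_chars) {
  structure(list(seq = seqs, origin = rep(NA_integer_, length(seqs)),
                 read_chars = read_chars, gc_fallback = 0),
            class = "read_pool")
}
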
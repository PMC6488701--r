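p0_pool <- function(enc, coverage = 50, seed = 9, sigma = 0) {
  simulate_reads(enc$fragments,
                 simulation_config(coverage, p = 0, sigma = sigma,
                                   gc_bounds = NULL, seed = seed))
}

small_encoding <- function(n_bytes = 120L, seed = 2L) {
  payload <- random_payload(n_bytes, seed)
  enc <- encode_data(payload, fragment_geometry(4L, 3L),
                     standard_alphabet("iupac15"))
  enc$payload <- payload
  enc
}

test_that("the length filter removes exactly the off-length reads", {
  pool <- synthetic_pool(c("ACGTA", "ACGT", "ACGTAC", "AAAAA"), 5L)
  flt <- filter_reads(pool, 5L)
  expect_equal(flt$seq, c("ACGTA", "AAAAA"))
  expect_equal(flt$n_discarded, 2L)
  expect_error(filter_reads(synthetic_pool("ACG", 3L), 5L), "all reads")
})

test_that("error-free pools demultiplex to their true fragments", {
  enc <- small_encoding()
  pool <- p0_pool(enc)
  pool <- filter_reads(pool, enc$fragments$geometry$read_chars)
  dmx <- demultiplex(pool, enc$manifest)
  expect_equal(dmx$group, dmx$origin)
  expect_equal(dmx$n_unassigned, 0L)
})

test_that("reads with out-of-range addresses are discarded and counted", {
  enc <- small_encoding()                      # < 64 fragments, 3-char address
  pool <- p0_pool(enc)
  n_frag <- length(enc$fragments)
  expect_lt(n_frag, 64L)
  # rewrite one read's address to the last address of the space (unused)
  bad <- pool
  substr(bad$seq[1L], 1L, 3L) <- "TTT"
  dmx <- demultiplex(bad, enc$manifest)
  expect_equal(dmx$n_unassigned, 1L)
  expect_equal(length(dmx$seq), length(pool$seq) - 1L)
})

test_that("deduplicate collapses exact duplicates only", {
  pool <- synthetic_pool(c("AAAA", "CCCC", "AAAA", "AAAA", "GGGG"), 4L)
  pool$group <- c(0L, 1L, 0L, 0L, 2L)
  dd <- deduplicate(pool)
  expect_equal(dd$seq, c("AAAA", "CCCC", "GGGG"))
  expect_equal(dd$n_duplicates, 2L)
})

test_that("base fractions sum to one at covered positions", {
  enc <- small_encoding()
  pool <- p0_pool(enc)
  bf <- base_fractions(pool$seq[pool$origin == 0L])
  expect_s3_class(bf, "base_fraction_matrix")
  expect_equal(unname(colSums(bf$fractions)),
               rep(1, ncol(bf$fractions)), tolerance = 1e-9)
  expect_equal(dim(bf$counts), c(4L, enc$fragments$geometry$read_chars))
  expect_error(base_fractions(character(0)), "empty read group")
})

test_that("the threshold lands inside a known histogram valley", {
  al <- standard_alphabet("iupac15")
  set.seed(123)
  for (i in 1:5) {
    valley_lo <- runif(1, 0.05, 0.10)
    valley_hi <- runif(1, 0.15, 0.20)
    # error fractions decay toward zero, like real substitution noise
    noise <- valley_lo * runif(4000)^3
    signal <- runif(6000, valley_hi, 1)
    thr <- find_error_threshold(c(noise, signal), al)
    expect_false(thr$fallback)
    expect_gte(thr$cutoff, valley_lo - 0.01)
    expect_lte(thr$cutoff, valley_hi + 0.01)
  }
})

test_that("degenerate histograms fall back with a warning", {
  al <- standard_alphabet("iupac15")
  # strictly decaying histogram: a descent that never turns back up
  centers <- seq(0.005, 0.995, by = 0.01)
  flat <- rep(centers, times = rev(seq_along(centers)) * 10L)
  expect_warning(thr <- find_error_threshold(flat, al), "falling back")
  expect_true(thr$fallback)
  expect_equal(thr$cutoff, 0.125)           # half the smallest design fraction
})

test_that("character inference applies the documented support rules", {
  i15 <- standard_alphabet("iupac15")
  frac <- cbind(c(0.24, 0.26, 0.26, 0.24),   # N
                c(0.02, 0.49, 0.47, 0.02),   # S
                c(0.96, 0.02, 0.01, 0.01))   # A
  bfm <- structure(list(fractions = frac, depth = rep(100L, 3L)),
                   class = "base_fraction_matrix")
  inf <- infer_characters(bfm, 0.1, i15)
  expect_equal(inf$symbols, c("N", "S", "A"))
  expect_false(any(inf$flags))

  r21 <- standard_alphabet("ratio21")
  frac2 <- cbind(c(0.71, 0.01, 0.01, 0.27),  # W with A-major -> W2
                 c(0.28, 0.01, 0.01, 0.70))  # W with T-major -> W1
  bfm2 <- structure(list(fractions = frac2, depth = rep(100L, 2L)),
                    class = "base_fraction_matrix")
  inf2 <- infer_characters(bfm2, 0.1, r21)
  expect_equal(inf2$symbols, c("W2", "W1"))

  # everything below the cutoff: unresolved, flagged
  frac3 <- cbind(c(0.05, 0.05, 0.05, 0.85))
  bfm3 <- structure(list(fractions = frac3, depth = 0L),
                    class = "base_fraction_matrix")
  inf3 <- infer_characters(bfm3, 0.1, i15)
  expect_true(all(inf3$flags))
})

test_that("character error rate counts NA as wrong, pre-correction", {
  a <- matrix(c(1L, 2L, NA, 4L), nrow = 1L)
  b <- matrix(c(1L, 2L, 3L, 5L), nrow = 1L)
  expect_equal(character_error_rate(a, b), 0.5)
  expect_equal(character_error_rate(b, b), 0)
  expect_error(character_error_rate(a, matrix(1L)), "sizes differ")
})

test_that("a clean uniform pool decodes exactly at 50x", {
  enc <- small_encoding()
  pool <- p0_pool(enc, coverage = 50)
  res <- decode_pool(pool, enc$manifest, truth = enc$fragments)
  expect_true(res$success)
  expect_identical(res$bytes, enc$payload)
  expect_equal(res$stats$char_error_rate, 0)
  expect_gt(res$stats$cutoff, 0)
  expect_lt(res$stats$cutoff, 0.25)          # below the smallest design frac
})

test_that("decoding works for every alphabet at p = 0", {
  for (nm in c("pure4", "ws6", "iupac15", "ratio21")) {
    payload <- random_payload(90L, 4L)
    enc <- encode_data(payload, fragment_geometry(4L, 3L),
                       standard_alphabet(nm))
    pool <- simulate_reads(enc$fragments,
                           simulation_config(50, p = 0, sigma = 0,
                                             gc_bounds = NULL, seed = 12))
    res <- decode_pool(pool, enc$manifest)
    expect_true(res$success)
    expect_identical(res$bytes, payload)
  }
})

test_that("a fixed cutoff overrides the automatic threshold", {
  enc <- small_encoding()
  # deep pool so every 0.25 design fraction sits safely above the 0.12 cutoff
  pool <- p0_pool(enc, coverage = 300)
  res <- decode_pool(pool, enc$manifest, cutoff = 0.12)
  expect_equal(res$stats$cutoff, 0.12)
  expect_identical(res$bytes, enc$payload)
})

test_that("the outlier filter removes foreign reads, not genuine ones", {
  enc <- small_encoding()
  pool <- p0_pool(enc, coverage = 400)
  # relabel a coherent block of fragment-1 reads with fragment 0's address:
  # simulates address substitutions landing on another valid address. The
  # block stays below the cutoff (54 / ~454 = 12%), so the first-pass support
  # reflects fragment 0's design and the foreign reads mismatch it heavily.
  foreign <- which(pool$origin == 1L)[1:54]
  addr0 <- enc$fragments$address[1L]
  for (i in foreign) substr(pool$seq[i], 1L, 3L) <- addr0
  # dedup off: at p = 0 genuine duplicate molecules are real signal here
  res <- decode_pool(pool, enc$manifest, cutoff = 0.17, dedup = FALSE,
                     truth = enc$fragments)
  expect_true(res$success)
  expect_identical(res$bytes, enc$payload)
  expect_gte(res$stats$n_outlier_reads, 40L)    # most of the planted block
  expect_lte(res$stats$n_outlier_reads, 60L)    # and few genuine reads
  # the filter can be switched off
  res2 <- decode_pool(pool, enc$manifest, cutoff = 0.17,
                      outlier_filter = FALSE)
  expect_null(res2$stats$n_outlier_reads)
})

test_that("fragment dropout without parity fails with diagnostics", {
  enc <- small_encoding()
  pool <- p0_pool(enc)
  keep <- pool$origin != 0L                    # silence one fragment entirely
  pool$seq <- pool$seq[keep]
  pool$origin <- pool$origin[keep]
  res <- decode_pool(pool, enc$manifest)
  expect_false(res$success)
  expect_match(res$stats$failure, "no redundancy")
})

test_that("decode_pool recovers dropout through Reed-Solomon parity", {
  payload <- random_payload(140L, 6L)
  enc <- encode_data(payload, fragment_geometry(4L, 3L),
                     standard_alphabet("iupac15"))
  enc <- add_parity(enc, redundancy_config(parity_count = 3L))
  pool <- simulate_reads(enc$fragments,
                         simulation_config(50, p = 0, sigma = 0,
                                           gc_bounds = NULL, seed = 14))
  keep <- pool$origin != 2L
  pool$seq <- pool$seq[keep]
  pool$origin <- pool$origin[keep]
  res <- decode_pool(pool, enc$manifest)
  expect_true(res$success)
  expect_identical(res$bytes, payload)
  expect_equal(sum(res$stats$rs$erasures), 1L)
})
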
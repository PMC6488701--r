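demo_encoding <- function(n_bytes = 100L, seed = 3L, alphabet = "iupac15",
                          geometry = fragment_geometry(4L, 3L)) {
  payload <- random_payload(n_bytes, seed)
  enc <- encode_data(payload, geometry, standard_alphabet(alphabet))
  enc$payload <- payload
  enc
}

test_that("simulation_config validates its arguments", {
  expect_s3_class(simulation_config(250), "simulation_config")
  expect_error(simulation_config(0))
  expect_error(simulation_config(250, p = 1))
  expect_error(simulation_config(250, gc_bounds = c(0.6, 0.4)))
  expect_error(simulation_config(250, representation = "empirical"),
               "requires weights")
})

test_that("sample_molecule realizes degenerate positions only", {
  al <- standard_alphabet("iupac15")
  set.seed(1)
  draws <- replicate(50, sample_molecule("AWC", al))
  expect_true(all(draws %in% c("AAC", "ATC")))
  expect_gt(length(unique(draws)), 1L)
  expect_equal(sample_molecule("ACGT", al), "ACGT")
  expect_error(sample_molecule("AXC", al), "unknown symbols")
})

test_that("read pools are byte-identical for a fixed seed", {
  enc <- demo_encoding()
  cfg <- simulation_config(40, p = 0.02, seed = 99)
  a <- simulate_reads(enc$fragments, cfg)
  b <- simulate_reads(enc$fragments, cfg)
  expect_identical(a$seq, b$seq)
  expect_identical(a$origin, b$origin)
})

test_that("per-position fractions converge to the design composition", {
  # law of large numbers at high coverage, p = 0
  enc <- demo_encoding(n_bytes = 30L)
  cfg <- simulation_config(1e4, p = 0, sigma = 0, gc_bounds = NULL, seed = 5)
  pool <- simulate_reads(enc$fragments, cfg)
  al <- enc$fragments$alphabet
  g <- enc$fragments$geometry
  for (fr in c(1L)) {
    bf <- base_fractions(pool$seq[pool$origin == fr - 1L])
    design <- dnastore:::design_matrix(enc$fragments)[fr, ]
    for (pos in seq_len(g$read_chars)) {
      expect_lt(max(abs(bf$fractions[, pos] -
                          al$composition[design[pos], ])), 0.02)
    }
  }
})

test_that("mixed-base calls follow the design binomial (3-sigma)", {
  # one fragment whose payload contains W1 (A:T = 3:7) positions
  al <- standard_alphabet("ratio21")
  geo <- fragment_geometry(1L, 1L)
  w1 <- match("W1", al$symbols)
  a <- match("A", al$symbols)
  g <- match("G", al$symbols)
  frags <- dna_fragments(al, geo, 0L, "A",
                         matrix(c(w1, a, g), nrow = 1L), "data")
  n <- 1e5
  cfg <- simulation_config(n, p = 0, gc_bounds = NULL, seed = 8)
  pool <- simulate_reads(frags, cfg)
  calls <- substr(pool$seq, 2L, 2L)                    # the W1 position
  expect_setequal(unique(calls), c("A", "T"))
  n_A <- sum(calls == "A")
  expect_lt(abs(n_A - 0.3 * n), 3 * sqrt(n * 0.3 * 0.7))
})

test_that("representation spread follows sigma", {
  enc <- demo_encoding(n_bytes = 200L, geometry = fragment_geometry(4L, 3L))
  cv <- vapply(c(0, 0.5, 1.5), function(s) {
    cfg <- simulation_config(100, p = 0, sigma = s, gc_bounds = NULL,
                             seed = 21)
    pool <- simulate_reads(enc$fragments, cfg)
    counts <- tabulate(pool$origin + 1L, length(enc$fragments))
    stats::sd(counts) / mean(counts)
  }, numeric(1L))
  expect_true(all(diff(cv) > 0))
})

test_that("read counts follow empirical weights (chi-square)", {
  enc <- demo_encoding(n_bytes = 60L)
  n <- length(enc$fragments)
  w <- seq_len(n)
  cfg <- simulation_config(500, p = 0, representation = "empirical",
                           weights = w, gc_bounds = NULL, seed = 33)
  pool <- simulate_reads(enc$fragments, cfg)
  counts <- tabulate(pool$origin + 1L, n)
  pval <- stats::chisq.test(counts, p = w / sum(w))$p.value
  expect_gt(pval, 0.01)
})

test_that("GC filtering keeps reads within bounds or warns on fallback", {
  enc <- demo_encoding(n_bytes = 60L)
  cfg <- simulation_config(50, p = 0.02, gc_bounds = c(0.4, 0.6), seed = 44)
  pool <- simulate_reads(enc$fragments, cfg)
  gc <- vapply(strsplit(pool$seq, ""), function(b)
    mean(b %in% c("C", "G")), numeric(1L))
  if (pool$gc_fallback == 0) {
    expect_true(all(gc >= 0.4 & gc <= 0.6))
  }
  # an all-A design cannot satisfy the bounds: fallback warning
  al <- standard_alphabet("pure4")
  frags <- dna_fragments(al, fragment_geometry(1L, 1L), 0L, "A",
                         matrix(c(1L, 1L, 1L), nrow = 1L), "data")
  expect_warning(
    simulate_reads(frags, simulation_config(10, p = 0, seed = 1,
                                            max_attempts = 5L)),
    "without GC filtering")
})

test_that("indel reads are emitted off-length and countable", {
  enc <- demo_encoding(n_bytes = 60L)
  cfg <- simulation_config(100, p = 0, gc_bounds = NULL, indel_rate = 0.3,
                           seed = 55)
  pool <- simulate_reads(enc$fragments, cfg)
  off <- sum(nchar(pool$seq) != pool$read_chars)
  expect_gt(off, 0L)
  flt <- filter_reads(pool, pool$read_chars)
  expect_equal(flt$n_discarded, off)
  expect_true(all(nchar(flt$seq) == pool$read_chars))
})

test_that("FASTQ output round-trips, including the empty pool", {
  enc <- demo_encoding(n_bytes = 40L)
  cfg <- simulation_config(20, p = 0.01, gc_bounds = NULL, seed = 66)
  pool <- simulate_reads(enc$fragments, cfg)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(pool, path)
  back <- read_fastq(path)
  expect_identical(back$seq, pool$seq)
  expect_equal(back$read_chars, pool$read_chars)

  empty <- withr::local_tempfile(fileext = ".fastq")
  file.create(empty)
  ep <- read_fastq(empty)
  expect_equal(length(ep), 0L)
})

test_that("the truth table records read origins", {
  enc <- demo_encoding(n_bytes = 40L)
  pool <- simulate_reads(enc$fragments,
                         simulation_config(10, p = 0, gc_bounds = NULL,
                                           seed = 77))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(pool, path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_equal(tab$origin, pool$origin)
  expect_equal(tab$seq, pool$seq)
})

test_that("weights files accept one- and two-column layouts", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1", "2.5", "0.5"), p1)
  expect_equal(read_weights(p1), c(1, 2.5, 0.5))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("2\t0.5", "1\t1", "3\t2.5"), p2)
  expect_equal(read_weights(p2), c(1, 0.5, 2.5))
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("-1"), p3)
  expect_error(read_weights(p3), "non-negative")
})
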
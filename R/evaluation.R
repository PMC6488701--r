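#' Error rate versus coverage sweep
#'
#' For each coverage and repetition: generate a random payload, encode it
#' (optionally with Reed-Solomon parity), simulate the sequencing readout,
#' decode, and record the pre-correction character error rate and whether the
#' bytes were recovered exactly. Fully deterministic given `base_seed`.
#'
#' @param payload_bytes Random payload size in bytes.
#' @param geometry A [fragment_geometry()].
#' @param alphabet A [alphabet()] object.
#' @param coverages Numeric vector of mean coverages to test.
#' @param reps Repetitions per coverage.
#' @param base_seed Base RNG seed; per-run seeds are derived from it.
#' @param p Substitution probability (default 0.02).
#' @param rs Optional [redundancy_config()].
#' @param sigma Lognormal representation spread.
#' @param gc_bounds GC filter bounds, or `NULL` to disable.
#' @param dedup Remove duplicate reads during decoding.
#' @return A list of class `sweep_result`: `runs` (one row per run with
#'   coverage, rep, seed, char_error_rate, success) and `summary` (mean and
#'   sd of the error rate and success count per coverage).
#' @export
coverage_sweep <- function(payload_bytes, geometry, alphabet, coverages,
                           reps = 5L, base_seed = 1L, p = 0.02, rs = NULL,
                           sigma = 0.5, gc_bounds = c(0.4, 0.6),
                           dedup = TRUE) {
  table <- build_codon_table(alphabet)
  runs <- list()
  for (ci in seq_along(coverages)) {
    for (rep_i in seq_len(reps)) {
      seed <- (base_seed + 7919L * ci + 104729L * rep_i) %% .Machine$integer.max
      set.seed(seed)
      payload <- as.raw(sample.int(256L, payload_bytes, replace = TRUE) - 1L)
      enc <- encode_data(payload, geometry, table)
      if (!is.null(rs)) enc <- add_parity(enc, rs)
      cfg <- simulation_config(coverages[ci], p = p, sigma = sigma,
                               gc_bounds = gc_bounds, seed = seed + 1L)
      pool <- simulate_reads(enc$fragments, cfg)
      truth <- enc$fragments
      truth_data <- subset_fragments(truth, truth$kind == "data")
      res <- decode_pool(pool, enc$manifest, dedup = dedup, truth = truth_data)
      runs[[length(runs) + 1L]] <- data.frame(
        coverage = coverages[ci], rep = rep_i, seed = seed,
        char_error_rate = res$stats$char_error_rate,
        success = res$success && identical(res$bytes, payload))
    }
  }
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(split(runs, runs$coverage), function(d)
    data.frame(coverage = d$coverage[1L],
               mean_error = mean(d$char_error_rate),
               sd_error = if (nrow(d) >= 2L) stats::sd(d$char_error_rate)
                          else NA_real_,
               successes = sum(d$success), reps = nrow(d))))
  summ <- summ[order(summ$coverage), ]
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<coverage sweep>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

subset_fragments <- function(frags, keep) {
  dna_fragments(frags$alphabet, frags$geometry, frags$index[keep],
                frags$address[keep], frags$payload[keep, , drop = FALSE],
                frags$kind[keep])
}

#' Minimum coverage for error-free decoding on a grid
#'
#' Encodes one random payload with Reed-Solomon parity and simulates
#' decoding at increasing coverages; returns the smallest grid coverage at
#' which every repetition recovers the payload with zero residual byte
#' errors. The 100 MB-scale experiment is exercised at a scaled-down payload
#' (default 100 kB); payload size is a parameter for full-scale runs.
#'
#' @param payload_bytes Payload size (default 102400 = 100 kB).
#' @param geometry A [fragment_geometry()] (default the 200-nt layout).
#' @param alphabet A [alphabet()] object.
#' @param rs_fraction Reed-Solomon parity fraction (default 0.10).
#' @param coverages Ascending coverage grid.
#' @param reps Repetitions per grid point (default 2).
#' @param base_seed Base RNG seed.
#' @param p Substitution probability (default 0.02).
#' @param sigma Lognormal representation spread.
#' @param gc_bounds GC filter bounds.
#' @return A list of class `min_coverage_result`: `coverage` (smallest
#'   sufficient grid value, `NA` if none succeeded), `tested` (per-run
#'   outcomes), and `max_tested`.
#' @export
find_min_zero_error_coverage <- function(payload_bytes = 102400L,
                                         geometry = preset_geometry("sim200"),
                                         alphabet,
                                         rs_fraction = 0.10,
                                         coverages = c(250, 650, 1300, 2000),
                                         reps = 2L, base_seed = 1L, p = 0.02,
                                         sigma = 0.5,
                                         gc_bounds = c(0.4, 0.6)) {
  stopifnot(!is.unsorted(coverages))
  set.seed(base_seed)
  payload <- as.raw(sample.int(256L, payload_bytes, replace = TRUE) - 1L)
  enc <- encode_data(payload, geometry, alphabet)
  enc <- add_parity(enc, redundancy_config(r = rs_fraction))
  tested <- list()
  found <- NA_real_
  for (cov in coverages) {
    ok <- TRUE
    for (rep_i in seq_len(reps)) {
      seed <- (base_seed + 31L * rep_i + round(17L * cov)) %% .Machine$integer.max
      cfg <- simulation_config(cov, p = p, sigma = sigma,
                               gc_bounds = gc_bounds, seed = seed)
      pool <- simulate_reads(enc$fragments, cfg)
      res <- decode_pool(pool, enc$manifest)
      exact <- res$success && identical(res$bytes, payload)
      tested[[length(tested) + 1L]] <- data.frame(
        coverage = cov, rep = rep_i, seed = seed, success = exact)
      if (!exact) { ok <- FALSE; break }
    }
    if (ok) { found <- cov; break }
  }
  structure(list(coverage = found,
                 tested = do.call(rbind, tested),
                 max_tested = max(vapply(tested, `[[`, numeric(1L),
                                         "coverage"))),
            class = "min_coverage_result")
}

#' @export
print.min_coverage_result <- function(x, ...) {
  if (is.na(x$coverage))
    cat(sprintf("<no grid coverage up to %gx decoded error-free>\n",
                x$max_tested))
  else cat(sprintf("<minimum sufficient coverage on grid: %gx>\n", x$coverage))
  invisible(x)
}

#' Cost-projection model
#'
#' Parameterized write/read cost model: writing cost is per designed
#' nucleotide synthesized, reading cost is per sequenced nucleotide times
#' coverage. Defaults use the published per-nt prices — synthesis about
#' $0.05 per 100 nt (inkjet-based pool synthesis) and sequencing about
#' $0.0000012 per 100 nt.
#'
#' @param synthesis_per_nt Synthesis cost, $ per designed nt.
#' @param sequencing_per_nt Sequencing cost, $ per sequenced nt.
#' @param coverage Mean sequencing coverage.
#' @param adapter_fraction Fraction of each designed fragment taken by
#'   adapters (synthesized and sequenced but carrying no data).
#' @param capacity Information capacity of the encoding, bits per
#'   non-adapter character.
#' @return An object of class `cost_model`.
#' @export
cost_model <- function(synthesis_per_nt = 0.05 / 100,
                       sequencing_per_nt = 0.0000012 / 100,
                       coverage = 250, adapter_fraction = 0.2,
                       capacity = log2(15)) {
  stopifnot(synthesis_per_nt >= 0, sequencing_per_nt >= 0, coverage >= 0,
            adapter_fraction >= 0, adapter_fraction < 1)
  if (capacity <= 0) stop("capacity must be positive")
  structure(list(synthesis_per_nt = synthesis_per_nt,
                 sequencing_per_nt = sequencing_per_nt,
                 coverage = coverage, adapter_fraction = adapter_fraction,
                 capacity = capacity),
            class = "cost_model")
}

#' Project storage cost for a data volume
#'
#' Designed nucleotides per megabyte are `(8 * 2^20 / capacity) /
#' (1 - adapter_fraction)`; writing cost is nucleotides times the synthesis
#' price, reading cost is nucleotides times coverage times the sequencing
#' price. The read/write ratio equals `coverage * sequencing_per_nt /
#' synthesis_per_nt`, independent of data volume.
#'
#' @param model A [cost_model()].
#' @param megabytes Data volume in MB (default 1).
#' @return A list with `write_dollars`, `read_dollars`, `ratio` and
#'   `designed_nt`.
#' @examples
#' project_cost(cost_model(coverage = 2000))$ratio   # 0.048 < 5%
#' @export
project_cost <- function(model, megabytes = 1) {
  nt <- megabytes * (8 * 2^20 / model$capacity) / (1 - model$adapter_fraction)
  write_d <- nt * model$synthesis_per_nt
  read_d <- nt * model$coverage * model$sequencing_per_nt
  list(write_dollars = write_d, read_dollars = read_d,
       ratio = if (write_d > 0) read_d / write_d else NA_real_,
       designed_nt = nt)
}
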
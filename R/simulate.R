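#' Monte Carlo sequencing-simulation configuration
#'
#' Models the oligonucleotide pool and its NGS readout: per-fragment read
#' counts are drawn multinomially with probabilities proportional to
#' representation weights (uneven representation from amplification bias),
#' each molecule realizes every degenerate position independently according
#' to its mixing fractions (binomial base calls), substitution errors hit
#' each base with probability `p` (uniform over the three other bases), and
#' reads whose GC fraction falls outside the bounds are discarded and
#' regenerated, emulating the low PCR yield of extreme-GC molecules.
#'
#' @param coverage Mean reads per fragment.
#' @param p Per-base substitution probability (default 0.02, the Monte Carlo
#'   setting; the empirical base-call substitution estimate is about 0.01).
#' @param representation `"lognormal"` (weights `exp(N(0, sigma))`,
#'   normalized), `"uniform"`, or `"empirical"` (supply `weights`).
#' @param sigma Lognormal spread of representation weights (default 0.5).
#' @param weights Numeric vector (recycled to the fragment count) or path to
#'   a one- or two-column TSV of per-fragment weights, for
#'   `representation = "empirical"`.
#' @param gc_bounds Length-2 GC acceptance bounds as fractions, or `NULL` to
#'   disable the filter.
#' @param max_attempts Regeneration cap per read before the GC filter is
#'   waived for that molecule (with a warning).
#' @param indel_rate Probability of one random 1-nt insertion or deletion
#'   per read (default 0; substitution-only model), giving the decoder's
#'   length filter off-length reads to discard.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(coverage, p = 0.02,
                              representation = c("lognormal", "uniform",
                                                 "empirical"),
                              sigma = 0.5, weights = NULL,
                              gc_bounds = c(0.4, 0.6), max_attempts = 50L,
                              indel_rate = 0, seed = NULL) {
  representation <- match.arg(representation)
  stopifnot(coverage > 0, p >= 0, p < 1, indel_rate >= 0, indel_rate <= 1)
  if (!is.null(gc_bounds)) {
    stopifnot(length(gc_bounds) == 2L, gc_bounds[1] >= 0,
              gc_bounds[1] < gc_bounds[2], gc_bounds[2] <= 1)
  }
  if (representation == "empirical" && is.null(weights))
    stop("empirical representation requires weights")
  structure(list(coverage = coverage, p = p, representation = representation,
                 sigma = sigma, weights = weights, gc_bounds = gc_bounds,
                 max_attempts = as.integer(max_attempts),
                 indel_rate = indel_rate, seed = seed),
            class = "simulation_config")
}

representation_weights <- function(n, config) {
  w <- switch(config$representation,
    uniform = rep(1, n),
    lognormal = if (config$sigma == 0) rep(1, n) else
      exp(stats::rnorm(n, 0, config$sigma)),
    empirical = {
      w <- config$weights
      if (is.character(w)) w <- read_weights(w)
      rep_len(as.numeric(w), n)
    })
  w / sum(w)
}

#' Read per-fragment representation weights from a TSV
#'
#' Accepts a single numeric column, or two columns (fragment index, weight).
#'
#' @param path TSV path.
#' @return Numeric weight vector.
#' @export
read_weights <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE)
  w <- if (ncol(tab) >= 2L) tab[[2L]][order(tab[[1L]])] else tab[[1L]]
  if (any(w < 0)) stop("weights must be non-negative")
  as.numeric(w)
}

#' Realize one molecule from a designed character sequence
#'
#' Each position is drawn independently according to its character's base
#' mixing fractions; pure positions are copied verbatim. `"AWC"` yields
#' `"AAC"` or `"ATC"`, each with probability one half.
#'
#' @param characters Character vector of alphabet symbols (or a single
#'   string of single-letter symbols), or integer character indices.
#' @param alphabet A [alphabet()] object.
#' @return Pure-base string.
#' @export
sample_molecule <- function(characters, alphabet) {
  idx <- resolve_symbols(characters, alphabet)
  bases <- c("A", "C", "G", "T")
  out <- vapply(idx, function(i) {
    comp <- alphabet$composition[i, ]
    sample(bases, 1L, prob = comp)
  }, character(1L))
  paste(out, collapse = "")
}

resolve_symbols <- function(characters, alphabet) {
  if (is.numeric(characters)) return(as.integer(characters))
  if (length(characters) == 1L && nchar(characters) > 1L &&
      all(nchar(alphabet$symbols) == 1L))
    characters <- strsplit(characters, "")[[1L]]
  idx <- match(characters, alphabet$symbols)
  if (anyNA(idx)) stop("unknown symbols: ",
                       paste(characters[is.na(idx)], collapse = ", "))
  idx
}

#' Simulate an NGS read pool from designed fragments
#'
#' @param fragments A [dna_fragments()] object.
#' @param config A [simulation_config()].
#' @return An object of class `read_pool`: a list with `seq` (character
#'   vector of read sequences over A/C/G/T, covering address + payload + pad;
#'   adapters are sequencing primers and are not emitted), `origin` (0-based
#'   true fragment index of each read, the simulator's hidden truth), and
#'   `read_chars` (the designed read length).
#' @export
simulate_reads <- function(fragments, config) {
  stopifnot(inherits(fragments, "dna_fragments"),
            inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- length(fragments)
  w <- representation_weights(n, config)
  total <- round(config$coverage * n)
  counts <- as.integer(stats::rmultinom(1L, total, w)[, 1L])
  dm <- design_matrix(fragments) - 1L           # 0-based for C++
  gc_filter <- !is.null(config$gc_bounds)
  res <- simulate_reads_cpp(dm, unname(fragments$alphabet$composition),
                            counts, config$p, gc_filter,
                            if (gc_filter) config$gc_bounds[1] else 0,
                            if (gc_filter) config$gc_bounds[2] else 1,
                            config$max_attempts, config$indel_rate)
  if (res$gc_fallback > 0)
    warning(res$gc_fallback, " reads emitted without GC filtering ",
            "(regeneration cap reached)")
  structure(list(seq = res$seq, origin = res$origin,
                 read_chars = fragments$geometry$read_chars,
                 gc_fallback = res$gc_fallback),
            class = "read_pool")
}

#' @export
print.read_pool <- function(x, ...) {
  cat(sprintf("<read pool: %d reads of designed length %d>\n",
              length(x$seq), x$read_chars))
  invisible(x)
}

#' @export
length.read_pool <- function(x) length(x$seq)

#' FASTQ input and output for read pools
#'
#' Writes reads as standard FASTQ with a constant placeholder quality
#' (`I`); reads them back losslessly (sequences only). `read_fastq` accepts
#' any FASTQ, e.g. real sequencer output.
#'
#' @param pool A `read_pool` (or character vector of sequences).
#' @param path FASTQ path.
#' @return `read_fastq` returns a `read_pool` (with unknown origins);
#'   `write_fastq` returns `path` invisibly.
#' @export
write_fastq <- function(pool, path) {
  seqs <- if (inherits(pool, "read_pool")) pool$seq else pool
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("read%08d", seq_along(x))
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), character(1L)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_fastq
#' @param read_chars Designed read length; taken from the most common read
#'   length when `NULL`.
#' @export
read_fastq <- function(path, read_chars = NULL) {
  if (file.exists(path) && file.size(path) == 0) {
    seqs <- character(0)              # empty input -> empty pool
  } else {
    x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                  error = function(e) stop("malformed FASTQ '", path, "': ",
                                           conditionMessage(e)))
    seqs <- as.character(unname(x))
  }
  if (is.null(read_chars))
    read_chars <- if (length(seqs) == 0L) 0L else
      as.integer(names(sort(table(nchar(seqs)), decreasing = TRUE))[1L])
  structure(list(seq = seqs, origin = rep(NA_integer_, length(seqs)),
                 read_chars = read_chars, gc_fallback = 0),
            class = "read_pool")
}

#' Write the simulator's per-read truth table
#'
#' TSV of read sequence and true originating fragment, for evaluating
#' demultiplexing and filtering against ground truth.
#'
#' @param pool A `read_pool` from [simulate_reads()].
#' @param path TSV path.
#' @export
write_truth <- function(pool, path) {
  utils::write.table(data.frame(origin = pool$origin, seq = pool$seq),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
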
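#' Filter reads by designed length
#'
#' Only reads of exactly the expected (non-adapter) length are retained;
#' indel-bearing reads fail this filter. The discarded count is recorded on
#' the returned pool.
#'
#' @param pool A `read_pool`.
#' @param expected_length Designed read length (address + payload + pad).
#' @return The filtered `read_pool` with attribute-like field `n_discarded`.
#' @export
filter_reads <- function(pool, expected_length) {
  keep <- nchar(pool$seq) == expected_length
  if (!any(keep)) stop("all reads removed by the length filter")
  out <- pool
  out$seq <- pool$seq[keep]
  out$origin <- pool$origin[keep]
  out$n_discarded <- sum(!keep)
  out$read_chars <- expected_length
  out
}

#' Demultiplex reads by fragment address
#'
#' Exact match on the address prefix: the address characters are converted
#' to a fragment index, and reads whose index is outside the design's
#' fragment range (e.g. a substitution inside the address) are discarded and
#' counted. Empty groups are legal — they become Reed-Solomon erasures.
#'
#' @param pool A `read_pool` (length-filtered).
#' @param manifest The `design_manifest`.
#' @return The pool with an added integer field `group` (0-based fragment
#'   index per read) and `n_unassigned`; discarded reads are removed.
#' @export
demultiplex <- function(pool, manifest) {
  g <- manifest_geometry(manifest)
  n_total <- manifest$n_data + manifest$n_parity
  addr <- substr(pool$seq, 1L, g$address_chars)
  idx <- suppressWarnings(strtoi(chartr("ACGT", "0123", addr), base = 4L))
  ok <- !is.na(idx) & idx < n_total
  out <- pool
  out$seq <- pool$seq[ok]
  out$origin <- pool$origin[ok]
  out$group <- idx[ok]
  out$n_unassigned <- sum(!ok)
  out
}

#' Remove duplicated reads
#'
#' Collapses exact-duplicate sequences to a single representative (reads
#' with identical sequence necessarily share an address). Mirrors the
#' duplicate-removal step applied before the base-call distribution is
#' analysed; can be skipped for depth-weighted fractions.
#'
#' @param pool A `read_pool`.
#' @return The deduplicated pool with field `n_duplicates`.
#' @export
deduplicate <- function(pool) {
  dup <- duplicated(pool$seq)
  out <- pool
  out$seq <- pool$seq[!dup]
  out$origin <- pool$origin[!dup]
  if (!is.null(pool$group)) out$group <- pool$group[!dup]
  out$n_duplicates <- sum(dup)
  out
}

#' Per-position base-call counts and fractions for one read group
#'
#' @param seqs Character vector of equal-length reads (one demultiplexed
#'   group).
#' @return A list of class `base_fraction_matrix`: `counts` and `fractions`
#'   (4 x L matrices with rows A, C, G, T) and `depth` (reads per position).
#' @export
base_fractions <- function(seqs) {
  if (length(seqs) == 0L) stop("empty read group (fragment dropout)")
  L <- nchar(seqs[1L])
  if (any(nchar(seqs) != L)) stop("reads must have equal length")
  counts <- count_bases_grouped_cpp(seqs, rep(0L, length(seqs)), 1L, L)[, , 1L]
  rownames(counts) <- c("A", "C", "G", "T")
  depth <- colSums(counts)
  frac <- sweep(counts, 2L, pmax(depth, 1L), "/")
  structure(list(counts = counts, fractions = frac, depth = depth),
            class = "base_fraction_matrix")
}

# counts for all groups at once: 4 x L x n_groups
base_count_array <- function(pool, n_groups) {
  count_bases_grouped_cpp(pool$seq, pool$group, n_groups, pool$read_chars)
}

#' Locate the error threshold at the distribution's first inflection point
#'
#' Sequencing errors produce base-call fractions concentrated near zero,
#' while intended bases cluster at their design fractions. Pooling all
#' per-position fractions, a histogram on `[0, 1]` is smoothed by a centered
#' moving average and scanned from zero for the first valley (first sign
#' change of the first difference from negative to positive); the cutoff is
#' that bin's right edge. If no valley is found below `max_cutoff`, the
#' fallback cutoff is half the alphabet's smallest design fraction.
#'
#' @param fractions Numeric vector of pooled base-call fractions (all four
#'   bases, all payload positions, all fragments).
#' @param alphabet The design [alphabet()] (sets the fallback cutoff).
#' @param bin_width Histogram bin width (default 0.01).
#' @param window Moving-average window in bins (default 5, centered).
#' @param max_cutoff Valley search limit (default 0.2).
#' @return A list of class `threshold_result`: `cutoff`, `breaks`, `counts`
#'   (raw), `smoothed`, `inflection_bin`, and `fallback` (logical).
#' @export
find_error_threshold <- function(fractions, alphabet, bin_width = 0.01,
                                 window = 5L, max_cutoff = 0.2) {
  fractions <- fractions[!is.na(fractions)]
  if (length(fractions) < 1000L)
    warning("only ", length(fractions),
            " fraction values; threshold may be unstable")
  fallback_cut <- min(alphabet$composition[alphabet$composition > 0]) / 2
  breaks <- seq(0, 1, by = bin_width)
  nb <- length(breaks) - 1L
  bin <- pmin(pmax(ceiling(fractions / bin_width), 1L), nb)
  counts <- tabulate(bin, nbins = nb)
  half <- window %/% 2L
  # fixed-width centered window, zero-padded at the edges: a truncated
  # window with an adaptive denominator would create spurious wobbles (and
  # hence false valleys) right at the error peak
  padded <- c(rep(0, half), counts, rep(0, half))
  smoothed <- vapply(seq_len(nb), function(i)
    mean(padded[i:(i + window - 1L)]), numeric(1L))
  # first valley: the error peak's descent must be followed by a confirming
  # rise (first sign change of the first difference from negative to
  # positive); the valley bin is the first minimal bin between the two, so a
  # flat stretch of the valley floor yields its left edge
  d <- diff(smoothed)
  t1 <- which(d < 0)[1L]
  inflection <- NA_integer_
  if (!is.na(t1)) {
    t2 <- which(d > 0 & seq_along(d) > t1)[1L]
    if (!is.na(t2)) {
      rng <- (t1 + 1L):t2
      inflection <- rng[which.min(smoothed[rng])]
    }
  }
  fallback <- is.na(inflection) || inflection * bin_width > max_cutoff
  if (fallback)
    warning("no histogram valley below ", max_cutoff,
            "; falling back to half the smallest design fraction (",
            signif(fallback_cut, 3), ")")
  cutoff <- if (fallback) fallback_cut else inflection * bin_width
  structure(list(cutoff = cutoff, breaks = breaks, counts = counts,
                 smoothed = smoothed, inflection_bin = inflection,
                 fallback = fallback),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<error threshold: cutoff %.3f (%s)>\n", x$cutoff,
              if (x$fallback) "fallback: half the smallest design fraction"
              else sprintf("first valley at bin %d", x$inflection_bin)))
  invisible(x)
}

#' Infer the designed encoding characters of one fragment
#'
#' Error elimination: at each position, bases whose call fraction exceeds
#' the cutoff form the intended support; the support is matched to the
#' alphabet character, with ratio variants resolved by comparing the two
#' bases' observed fractions. Positions whose support matches no character
#' (or with zero depth) are flagged as unresolved.
#'
#' @param bfm A [base_fractions()] result (or a 4 x L fraction matrix).
#' @param threshold A [find_error_threshold()] result, or a numeric cutoff.
#' @param alphabet The design [alphabet()].
#' @return A list with `indices` (integer character indices, NA where
#'   unresolved), `symbols`, and `flags` (logical, TRUE = unresolved).
#' @export
infer_characters <- function(bfm, threshold, alphabet) {
  frac <- if (inherits(bfm, "base_fraction_matrix")) bfm$fractions else bfm
  depth <- if (inherits(bfm, "base_fraction_matrix")) bfm$depth else
    rep(1L, ncol(frac))
  cutoff <- if (inherits(threshold, "threshold_result")) threshold$cutoff
            else threshold
  arr <- array(frac, dim = c(4L, ncol(frac), 1L))
  res <- infer_character_array(arr, matrix(depth, ncol = 1L), cutoff, alphabet)
  list(indices = res$indices[, 1L],
       symbols = ifelse(is.na(res$indices[, 1L]), NA_character_,
                        alphabet$symbols[res$indices[, 1L]]),
       flags = is.na(res$indices[, 1L]))
}

# vectorized inference over a 4 x L x G fraction array; depth is L x G
infer_character_array <- function(frac, depth, cutoff, alphabet) {
  L <- dim(frac)[2L]
  G <- dim(frac)[3L]
  above <- frac > cutoff
  code <- matrix(as.integer(above[1L, , ]) + 2L * above[2L, , ] +
                   4L * above[3L, , ] + 8L * above[4L, , ],
                 nrow = L, ncol = G)
  code[depth == 0L] <- 0L
  stab <- support_table(alphabet)
  idx <- matrix(NA_integer_, nrow = L, ncol = G)
  for (mask in names(stab)) {
    cand <- stab[[mask]]
    sel <- code == as.integer(mask)
    if (!any(sel)) next
    if (length(cand) == 1L) {
      idx[sel] <- cand
    } else {
      # ratio variants: two bases b1 < b2; variant with larger design
      # fraction on the base observed more often
      comp <- alphabet$composition[cand[1L], ]
      bb <- which(comp > 0)
      w <- which(sel)
      g <- (w - 1L) %/% L + 1L
      pos <- (w - 1L) %% L + 1L
      f1 <- frac[cbind(bb[1L], pos, g)]
      f2 <- frac[cbind(bb[2L], pos, g)]
      des1 <- alphabet$composition[cand[1L], bb[1L]]
      des2 <- alphabet$composition[cand[2L], bb[1L]]
      first_major <- if (des1 > des2) cand[1L] else cand[2L]
      first_minor <- if (des1 > des2) cand[2L] else cand[1L]
      idx[w] <- ifelse(f1 > f2, first_major, first_minor)
    }
  }
  list(indices = idx)
}

#' Character error rate between inferred and designed sequences
#'
#' Fraction of designed character positions whose inferred character (ratio
#' variants included) differs, computed before any Reed-Solomon correction.
#' Unresolved (NA) positions count as errors.
#'
#' @param inferred,designed Equal-size integer matrices of character
#'   indices, [dna_fragments()] objects, or symbol strings.
#' @return Mismatch fraction in `[0, 1]`.
#' @export
character_error_rate <- function(inferred, designed) {
  to_mat <- function(x) {
    if (inherits(x, "dna_fragments")) return(x$payload)
    if (is.character(x)) return(do.call(rbind, lapply(strsplit(x, ""), identity)))
    as.matrix(x)
  }
  a <- to_mat(inferred)
  b <- to_mat(designed)
  if (!all(dim(a) == dim(b))) stop("inferred and designed sizes differ")
  mean(is.na(a) | a != b)
}

#' Decode an NGS read pool back to the original bytes
#'
#' Runs the full decoding pipeline: length filter, address demultiplexing,
#' optional duplicate removal, per-position base fractions, global
#' first-inflection-point error threshold, character inference, Reed-Solomon
#' recovery of dropped or failed fragments, codon-to-bit conversion, and
#' truncation to the original byte length.
#'
#' @param pool A `read_pool` (simulated or read from FASTQ).
#' @param manifest The `design_manifest` of the encoding.
#' @param dedup Remove duplicate reads before analysing fractions
#'   (default TRUE).
#' @param truth Optional designed [dna_fragments()] for computing the
#'   pre-correction character error rate.
#' @param cutoff Optional fixed threshold overriding the automatic one.
#' @param outlier_filter Exclude reads grossly inconsistent with their own
#'   group before the final fraction analysis (default TRUE). A substitution
#'   inside the address can relabel a read with another fragment's valid
#'   address; such foreign reads share one origin and bias base fractions
#'   coherently, which no global threshold can undo. They are identified by
#'   their payload: a read whose called base falls outside its group's
#'   first-pass supported set in more than `max_mismatch` of payload
#'   positions follows a different design and is removed, and fractions and
#'   threshold are recomputed. Groups that would lose all reads keep them.
#' @param max_mismatch Mismatch-fraction limit for `outlier_filter`
#'   (default 0.15; genuine reads mismatch only via substitution errors,
#'   about `p`, while foreign reads mismatch at a large fraction of
#'   positions).
#' @return A list of class `decode_result`: `bytes` (raw vector, `NULL` on
#'   failure), `success`, and `stats` (read accounting, threshold, erasure
#'   and correction counts, and `char_error_rate` when truth is given).
#' @export
decode_pool <- function(pool, manifest, dedup = TRUE, truth = NULL,
                        cutoff = NULL, outlier_filter = TRUE,
                        max_mismatch = 0.15) {
  g <- manifest_geometry(manifest)
  al <- manifest$alphabet
  n_total <- manifest$n_data + manifest$n_parity
  stats <- list(n_reads = length(pool$seq))
  pool <- filter_reads(pool, g$read_chars)
  stats$n_length_filtered <- pool$n_discarded
  pool <- demultiplex(pool, manifest)
  stats$n_unassigned <- pool$n_unassigned
  if (dedup) {
    pool <- deduplicate(pool)
    stats$n_duplicates <- pool$n_duplicates
  }
  pay <- g$address_chars + seq_len(g$payload_chars)
  analyse <- function(pool) {
    counts <- base_count_array(pool, n_total)[, pay, , drop = FALSE]
    depth <- apply(counts, c(2L, 3L), sum)
    frac <- counts / array(rep(pmax(depth, 1L), each = 4L), dim = dim(counts))
    thr <- if (is.null(cutoff))
      find_error_threshold(as.vector(frac[, , colSums(depth) > 0L]), al)
    else structure(list(cutoff = cutoff, fallback = FALSE),
                   class = "threshold_result")
    list(depth = depth, frac = frac, thr = thr)
  }
  an <- analyse(pool)
  if (outlier_filter) {
    support <- an$frac > an$thr$cutoff
    sc <- mismatch_scores_cpp(pool$seq, pool$group, support, n_total,
                              g$payload_chars, g$address_chars)
    drop <- sc > max_mismatch * g$payload_chars
    # never empty a group: an all-outlier group is more likely low-depth
    # than entirely foreign, and an erasure would be forced either way
    emptied <- setdiff(pool$group[drop], pool$group[!drop])
    drop[pool$group %in% emptied] <- FALSE
    stats$n_outlier_reads <- sum(drop)
    if (any(drop)) {
      pool$seq <- pool$seq[!drop]
      pool$origin <- pool$origin[!drop]
      pool$group <- pool$group[!drop]
      an <- analyse(pool)
    }
  }
  depth <- an$depth
  frac <- an$frac
  thr <- an$thr
  stats$cutoff <- thr$cutoff
  inf <- infer_character_array(frac, depth, thr$cutoff, al)
  payload_t <- inf$indices                       # L x G
  group_ok <- colSums(is.na(payload_t)) == 0L & colSums(depth) > 0L
  stats$n_flagged_fragments <- sum(!group_ok)
  if (!is.null(truth)) {
    des <- t(truth$payload)                      # L x G over truth fragments
    gt <- seq_len(min(ncol(des), ncol(payload_t)))
    stats$char_error_rate <-
      mean(is.na(payload_t[, gt]) | payload_t[, gt] != des[, gt])
  }
  present <- which(group_ok) - 1L
  frags <- dna_fragments(al, g, present,
                         make_address(present, g$address_chars),
                         t(payload_t[, present + 1L, drop = FALSE]),
                         rep("data", length(present)))
  rec <- tryCatch(recover(frags, manifest),
                  dnastore_unrecoverable = function(e) e)
  if (inherits(rec, "condition")) {
    stats$failure <- conditionMessage(rec)
    return(structure(list(bytes = NULL, success = FALSE, stats = stats),
                     class = "decode_result"))
  }
  stats$rs <- rec$stats
  bytes <- tryCatch(decode_data(rec$fragments, manifest),
                    error = function(e) e)
  if (inherits(bytes, "condition")) {
    stats$failure <- conditionMessage(bytes)
    return(structure(list(bytes = NULL, success = FALSE, stats = stats),
                     class = "decode_result"))
  }
  structure(list(bytes = bytes, success = TRUE, stats = stats),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode %s: %d reads, cutoff %.3f, %d flagged fragments>\n",
              if (x$success) "OK" else "FAILED", x$stats$n_reads,
              x$stats$cutoff %||% NA, x$stats$n_flagged_fragments %||% NA))
  invisible(x)
}
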
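#' Designed DNA fragments
#'
#' Container for a set of designed fragments sharing one alphabet and
#' geometry. Payload characters are stored as integer indices into the
#' alphabet's character list; addresses are pure-base strings.
#'
#' @param alphabet A [alphabet()] object.
#' @param geometry A [fragment_geometry()] object.
#' @param index Integer vector of 0-based fragment ordinals.
#' @param address Character vector of address strings.
#' @param payload Integer matrix (fragments x payload characters) of alphabet
#'   character indices.
#' @param kind Character vector, `"data"` or `"parity"` per fragment.
#' @return An object of class `dna_fragments`.
#' @export
dna_fragments <- function(alphabet, geometry, index, address, payload, kind) {
  stopifnot(inherits(alphabet, "dna_alphabet"),
            inherits(geometry, "fragment_geometry"))
  n <- length(index)
  if (is.matrix(payload)) {
    storage.mode(payload) <- "integer"   # keep dims even when n = 0
  } else {
    payload <- matrix(as.integer(payload), nrow = n)
  }
  stopifnot(length(address) == n, nrow(payload) == n,
            ncol(payload) == geometry$payload_chars,
            all(kind %in% c("data", "parity")))
  structure(list(alphabet = alphabet, geometry = geometry,
                 index = as.integer(index), address = address,
                 payload = payload, kind = rep_len(kind, n)),
            class = "dna_fragments")
}

#' @export
print.dna_fragments <- function(x, ...) {
  cat(sprintf("<%d DNA fragments (%d data, %d parity), alphabet '%s', %d nt>\n",
              length(x$index), sum(x$kind == "data"), sum(x$kind == "parity"),
              x$alphabet$name, x$geometry$total_chars))
  invisible(x)
}

#' @export
length.dna_fragments <- function(x) length(x$index)

# pad character index per fragment: first pure base differing from the last
# payload character (keeps the character-level homopolymer rule at the pad)
pad_index <- function(fragments) {
  if (fragments$geometry$pad_chars == 0L) return(integer(0L))
  last <- fragments$payload[, ncol(fragments$payload)]
  pure <- fragments$alphabet$pure_index
  ifelse(last == pure[1L], pure[2L], pure[1L])
}

# fragments x read_chars matrix of alphabet character indices covering
# address + payload + pad (the sequenced, non-adapter region)
design_matrix <- function(fragments) {
  al <- fragments$alphabet
  g <- fragments$geometry
  n <- length(fragments$index)
  addr <- matrix(al$pure_index[unlist(strsplit(fragments$address, ""),
                                      use.names = FALSE)],
                 nrow = n, byrow = TRUE)
  m <- cbind(addr, fragments$payload)
  if (g$pad_chars > 0L) m <- cbind(m, matrix(pad_index(fragments), nrow = n,
                                             ncol = g$pad_chars))
  unname(m)
}

# character-symbol string of the non-adapter region, one per fragment
fragment_symbols <- function(fragments) {
  m <- design_matrix(fragments)
  apply(m, 1L, function(r) paste(fragments$alphabet$symbols[r], collapse = ""))
}

# IUPAC sequence of the full designed fragment (with adapters)
fragment_iupac <- function(fragments, adapters = TRUE) {
  m <- design_matrix(fragments)
  core <- apply(m, 1L, function(r)
    paste(fragments$alphabet$iupac[r], collapse = ""))
  if (adapters)
    paste0(fragments$geometry$adapter5, core, fragments$geometry$adapter3)
  else core
}

#' Write designed fragments as IUPAC FASTA
#'
#' One record per fragment (ID = 0-based index plus kind), full designed
#' sequence including adapters, degenerate positions as plain IUPAC letters.
#' Ratio variants (e.g. W1/W2) cannot be expressed in FASTA; when the
#' alphabet contains them, pass `variants_path` to also write a TSV of
#' per-fragment symbol strings from which the variants can be recovered.
#'
#' @param fragments A [dna_fragments()] object.
#' @param path Output FASTA path.
#' @param variants_path Optional TSV path for ratio-variant annotations.
#' @return `path`, invisibly.
#' @export
write_design_fasta <- function(fragments, path, variants_path = NULL) {
  seqs <- Biostrings::DNAStringSet(fragment_iupac(fragments))
  names(seqs) <- sprintf("frag%06d|%s", fragments$index, fragments$kind)
  Biostrings::writeXStringSet(seqs, path)
  if (!is.null(variants_path)) {
    utils::write.table(
      data.frame(index = fragments$index, kind = fragments$kind,
                 address = fragments$address,
                 symbols = apply(fragments$payload, 1L, function(r)
                   paste(fragments$alphabet$symbols[r], collapse = " "))),
      variants_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read designed fragments back from IUPAC FASTA
#'
#' Inverts [write_design_fasta()]. For alphabets without ratio variants the
#' FASTA alone suffices; with ratio variants, supply the variants TSV.
#'
#' @param path FASTA path written by [write_design_fasta()].
#' @param alphabet,geometry The design alphabet and geometry.
#' @param variants_path Optional variants TSV (required for `ratio21`).
#' @return A [dna_fragments()] object.
#' @export
read_design_fasta <- function(path, alphabet, geometry, variants_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- strsplit(names(seqs), "|", fixed = TRUE)
  index <- as.integer(sub("^frag", "", vapply(ids, `[[`, "", 1L)))
  kind <- vapply(ids, `[[`, "", 2L)
  s <- unname(as.character(seqs))
  a5 <- nchar(geometry$adapter5)
  core <- substr(s, a5 + 1L, a5 + geometry$read_chars)
  address <- substr(core, 1L, geometry$address_chars)
  if (!is.null(variants_path)) {
    tab <- utils::read.table(variants_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    tab <- tab[match(index, tab$index), ]
    payload <- t(vapply(strsplit(tab$symbols, " ", fixed = TRUE),
                        function(sy) match(sy, alphabet$symbols),
                        integer(geometry$payload_chars)))
  } else {
    if (anyDuplicated(alphabet$iupac))
      stop("alphabet has ratio variants; a variants file is required")
    pl <- substr(core, geometry$address_chars + 1L,
                 geometry$address_chars + geometry$payload_chars)
    payload <- t(vapply(strsplit(pl, "", fixed = TRUE),
                        function(ch) match(ch, alphabet$iupac),
                        integer(geometry$payload_chars)))
    if (anyNA(payload))
      stop("FASTA contains letters outside the alphabet's IUPAC set")
  }
  dna_fragments(alphabet, geometry, index, address, payload, kind)
}
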
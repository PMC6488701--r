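#' Build the context-dependent codon table for an alphabet
#'
#' Data are carried in three-character codons. To forbid character
#' homopolymers of four or more, a codon's first character must differ from
#' the last character of the preceding codon (the "context"); within a codon
#' runs are at most three. For an alphabet of k characters there are
#' (k-1)*k^2 admissible codons per context, so each codon carries
#' b = floor(log2((k-1)*k^2)) bits.
#'
#' The table is deterministic: for each context, admissible codons (x,y,z)
#' with x != context are enumerated in lexicographic order of character
#' indices in the alphabet's declared order, and the first 2^b are kept.
#' The same alphabet therefore yields a byte-identical table on every run
#' and platform.
#'
#' @param alphabet A [alphabet()] object with k >= 4 characters.
#' @return An object of class `codon_table` with elements `alphabet`, `b`
#'   (bits per codon), `n_admissible` (full admissible count per context),
#'   `enc` (k x 2^b integer matrix: 0-based packed codon index by context and
#'   value) and `dec` (k x k^3 integer matrix: value by context and packed
#'   codon, NA where inadmissible or unused).
#' @examples
#' tab <- build_codon_table(standard_alphabet("pure4"))
#' tab$b                     # 5 bits per codon
#' tab$n_admissible          # 48 admissible codons per context
#' @export
build_codon_table <- function(alphabet) {
  stopifnot(inherits(alphabet, "dna_alphabet"))
  k <- alphabet$k
  n_adm <- (k - 1L) * k * k
  b <- floor(log2(n_adm))
  nv <- as.integer(2^b)
  enc <- matrix(NA_integer_, nrow = k, ncol = nv)
  dec <- matrix(NA_integer_, nrow = k, ncol = k^3)
  base <- 0:(k * k - 1L)                       # all (y, z) pairs, packed
  for (ctx in seq_len(k)) {
    xs <- setdiff(seq_len(k), ctx)
    nx <- ceiling(nv / (k * k))
    codons <- as.vector(outer(base, (xs[seq_len(nx)] - 1L) * k * k, "+"))[seq_len(nv)]
    enc[ctx, ] <- codons
    dec[ctx, codons + 1L] <- 0:(nv - 1L)
  }
  structure(list(alphabet = alphabet, b = b, n_admissible = n_adm,
                 enc = enc, dec = dec),
            class = "codon_table")
}

#' @export
print.codon_table <- function(x, ...) {
  cat(sprintf("<codon table for '%s': k=%d, %d admissible/context, b=%d bits/codon>\n",
              x$alphabet$name, x$alphabet$k, x$n_admissible, x$b))
  invisible(x)
}

# packed codon index <-> character-index triple (all 0-based packing, 1-based chars)
codon_unpack <- function(cidx, k) {
  cbind(x = cidx %/% (k * k) + 1L,
        y = (cidx %/% k) %% k + 1L,
        z = cidx %% k + 1L)
}

codon_pack <- function(x, y, z, k) {
  (x - 1L) * k * k + (y - 1L) * k + (z - 1L)
}

#' Encode or decode a single codon value
#'
#' `encode_codon` maps a b-bit integer value to the codon assigned to it
#' under the given context character; `decode_codon` inverts it. These are
#' scalar convenience wrappers around the table lookups that the block
#' encoder applies in vectorized form.
#'
#' @param value Integer in `[0, 2^b)`.
#' @param context Context character: the symbol (or index) of the preceding
#'   character.
#' @param table A [build_codon_table()] object.
#' @return `encode_codon`: character vector of the three codon symbols.
#'   `decode_codon`: the integer value.
#' @export
encode_codon <- function(value, context, table) {
  ctx <- context_index(context, table$alphabet)
  value <- as.integer(value)
  if (value < 0L || value >= 2^table$b)
    stop("value ", value, " out of range [0, ", 2^table$b, ")")
  cidx <- table$enc[ctx, value + 1L]
  table$alphabet$symbols[codon_unpack(cidx, table$alphabet$k)[1L, ]]
}

#' @rdname encode_codon
#' @param codon Character vector of three symbols (or their indices).
#' @export
decode_codon <- function(codon, context, table) {
  k <- table$alphabet$k
  ctx <- context_index(context, table$alphabet)
  idx <- if (is.numeric(codon)) as.integer(codon) else
    match(codon, table$alphabet$symbols)
  if (length(idx) != 3L || anyNA(idx))
    stop("codon must be three symbols of the alphabet")
  v <- table$dec[ctx, codon_pack(idx[1L], idx[2L], idx[3L], k) + 1L]
  if (is.na(v))
    stop("invalid codon '", paste(table$alphabet$symbols[idx], collapse = ""),
         "' for context '", table$alphabet$symbols[ctx], "'")
  v
}

context_index <- function(context, alphabet) {
  ctx <- if (is.numeric(context)) as.integer(context) else
    match(context, alphabet$symbols)
  if (is.na(ctx) || ctx < 1L || ctx > alphabet$k)
    stop("context is not a character of the alphabet")
  ctx
}
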
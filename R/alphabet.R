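#' Construct an encoding character
#'
#' An encoding character is a symbol usable at a designed sequence position:
#' a pure base (A, C, G, T), an IUPAC degenerate base synthesized as an
#' equimolar nucleotide mixture, or a ratio-skewed mixed base such as
#' `W1` (A:T = 3:7). The composition gives the mixing fraction of each base
#' in the pool of synthesized molecules.
#'
#' @param symbol Character scalar naming the symbol, e.g. `"W"` or `"W1"`.
#'   Ratio variants use the IUPAC letter plus a variant index.
#' @param composition Named numeric vector over a subset of `c("A","C","G","T")`
#'   with positive fractions summing to 1.
#' @param iupac Single IUPAC letter the symbol maps to in FASTA output.
#'   Defaults to `symbol` when that is a single letter.
#' @return An object of class `encoding_character` with elements `symbol`,
#'   `iupac` and `composition` (length-4 named vector over A,C,G,T).
#' @examples
#' encoding_character("W", c(A = 0.5, T = 0.5))
#' encoding_character("W1", c(A = 0.3, T = 0.7), iupac = "W")
#' @export
encoding_character <- function(symbol, composition, iupac = NULL) {
  stopifnot(is.character(symbol), length(symbol) == 1L, nchar(symbol) >= 1L)
  bases <- c("A", "C", "G", "T")
  if (is.null(names(composition)) || !all(names(composition) %in% bases))
    stop("composition must be named with bases among A, C, G, T")
  comp <- stats::setNames(numeric(4L), bases)
  comp[names(composition)] <- as.numeric(composition)
  if (any(comp < 0)) stop("composition fractions must be non-negative")
  if (abs(sum(comp) - 1) > 1e-9)
    stop("composition fractions must sum to 1 (got ", sum(comp), ")")
  if (!any(comp > 0)) stop("composition support must be non-empty")
  if (is.null(iupac)) {
    if (nchar(symbol) != 1L)
      stop("multi-character symbols need an explicit iupac letter")
    iupac <- symbol
  }
  structure(list(symbol = symbol, iupac = iupac, composition = comp),
            class = "encoding_character")
}

#' @export
print.encoding_character <- function(x, ...) {
  sup <- names(x$composition)[x$composition > 0]
  cat(sprintf("<encoding character %s = %s>\n", x$symbol,
              paste(sprintf("%s:%g", sup, x$composition[sup]), collapse = " ")))
  invisible(x)
}

#' Construct an alphabet of encoding characters
#'
#' An alphabet is an ordered set of encoding characters. All four pure bases
#' must be present (addresses are written in pure bases) and no two
#' characters may share both support and composition.
#'
#' @param name Identifier for the alphabet.
#' @param characters List of [encoding_character()] objects, in the order used
#'   for deterministic codon-table enumeration.
#' @return An object of class `dna_alphabet` with elements `name`,
#'   `characters`, `symbols`, `k` (alphabet size) and `composition`
#'   (k x 4 matrix of mixing fractions).
#' @seealso [standard_alphabet()] for the built-in alphabets.
#' @export
alphabet <- function(name, characters) {
  stopifnot(is.character(name), length(name) == 1L, is.list(characters))
  if (!all(vapply(characters, inherits, logical(1L), "encoding_character")))
    stop("characters must all be encoding_character objects")
  k <- length(characters)
  if (k < 4L) stop("alphabet must have at least 4 characters")
  comp <- t(vapply(characters, `[[`, numeric(4L), "composition"))
  rownames(comp) <- vapply(characters, `[[`, character(1L), "symbol")
  if (anyDuplicated(rownames(comp))) stop("duplicate symbols in alphabet")
  key <- apply(round(comp, 9L), 1L, paste, collapse = "/")
  if (anyDuplicated(key))
    stop("two characters share the same support and composition")
  pure <- purity_index(comp)
  for (b in c("A", "C", "G", "T"))
    if (is.na(pure[b])) stop("alphabet must contain the pure base ", b)
  structure(list(name = name, characters = characters,
                 symbols = rownames(comp), k = k, composition = comp,
                 iupac = vapply(characters, `[[`, character(1L), "iupac"),
                 pure_index = pure),
            class = "dna_alphabet")
}

# index of the pure character for each base, NA when absent
purity_index <- function(comp) {
  bases <- c("A", "C", "G", "T")
  idx <- stats::setNames(rep(NA_integer_, 4L), bases)
  for (i in seq_len(nrow(comp))) {
    sup <- which(comp[i, ] > 0)
    if (length(sup) == 1L && abs(comp[i, sup] - 1) < 1e-9)
      idx[bases[sup]] <- i
  }
  idx
}

#' @export
print.dna_alphabet <- function(x, ...) {
  cat(sprintf("<alphabet '%s': %d encoding characters>\n", x$name, x$k))
  cat(" ", paste(x$symbols, collapse = " "), "\n")
  invisible(x)
}

# two-base IUPAC letters with their supports in alphabetical base order
.iupac2 <- list(R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))
.iupac3 <- list(B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"))

#' Built-in encoding alphabets
#'
#' Four alphabets are provided:
#' \describe{
#'   \item{`pure4`}{The four DNA bases A, C, G, T (2 bits/character
#'     theoretical capacity).}
#'   \item{`ws6`}{A, C, G, T plus the two degenerate bases W (A/T) and
#'     S (C/G) at equimolar ratios.}
#'   \item{`iupac15`}{All fifteen non-empty base combinations: the four pure
#'     bases, the six two-base degenerate bases at 1:1, the four three-base
#'     degenerate bases at equal thirds, and N at equal quarters.}
#'   \item{`ratio21`}{The pure bases, each two-base degenerate letter in two
#'     ratio variants (3:7 and 7:3, e.g. W1 = A:T 3:7 and W2 = A:T 7:3),
#'     plus B, D, H, V and N — 21 characters in total.}
#' }
#'
#' @param name One of `"pure4"`, `"ws6"`, `"iupac15"`, `"ratio21"`.
#' @return A [alphabet()] object.
#' @examples
#' standard_alphabet("iupac15")$k          # 15
#' theoretical_capacity(standard_alphabet("iupac15"))
#' @export
standard_alphabet <- function(name) {
  valid <- c("pure4", "ws6", "iupac15", "ratio21")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown alphabet '", name, "'; valid options: ",
         paste(valid, collapse = ", "))
  pure <- lapply(c("A", "C", "G", "T"), function(b)
    encoding_character(b, stats::setNames(1, b)))
  chars <- switch(name,
    pure4 = pure,
    ws6 = c(pure, list(
      encoding_character("W", c(A = 0.5, T = 0.5)),
      encoding_character("S", c(C = 0.5, G = 0.5)))),
    iupac15 = c(pure,
      lapply(names(.iupac2), function(s)
        encoding_character(s, stats::setNames(rep(0.5, 2L), .iupac2[[s]]))),
      lapply(names(.iupac3), function(s)
        encoding_character(s, stats::setNames(rep(1 / 3, 3L), .iupac3[[s]]))),
      list(encoding_character("N", c(A = .25, C = .25, G = .25, T = .25)))),
    ratio21 = c(pure,
      unlist(lapply(names(.iupac2), function(s) {
        b <- .iupac2[[s]]
        list(encoding_character(paste0(s, "1"),
                                stats::setNames(c(0.3, 0.7), b), iupac = s),
             encoding_character(paste0(s, "2"),
                                stats::setNames(c(0.7, 0.3), b), iupac = s))
      }), recursive = FALSE),
      lapply(names(.iupac3), function(s)
        encoding_character(s, stats::setNames(rep(1 / 3, 3L), .iupac3[[s]]))),
      list(encoding_character("N", c(A = .25, C = .25, G = .25, T = .25)))))
  alphabet(name, chars)
}

#' Theoretical information capacity of an alphabet
#'
#' The maximum number of bits a single designed character can carry,
#' `log2(k)` for an alphabet of `k` encoding characters. The fifteen-character
#' alphabet reaches log2(15) = 3.91 bits/character against 2.0 for plain
#' four-base DNA.
#'
#' @param alphabet A [alphabet()] object, or an integer alphabet size.
#' @return Bits per character (numeric scalar).
#' @export
theoretical_capacity <- function(alphabet) {
  k <- if (inherits(alphabet, "dna_alphabet")) alphabet$k else as.numeric(alphabet)
  if (k < 1) stop("alphabet size must be positive")
  log2(k)
}

#' Match an observed base support (and fractions) to an encoding character
#'
#' Inverts the error-elimination step of the decoder: given the set of bases
#' whose call fractions survived the error threshold, return the alphabet
#' character with exactly that support. When two ratio variants share the
#' support (e.g. W1 and W2 in `ratio21`), the observed fractions decide: the
#' base with the larger fraction is assigned the larger design ratio.
#'
#' @param support Character vector of surviving bases (subset of A,C,G,T).
#' @param fractions Optional named numeric vector of observed call fractions
#'   (required to resolve ratio variants; ignored otherwise).
#' @param alphabet A [alphabet()] object.
#' @return The matching `encoding_character`.
#' @examples
#' match_character(c("G", "T"), alphabet = standard_alphabet("iupac15"))$symbol  # "K"
#' @export
match_character <- function(support, fractions = NULL, alphabet) {
  idx <- match_character_index(support, fractions, alphabet)
  alphabet$characters[[idx]]
}

# integer-index variant used by the vectorized decoder
match_character_index <- function(support, fractions = NULL, alphabet) {
  bases <- c("A", "C", "G", "T")
  if (length(support) == 0L || !all(support %in% bases))
    stop("support must be a non-empty subset of A, C, G, T")
  want <- bases %in% support
  cand <- which(apply(alphabet$composition > 0, 1L, function(s) all(s == want)))
  if (length(cand) == 0L)
    stop("unresolvable character: no alphabet character has support {",
         paste(support, collapse = ","), "}")
  if (length(cand) == 1L) return(cand)
  # ratio variants: larger observed fraction -> larger design ratio
  if (is.null(fractions))
    stop("fractions required to resolve ratio variants for support {",
         paste(support, collapse = ","), "}")
  sup <- sort(support)
  f <- fractions[sup]
  comp <- alphabet$composition[cand, sup, drop = FALSE]
  # pick candidate whose composition ordering matches the observed ordering
  obs_major <- sup[which.max(f)]
  des_major <- sup[apply(comp, 1L, which.max)]
  hit <- cand[des_major == obs_major]
  if (length(hit) == 0L) hit <- cand[1L]
  hit[1L]
}

# support bitmask (A=1, C=2, G=4, T=8) -> candidate character indices
support_table <- function(alphabet) {
  masks <- as.integer(alphabet$composition[, "A"] > 0) +
    2L * (alphabet$composition[, "C"] > 0) +
    4L * (alphabet$composition[, "G"] > 0) +
    8L * (alphabet$composition[, "T"] > 0)
  split(seq_len(alphabet$k), masks)
}

#' Write or read an alphabet definition file
#'
#' Serializes an alphabet to a plain TSV with one line per encoding character
#' (symbol, IUPAC letter, and the four mixing fractions), so custom alphabets
#' — e.g. compositions adjusted for coupling-efficiency skew — can be
#' supplied as files.
#'
#' @param alphabet A [alphabet()] object.
#' @param path File path.
#' @return `read_alphabet` returns a [alphabet()] object;
#'   `write_alphabet` returns `path` invisibly.
#' @export
write_alphabet <- function(alphabet, path) {
  df <- data.frame(symbol = alphabet$symbols, iupac = alphabet$iupac,
                   alphabet$composition, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alphabet
#' @param name Name for the alphabet read from file (defaults to the file name).
#' @export
read_alphabet <- function(path, name = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  chars <- lapply(seq_len(nrow(df)), function(i) {
    comp <- unlist(df[i, c("A", "C", "G", "T")])
    encoding_character(df$symbol[i], comp[comp > 0], iupac = df$iupac[i])
  })
  alphabet(name %||% basename(path), chars)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
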
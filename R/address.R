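#' Fragment addresses
#'
#' Each fragment carries a short non-degenerate prefix identifying its ordinal
#' position in the data stream. Addresses are the base-4 representation of the
#' fragment index over the digit alphabet A=0, C=1, G=2, T=3, most significant
#' digit first, zero-padded to a fixed width.
#'
#' @param index Integer vector of 0-based fragment indices.
#' @param address_chars Address width in characters.
#' @return `make_address` returns a character vector of pure-base strings;
#'   `address_to_index` returns the integer indices.
#' @examples
#' make_address(0L, 3L)              # "AAA"
#' address_to_index(make_address(45L, 3L))  # 45
#' @export
make_address <- function(index, address_chars) {
  index <- as.integer(index)
  if (any(index < 0)) stop("fragment index must be non-negative")
  if (any(index >= 4^address_chars))
    stop("index ", max(index), " does not fit in ", address_chars,
         " address characters (max ", 4^address_chars - 1,
         "); use a wider address")
  bases <- c("A", "C", "G", "T")
  out <- matrix("", nrow = address_chars, ncol = length(index))
  rem <- index
  for (p in address_chars:1) {
    out[p, ] <- bases[rem %% 4L + 1L]
    rem <- rem %/% 4L
  }
  apply(out, 2L, paste, collapse = "")
}

#' @rdname make_address
#' @param address Character vector of address strings over A, C, G, T.
#' @export
address_to_index <- function(address) {
  digits <- chartr("ACGT", "0123", address)
  if (any(grepl("[^0-3]", digits)))
    stop("address contains characters other than A, C, G, T")
  strtoi(digits, base = 4L)
}
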
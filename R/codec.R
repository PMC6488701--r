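#' Encode binary data into addressed DNA fragments
#'
#' The payload bit stream is cut into fragments of `b * n_codons` bits
#' (zero-padded at the tail), each fragment's bits are split into b-bit codon
#' values, and values are mapped to three-character codons left to right.
#' The context for the first codon is the last address character; thereafter
#' each codon's context is the previous codon's last character, which
#' enforces the no-homopolymer-of-4 rule across codon boundaries.
#'
#' @param data Raw vector (the payload bytes), or a file path.
#' @param geometry A [fragment_geometry()].
#' @param table A [build_codon_table()]; or an alphabet, from which the
#'   deterministic table is built.
#' @return A list with `fragments` (a [dna_fragments()] of kind `"data"`)
#'   and `manifest` (a `design_manifest` recording everything needed to
#'   invert the encoding).
#' @examples
#' enc <- encode_data(as.raw(1:20), fragment_geometry(14, 3),
#'                    standard_alphabet("iupac15"))
#' length(enc$fragments)   # 2 fragments: ceil(160 / 154)
#' @export
encode_data <- function(data, geometry, table) {
  if (is.character(data)) data <- read_binary(data)
  stopifnot(is.raw(data), inherits(geometry, "fragment_geometry"))
  if (inherits(table, "dna_alphabet")) table <- build_codon_table(table)
  stopifnot(inherits(table, "codon_table"))
  al <- table$alphabet
  b <- table$b
  bits_per_frag <- b * geometry$n_codons
  n_frag <- ceiling(8L * length(data) / bits_per_frag)
  if (n_frag > 4^geometry$address_chars)
    stop(n_frag, " fragments exceed the ", 4^geometry$address_chars,
         "-address space; widen the address")
  values <- bits_to_values(bytes_to_bits(data), b)
  length(values) <- n_frag * geometry$n_codons
  values[is.na(values)] <- 0L
  vm <- matrix(values, nrow = n_frag, byrow = TRUE)   # fragment x codon
  index <- seq_len(n_frag) - 1L
  address <- make_address(index, geometry$address_chars)
  payload <- payload_from_values(vm, address, table)
  frags <- dna_fragments(al, geometry, index, address, payload,
                         rep("data", n_frag))
  manifest <- design_manifest(al, geometry, byte_length = length(data),
                              n_data = n_frag, b = b)
  list(fragments = frags, manifest = manifest)
}

# vectorized codon encoding: value matrix (frag x codon) -> payload index matrix
payload_from_values <- function(vm, address, table) {
  al <- table$alphabet
  k <- al$k
  n <- nrow(vm)
  nc <- ncol(vm)
  payload <- matrix(NA_integer_, nrow = n, ncol = 3L * nc)
  ctx <- al$pure_index[substr(address, nchar(address), nchar(address))]
  for (j in seq_len(nc)) {
    cidx <- table$enc[cbind(ctx, vm[, j] + 1L)]
    trip <- codon_unpack(cidx, k)
    payload[, 3L * j - 2L] <- trip[, "x"]
    payload[, 3L * j - 1L] <- trip[, "y"]
    payload[, 3L * j] <- trip[, "z"]
    ctx <- trip[, "z"]
  }
  payload
}

# inverse: payload index matrix -> value matrix, NA where the codon is not in
# the context's table (invalid codon)
values_from_payload <- function(payload, address, table) {
  al <- table$alphabet
  k <- al$k
  nc <- ncol(payload) %/% 3L
  vm <- matrix(NA_integer_, nrow = nrow(payload), ncol = nc)
  ctx <- al$pure_index[substr(address, nchar(address), nchar(address))]
  for (j in seq_len(nc)) {
    x <- payload[, 3L * j - 2L]
    y <- payload[, 3L * j - 1L]
    z <- payload[, 3L * j]
    ok <- !(is.na(x) | is.na(y) | is.na(z) | is.na(ctx))
    cidx <- ifelse(ok, codon_pack(x, y, z, k), 0L)
    v <- table$dec[cbind(ctx, cidx + 1L)]
    v[!ok] <- NA_integer_
    vm[, j] <- v
    ctx <- z
  }
  vm
}

#' Decode fragments back to the original bytes
#'
#' Inverse of [encode_data()]: all data fragments (after any Reed-Solomon
#' recovery) are decoded codon by codon, the bit stream is reassembled in
#' address order and truncated to the manifest's original byte length.
#'
#' @param fragments A [dna_fragments()] holding the data fragments.
#' @param manifest The `design_manifest` from encoding.
#' @return Raw vector of the original bytes.
#' @export
decode_data <- function(fragments, manifest) {
  table <- manifest_table(manifest)
  g <- manifest_geometry(manifest)
  keep <- fragments$kind == "data"
  idx <- fragments$index[keep]
  if (!setequal(idx, seq_len(manifest$n_data) - 1L))
    stop("missing data fragments: ",
         paste(setdiff(seq_len(manifest$n_data) - 1L, idx), collapse = ", "))
  ord <- order(idx)
  payload <- fragments$payload[keep, , drop = FALSE][ord, , drop = FALSE]
  address <- fragments$address[keep][ord]
  vm <- values_from_payload(payload, address, table)
  if (anyNA(vm)) {
    bad <- idx[ord][rowSums(is.na(vm)) > 0L]
    stop("invalid codons in fragments: ", paste(bad, collapse = ", "))
  }
  bits <- values_to_bits(as.vector(t(vm)), table$b)
  bits_to_bytes(bits, manifest$byte_length)
}

#' Information capacity and physical density report
#'
#' Information capacity is the number of stored input bits divided by the
#' total count of designed encoding characters excluding adapters (address,
#' payload and pad characters all count). Physical density is stored bytes
#' per gram of DNA, available when per-fragment molecule counts are given.
#'
#' @param input_bytes Number of payload bytes stored.
#' @param fragments A [dna_fragments()] object, or a fragment count.
#' @param geometry Required when `fragments` is a count.
#' @param molecules_per_fragment Optional molecule count (scalar or
#'   per-fragment vector) for physical density.
#' @param mass_per_nt Grams per nucleotide of single-stranded DNA
#'   (default: average 330 g/mol over Avogadro's number).
#' @return A list of class `capacity_report` with `capacity`
#'   (bits/character), `input_bits`, `designed_chars`, and `density`
#'   (bytes/gram, `NA` without molecule counts).
#' @examples
#' g <- preset_geometry("oligo85")
#' capacity_report(854, 45, g)$capacity   # 3.37 bits/character
#' @export
capacity_report <- function(input_bytes, fragments, geometry = NULL,
                            molecules_per_fragment = NULL,
                            mass_per_nt = 330 / 6.02214076e23) {
  if (inherits(fragments, "dna_fragments")) {
    geometry <- fragments$geometry
    n <- length(fragments)
  } else {
    n <- as.integer(fragments)
    if (is.null(geometry)) stop("geometry required with a fragment count")
  }
  if (n < 1L) stop("fragment list is empty")
  chars <- n * (geometry$payload_chars + geometry$address_chars +
                  geometry$pad_chars)
  if (chars == 0L) stop("zero designed characters")
  density <- NA_real_
  if (!is.null(molecules_per_fragment)) {
    mol <- rep_len(molecules_per_fragment, n)
    density <- input_bytes / (sum(mol * geometry$total_chars) * mass_per_nt)
  }
  structure(list(input_bits = 8 * input_bytes,
                 designed_chars = chars,
                 capacity = 8 * input_bytes / chars,
                 n_fragments = n,
                 density = density),
            class = "capacity_report")
}

#' @export
print.capacity_report <- function(x, ...) {
  cat(sprintf("Information capacity: %.4f bits/character (%d bits over %d characters, %d fragments)\n",
              x$capacity, x$input_bits, x$designed_chars, x$n_fragments))
  if (!is.na(x$density))
    cat(sprintf("Physical density: %.3g bytes/gram\n", x$density))
  invisible(x)
}

read_binary <- function(path) {
  readBin(path, what = "raw", n = file.info(path)$size)
}
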
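#' Fragment geometry
#'
#' Describes the layout of one designed DNA fragment:
#' `adapter5 | address | payload (3 * n_codons characters) | pad | adapter3`.
#' Adapters are fixed pure-base primer sequences used for amplification and
#' sequencing; they carry no data and are excluded from capacity accounting.
#' The optional pad is a fixed pure base appended after the last codon so
#' that geometries whose designed data region is not a multiple of three
#' (e.g. 148 nt realized as 49 codons plus one pad character) keep the
#' payload a whole number of codons.
#'
#' @param n_codons Number of three-character codons in the payload.
#' @param address_chars Address width (non-degenerate characters).
#' @param adapter5,adapter3 Fixed 5' and 3' adapter base strings (A/C/G/T).
#' @param pad_chars Number of fixed pad characters after the payload (0 or 1).
#' @return An object of class `fragment_geometry`.
#' @examples
#' fragment_geometry(14, 3)          # 85 nt total with default 20-nt adapters
#' @export
fragment_geometry <- function(n_codons, address_chars,
                              adapter5 = "ACACGACGCTCTTCCGATCT",
                              adapter3 = "AGATCGGAAGAGCACACGTC",
                              pad_chars = 0L) {
  n_codons <- as.integer(n_codons)
  address_chars <- as.integer(address_chars)
  pad_chars <- as.integer(pad_chars)
  stopifnot(n_codons >= 1L, address_chars >= 1L, pad_chars >= 0L)
  if (grepl("[^ACGT]", adapter5) || grepl("[^ACGT]", adapter3))
    stop("adapters must be pure A/C/G/T strings")
  g <- structure(list(n_codons = n_codons,
                      payload_chars = 3L * n_codons,
                      address_chars = address_chars,
                      pad_chars = pad_chars,
                      adapter5 = adapter5, adapter3 = adapter3),
                 class = "fragment_geometry")
  g$read_chars <- g$address_chars + g$payload_chars + g$pad_chars
  g$total_chars <- g$read_chars + nchar(adapter5) + nchar(adapter3)
  g
}

#' @export
print.fragment_geometry <- function(x, ...) {
  cat(sprintf(paste0("<fragment geometry: %d-char address + %d codons (%d chars)",
                     "%s + 2 adapters = %d nt>\n"),
              x$address_chars, x$n_codons, x$payload_chars,
              if (x$pad_chars) sprintf(" + %d pad", x$pad_chars) else "",
              x$total_chars))
  invisible(x)
}

#' Preset fragment geometries
#'
#' Three ready-made layouts:
#' \describe{
#'   \item{`oligo85`}{85-nt column-synthesis fragment: 3-char address,
#'     14 codons (42 payload characters), 20-nt adapters. Used with
#'     `iupac15`.}
#'   \item{`oligo160`}{160-nt pooled-synthesis fragment: 9-char address,
#'     37 codons (111 payload characters), 20-nt adapters. Used with `ws6`.}
#'   \item{`sim200`}{200-nt fragment for large-scale simulation: 12-char
#'     address, 49 codons plus one pad character (148 data characters),
#'     20-nt adapters.}
#' }
#'
#' @param name One of `"oligo85"`, `"oligo160"`, `"sim200"`.
#' @return A [fragment_geometry()] object.
#' @export
preset_geometry <- function(name) {
  switch(match.arg(name, c("oligo85", "oligo160", "sim200")),
         oligo85 = fragment_geometry(14L, 3L),
         oligo160 = fragment_geometry(37L, 9L),
         sim200 = fragment_geometry(49L, 12L, pad_chars = 1L))
}
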
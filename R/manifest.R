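#' Design manifest
#'
#' Sidecar record of everything needed to invert an encoding: alphabet,
#' geometry, original byte length, fragment counts and Reed-Solomon block
#' layout. Keeping the byte length out of the DNA stream makes the fragment
#' count exactly `ceil(8 * bytes / (b * n_codons))` plus parity.
#'
#' @param alphabet A [alphabet()] object.
#' @param geometry A [fragment_geometry()] object.
#' @param byte_length Original payload length in bytes.
#' @param n_data Number of data fragments.
#' @param b Bits per codon.
#' @param rs Optional Reed-Solomon layout (set by [add_parity()]).
#' @return An object of class `design_manifest`.
#' @export
design_manifest <- function(alphabet, geometry, byte_length, n_data, b,
                            rs = NULL) {
  structure(list(alphabet = alphabet, geometry = geometry,
                 byte_length = as.integer(byte_length),
                 n_data = as.integer(n_data),
                 n_parity = if (is.null(rs)) 0L else sum(rs$parity_rows),
                 b = as.integer(b), rs = rs, table_id = "lex-v1"),
            class = "design_manifest")
}

#' @export
print.design_manifest <- function(x, ...) {
  cat(sprintf("<design manifest: %d bytes in %d data + %d parity fragments, alphabet '%s', b=%d>\n",
              x$byte_length, x$n_data, x$n_parity, x$alphabet$name, x$b))
  invisible(x)
}

manifest_geometry <- function(manifest) manifest$geometry

manifest_table <- function(manifest) build_codon_table(manifest$alphabet)

#' Write or read a design manifest as YAML
#'
#' Standard alphabets are stored by name; custom alphabets are embedded as
#' their full composition table.
#'
#' @param manifest A [design_manifest()].
#' @param path File path.
#' @return `read_manifest` returns the `design_manifest`; `write_manifest`
#'   returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  g <- manifest$geometry
  al <- manifest$alphabet
  std <- al$name %in% c("pure4", "ws6", "iupac15", "ratio21")
  out <- list(
    alphabet = if (std) al$name else list(
      name = al$name,
      characters = lapply(al$characters, function(ch)
        list(symbol = ch$symbol, iupac = ch$iupac,
             composition = as.list(ch$composition[ch$composition > 0])))),
    geometry = list(n_codons = g$n_codons, address_chars = g$address_chars,
                    pad_chars = g$pad_chars, adapter5 = g$adapter5,
                    adapter3 = g$adapter3),
    byte_length = manifest$byte_length,
    n_data = manifest$n_data, n_parity = manifest$n_parity,
    b = manifest$b, table_id = manifest$table_id,
    rs = if (is.null(manifest$rs)) NULL else
      list(data_rows = as.integer(manifest$rs$data_rows),
           parity_rows = as.integer(manifest$rs$parity_rows)))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  al <- if (is.character(y$alphabet)) standard_alphabet(y$alphabet) else
    alphabet(y$alphabet$name, lapply(y$alphabet$characters, function(ch)
      encoding_character(ch$symbol, unlist(ch$composition), iupac = ch$iupac)))
  g <- fragment_geometry(y$geometry$n_codons, y$geometry$address_chars,
                         y$geometry$adapter5, y$geometry$adapter3,
                         y$geometry$pad_chars)
  rs <- if (is.null(y$rs)) NULL else
    list(data_rows = as.integer(y$rs$data_rows),
         parity_rows = as.integer(y$rs$parity_rows))
  design_manifest(al, g, y$byte_length, y$n_data, y$b, rs = rs)
}
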
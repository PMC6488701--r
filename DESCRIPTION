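Package: dnastore
Title: DNA Data Storage with Degenerate-Base Encoding Characters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encode arbitrary binary data into DNA sequences using augmented
    alphabets of up to 21 encoding characters, including IUPAC degenerate
    bases and ratio-skewed mixed bases, via context-dependent three-character
    codons that forbid homopolymers of four or more characters. Provides
    Reed-Solomon parity fragments over GF(2^b) for dropout recovery, a Monte
    Carlo simulator of oligonucleotide pools and sequencing readout (binomial
    base calls, uneven fragment representation, substitution errors, GC-based
    read rejection), and a statistical decoder that infers designed encoding
    characters from per-position base-call fractions using a first-inflection-
    point error threshold. Includes capacity, physical-density and
    cost-projection reports plus drivers for error-rate-versus-coverage
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
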
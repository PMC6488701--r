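# dnastore

Encode arbitrary binary data into synthesizable DNA using **degenerate-base
encoding characters**, simulate the full synthesis–sequencing–readout cycle,
and decode the data back — including Reed–Solomon recovery of lost or
corrupted fragments.

The scheme implemented here follows Choi *et al.* (2019), "High information
capacity DNA-based data storage with augmented encoding characters using
degenerate bases" (*Scientific Reports* 9:6582). The central idea: a position
in a synthesized oligo pool need not carry a single base. Mixed-base
synthesis puts a *proportion* of each nucleotide at a position, so the
effective writing alphabet can grow from `{A, C, G, T}` to the 15 IUPAC
symbols (adding e.g. `W` = A/T 50:50, `N` = 25:25:25:25), or to 21 characters
when skewed mixtures (A:T at 3:7 vs 7:3) are distinguishable. Reading is
statistical: sequence the pool deeply, tally per-position base fractions, and
match them against the known mixture compositions.

## What the package provides

- **Alphabets** — `pure4` (4 characters, 2.00 bits), `ws6` (6), `iupac15`
  (15, log2(15) ≈ 3.91 bits), and `ratio21` (21 characters including skewed
  A:T mixtures), plus user-defined alphabets.
- **Codec** — context-dependent three-character codons that structurally
  forbid homopolymer runs of four or more; `b = floor(log2((k−1)k²))` bits
  per codon (11 bits for `iupac15`); base-4 fragment addresses.
- **Redundancy** — systematic Reed–Solomon parity fragments over `GF(2^b)`,
  applied column-wise across fragments, with errors-and-erasures decoding.
- **Synthesis/sequencing simulator** — per-molecule realization of mixed
  bases (binomial base calls), lognormal fragment representation,
  substitution and indel errors, GC-content read rejection.
- **Statistical decoder** — length filter, address demultiplexing,
  deduplication, pooled base-fraction tallies, an automatic
  first-inflection-point error threshold, an outlier read filter against
  address cross-contamination, and character inference with skew-ratio
  resolution; unresolved fragments become Reed–Solomon erasures.
- **Evaluation** — information capacity and physical density reports,
  sequencing/synthesis cost projections, error-rate-versus-coverage sweeps.

## Worked example

Encode an 854-byte file with the 15-character IUPAC alphabet on 85-nt
oligos, sequence it *in silico* at 250× with 1% substitution error and
uneven fragment representation, and decode:

```r
library(dnastore)

set.seed(1)
payload <- as.raw(sample(0:255, 854, replace = TRUE))

al <- standard_alphabet("iupac15")
al
#> <alphabet 'iupac15': 15 encoding characters>
#>   A C G T R Y S W K M B D H V N

theoretical_capacity(al)
#> [1] 3.906891

enc <- encode_data(payload, preset_geometry("oligo85"), al)
enc$manifest
#> <design manifest: 854 bytes in 45 data + 0 parity fragments, alphabet 'iupac15', b=11>

capacity_report(854, enc$fragments)
#> Information capacity: 3.3738 bits/character (6832 bits over 2025 characters, 45 fragments)

cfg  <- simulation_config(250, p = 0.01, sigma = 0.5, seed = 7)
pool <- simulate_reads(enc$fragments, cfg)
length(pool$seq)
#> [1] 11250
substr(pool$seq[1], 1, 45)       # one realized read: pure bases only
#> [1] "AAACCCCAGCCCGCTTATATTCCTCTTCTGACGAGTTATTTTCAT"

res <- decode_pool(pool, enc$manifest)
res
#> <decode OK: 11250 reads, cutoff 0.060, 0 flagged fragments>
identical(res$bytes, payload)
#> [1] TRUE
```

Add dropout protection with Reed–Solomon parity fragments:

```r
enc <- add_parity(enc, redundancy_config(r = 0.10))
```

A thin command-line interface covering the same pipeline
(`encode`, `simulate`, `decode`, `sweep`, `cost`) is installed at
`system.file("exec", "dnastore", package = "dnastore")`.

## Running the tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "dnastore", load_package = "installed")'
```

One acceptance-style test ("ten simulated sequencing runs at 250x …") is
intentionally strict: it demands 10/10 exact recoveries over a fixed seed
set, while the measured per-run success rate at those settings is ≈99.3%
(a ~3σ binomial dip at one low-coverage fragment makes one of the ten fixed
runs miss by a single character). The seeds were chosen before the outcome
was known and are kept as documentation of that failure mode.

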
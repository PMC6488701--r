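---
title: "Methods: DNA data storage with degenerate-base encoding characters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA data storage with degenerate-base encoding characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnastore)
```

This vignette records the model, the algorithmic choices and the numerical
conventions behind `dnastore`, an implementation of the degenerate-base
storage scheme of Choi *et al.* (2019, *Scientific Reports* 9:6582).

## 1. Encoding characters

A synthesized position in an oligo pool is a *mixture* of nucleotides. An
**encoding character** is a named composition vector over `(A, C, G, T)`:
`A` is `(1,0,0,0)`, the IUPAC symbol `W` is `(0.5,0,0,0.5)`, `N` is uniform.
Four standard alphabets are built in:

| alphabet  | k  | bits/char (log2 k) | contents |
|-----------|----|--------------------|----------|
| `pure4`   | 4  | 2.000 | A, C, G, T |
| `ws6`     | 6  | 2.585 | pure bases + W, S |
| `iupac15` | 15 | 3.907 | all IUPAC symbols except the gap |
| `ratio21` | 21 | 4.392 | `iupac15` + skewed two-base mixtures |

`ratio21` splits each two-base IUPAC symbol into 3:7 and 7:3 variants
(e.g. `W1` = A:T 3:7, `W2` = A:T 7:3). Variant numbering is a package
convention: variant 1 is the one in which the alphabetically first base is
the minority. Because both variants share one IUPAC letter, designs written
as FASTA need a sidecar variants table (`write_design_fasta(variants_path=)`).

## 2. Codons, homopolymer safety, addresses

Data is carried by **three-character codons** chosen context-dependently:
the first character of a codon must differ from the last character of the
preceding codon. This structurally guarantees that no designed sequence
contains a run of four identical characters, with no screening step. For an
alphabet of size `k` there are `(k−1)k²` admissible codons per context, so a
codon carries

```
b = floor(log2((k−1) k²))   bits
```

— 5, 7, 11 and 13 bits for the four standard alphabets. The value-to-codon
table is deterministic: admissible codons are enumerated in lexicographic
order per context (`table_id: lex-v1` in the manifest), and the first `2^b`
are used. Fragment addresses are plain base-4 numerals over `(A,C,G,T)`,
most significant digit first; the address also supplies the context for the
first payload codon. The byte stream is bit-packed MSB-first into `b`-bit
codon values; the original byte length is stored in the manifest rather than
in-band.

Geometries are package conventions chosen to match the published oligo
layouts: `oligo85` (3-char address + 14 codons, 85 nt with adapters),
`oligo160` (9 + 37×3), and `sim200` (12-char address, 49 codons and one pad
character) for large simulations.

## 3. Reed–Solomon redundancy

Fragment dropout is the dominant loss mode. `add_parity()` appends parity
*fragments*: codon values are treated as symbols of `GF(2^b)` and each codon
*column* is encoded with a systematic Reed–Solomon code down the fragment
axis. When the fragment count exceeds the field bound `2^b − 1`, fragments
are split evenly into blocks, each within the bound, and the requested
parity is distributed proportionally. Decoding uses errors-and-erasures
Berlekamp–Massey (first consecutive root = 1): `e` erasures and `t` unknown
errors are corrected whenever `e + 2t ≤` parity count. Fragments that the
statistical decoder could not resolve enter as erasures, so parity absorbs
both dropout and residual inference failures. A recovery beyond capability
raises a typed condition (`dnastore_unrecoverable`).

## 4. Readout simulator

`simulate_reads()` draws, for a requested mean coverage `c` over `n`
fragments:

1. per-fragment weights — lognormal with spread `sigma` (σ = 0 gives even
   representation; empirical weight files are also accepted), normalized and
   fed to one multinomial draw of `c·n` reads;
2. per-read molecule realization — every degenerate position is an
   independent categorical draw from the character's composition (this is
   what makes readout of mixed bases binomial);
3. substitution errors at rate `p` per position, optional indels;
4. GC-content rejection: reads outside the window (default 0.40–0.60) are
   redrawn, with a capped number of attempts (50) after which the read is
   emitted unfiltered and a warning is raised — a deliberate guard against
   designs whose composition makes the window unsatisfiable.

All randomness flows through R's RNG, so `seed` makes pools byte-identical.

## 5. Statistical decoding

`decode_pool()` runs: exact-length filter → exact-address demultiplexing
(reads whose address falls outside the design are dropped and counted) →
optional deduplication → per-fragment, per-position base counts → pooled
payload base fractions.

**Error threshold.** True mixture fractions live at or above the smallest
design fraction (0.25 for `iupac15`, 0.3 for `ratio21`); substitution noise
produces a spike of small fractions near zero. The cutoff separating them is
found from a histogram of all pooled fractions (bin width 0.01): the counts
are smoothed with a fixed-width centered moving average (window 5,
zero-padded at the boundaries — adaptive denominators at the edges create
spurious boundary valleys), and the cutoff is the right edge of the first
smoothed minimum that is both preceded by a descent and confirmed by a
subsequent rise, searched below a cap of 0.2. If no confirmed valley exists
the cutoff falls back to half the smallest design fraction, with a warning.

**Outlier read filter.** A single substitution inside an address often turns
it into *another valid address* (the address space is dense), so a coherent
block of one fragment's reads can contaminate a neighbor. Such blocks
produce spurious fractions around 0.05–0.15 in shallow groups — too high to
ignore, too low for any global cutoff. The decoder therefore makes a first
inference pass, computes each read's mismatch count against its group's
supported bases, and discards reads mismatching at more than 15% of payload
positions: genuine reads mismatch their own group at roughly the
substitution rate, foreign reads at 25–40%, so the two populations are far
apart and the exact threshold is uncritical. A group is never emptied — an
all-outlier group is more plausibly low-depth than entirely foreign.
Fractions and the threshold are then recomputed on the cleaned pool.

**Character calls.** At each position the supported base set (fractions
above the cutoff) is matched against the alphabet's support table; for
skew alphabets, two-base supports are resolved to a 3:7 or 7:3 variant by
which base is the minority. Positions with no match, and empty groups,
flag the fragment; flagged fragments become Reed–Solomon erasures.

## 6. Capacity, density, cost

`capacity_report()` computes realized information capacity as
`8·bytes / total designed characters` (address, payload and pad included):
3.37 bits/character for the 854-byte demonstration (45 fragments of 45
characters), 2.00 for the 135,393-byte `ws6` configuration (4183 data +
320 parity fragments of 120 characters). `cost_model()` captures the
economic argument for deep readout: at the default per-nt prices the cost
of sequencing at 2000× coverage is still only 4.8% of synthesis.

## 7. Numerical conventions and limitations

- Histogram bin 0.01, smoothing window 5, valley cap 0.2, outlier mismatch
  threshold 0.15: fixed constants, not fitted values; sensitivity to all of
  them is low because the quantities they threshold are well separated.
- Demultiplexing is exact-match only; reads with address errors are lost
  (or, rarely, cross-assigned — which the outlier filter handles). An
  alignment-based assigner would recover more reads but is out of scope.
- Indels are simulated but not corrected: off-length reads are simply
  filtered. The published scheme likewise relies on length filtering.
- At shallow depth (tens of reads per fragment) a true 0.25 fraction can
  drift below the cutoff by sampling noise alone (~3σ); without parity this
  can silently substitute one valid character for another. Measured per-run
  failure probability at the demonstration settings is ≈0.7%; Reed–Solomon
  parity eliminates it as a practical concern.
- `ratio21`'s skew resolution needs enough depth to tell 3:7 from 7:3
  (≈40+ reads); below that, variant flips are the dominant error mode.
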
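#include <Rcpp.h>
using namespace Rcpp;

// Monte Carlo readout of a degenerate-base fragment pool.
//
// design: n_fragments x L matrix of 0-based alphabet character indices over
//         the sequenced (non-adapter) region.
// comp:   k x 4 matrix of per-character base mixing fractions (A,C,G,T).
// counts: reads to emit per fragment.
// p:      per-base substitution probability (error to a uniform other base).
// gc_lo/gc_hi: GC-content acceptance bounds; reads outside are regenerated
//         (PCR-yield emulation). gc_filter = false disables rejection.
// max_attempts: regeneration cap per read; on exhaustion the last draw is
//         kept and counted in gc_fallback.
// indel_rate: probability a read receives one random 1-nt insertion or
//         deletion after acceptance (so the length filter has work to do).
//
// Uses R's RNG so results are reproducible from set.seed().
// [[Rcpp::export]]
List simulate_reads_cpp(IntegerMatrix design, NumericMatrix comp,
                        IntegerVector counts, double p,
                        bool gc_filter, double gc_lo, double gc_hi,
                        int max_attempts, double indel_rate) {
  const int nfrag = design.nrow();
  const int L = design.ncol();
  const int k = comp.nrow();
  static const char BASES[5] = "ACGT";

  // cumulative composition per character, and pure shortcut
  std::vector<double> cum(k * 4);
  std::vector<int> pure(k, -1);
  for (int c = 0; c < k; ++c) {
    double acc = 0.0;
    int nz = 0, last = 0;
    for (int b = 0; b < 4; ++b) {
      acc += comp(c, b);
      cum[c * 4 + b] = acc;
      if (comp(c, b) > 0) { nz++; last = b; }
    }
    if (nz == 1) pure[c] = last;
  }

  long total = 0;
  for (int f = 0; f < nfrag; ++f) total += counts[f];
  CharacterVector seqs(total);
  IntegerVector origin(total);
  long gc_fallback = 0;

  std::string buf(L, 'A');
  std::vector<int> bases(L);
  long r = 0;
  for (int f = 0; f < nfrag; ++f) {
    for (int c = 0; c < counts[f]; ++c) {
      bool accepted = false;
      for (int attempt = 0; attempt < max_attempts && !accepted; ++attempt) {
        int gc = 0;
        for (int pos = 0; pos < L; ++pos) {
          int ch = design(f, pos);
          int b;
          if (pure[ch] >= 0) {
            b = pure[ch];
          } else {
            double u = unif_rand();
            const double* cc = &cum[ch * 4];
            b = (u < cc[0]) ? 0 : (u < cc[1]) ? 1 : (u < cc[2]) ? 2 : 3;
          }
          if (p > 0 && unif_rand() < p) {
            int shift = 1 + (int)(unif_rand() * 3.0);
            if (shift > 3) shift = 3;
            b = (b + shift) % 4;
          }
          if (b == 1 || b == 2) gc++;
          bases[pos] = b;
        }
        double frac = (double)gc / L;
        if (!gc_filter || (frac >= gc_lo && frac <= gc_hi)) {
          accepted = true;
        } else if (attempt == max_attempts - 1) {
          gc_fallback++;  // design cannot satisfy the bounds; keep last draw
        }
      }
      for (int pos = 0; pos < L; ++pos) buf[pos] = BASES[bases[pos]];
      if (indel_rate > 0 && unif_rand() < indel_rate) {
        int pos = (int)(unif_rand() * L);
        if (pos >= L) pos = L - 1;
        if (unif_rand() < 0.5) {
          std::string t = buf; t.erase(pos, 1); seqs[r] = t;
        } else {
          int nb = (int)(unif_rand() * 4.0); if (nb > 3) nb = 3;
          std::string t = buf; t.insert(pos, 1, BASES[nb]); seqs[r] = t;
        }
      } else {
        seqs[r] = buf;
      }
      origin[r] = f;
      ++r;
    }
  }
  return List::create(_["seq"] = seqs, _["origin"] = origin,
                      _["gc_fallback"] = (double)gc_fallback);
}

// Per-read mismatch counts against each group's supported base sets.
//
// support: 4 x L x n_groups logical array (TRUE = base above the error
//          threshold at that payload position of that group).
// offset:  0-based start of the payload within each read (address width).
// L:       number of payload positions scored.
// A read's score is the number of payload positions whose called base is
// not in its group's support set; reads from a foreign fragment (address
// errors mapping onto a valid address) score high because their payload
// follows another design. Reads with group < 0 or unexpected length get -1.
// [[Rcpp::export]]
IntegerVector mismatch_scores_cpp(CharacterVector seqs, IntegerVector group,
                                  LogicalVector support, int n_groups,
                                  int L, int offset) {
  IntegerVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    int g = group[i];
    const char* s = CHAR(STRING_ELT(seqs, i));
    if (g < 0 || g >= n_groups || (int)std::strlen(s) < offset + L) {
      out[i] = -1;
      continue;
    }
    int base = 4 * L * g;
    int score = 0;
    for (int pos = 0; pos < L; ++pos) {
      int b;
      switch (s[offset + pos]) {
        case 'A': b = 0; break;
        case 'C': b = 1; break;
        case 'G': b = 2; break;
        case 'T': b = 3; break;
        default: score++; continue;
      }
      if (!support[base + 4 * pos + b]) score++;
    }
    out[i] = score;
  }
  return out;
}

// Per-position base counts for reads grouped by fragment.
// Returns a 4 x L x n_groups integer array (A,C,G,T rows). Reads whose
// length differs from L, or with group < 0, are skipped.
// [[Rcpp::export]]
IntegerVector count_bases_grouped_cpp(CharacterVector seqs,
                                      IntegerVector group,
                                      int n_groups, int L) {
  IntegerVector out(4 * L * n_groups);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    int g = group[i];
    if (g < 0 || g >= n_groups) continue;
    const char* s = CHAR(STRING_ELT(seqs, i));
    if ((int)std::strlen(s) != L) continue;
    int base = 4 * L * g;
    for (int pos = 0; pos < L; ++pos) {
      int b;
      switch (s[pos]) {
        case 'A': b = 0; break;
        case 'C': b = 1; break;
        case 'G': b = 2; break;
        case 'T': b = 3; break;
        default: continue;
      }
      out[base + 4 * pos + b]++;
    }
  }
  out.attr("dim") = IntegerVector::create(4, L, n_groups);
  return out;
}
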
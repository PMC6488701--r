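# Arithmetic over GF(2^m) via log/antilog tables. Codon values act as field
# symbols, so m is the codec's bits-per-codon b (5, 7, 11 or 13).
# Primitive polynomials (order of x verified to be 2^m - 1):
#   m=5: x^5+x^2+1, m=7: x^7+x^3+1, m=11: x^11+x^2+1, m=13: x^13+x^4+x^3+x+1

.gf_primpoly <- c(`5` = 0x25L, `7` = 0x89L, `11` = 0x805L, `13` = 0x201BL)

.gf_cache <- new.env(parent = emptyenv())

gf_field <- function(m) {
  key <- as.character(m)
  if (!is.null(.gf_cache[[key]])) return(.gf_cache[[key]])
  if (!key %in% names(.gf_primpoly))
    stop("no primitive polynomial registered for GF(2^", m, ")")
  poly <- .gf_primpoly[[key]]
  q <- as.integer(2^m)
  exp <- integer(2L * (q - 1L))
  log <- integer(q)                     # log[a + 1]; log of 0 unused
  a <- 1L
  for (i in 0:(q - 2L)) {
    exp[i + 1L] <- a
    log[a + 1L] <- i
    a <- bitwShiftL(a, 1L)
    if (bitwAnd(a, q) != 0L) a <- bitwXor(a, poly)
  }
  exp[q:(2L * (q - 1L))] <- exp[seq_len(q - 1L)]   # wrap so mul needs no mod
  f <- list(m = m, q = q, poly = poly, exp = exp, log = log)
  .gf_cache[[key]] <- f
  f
}

# all vectorized; 0 handled explicitly since log(0) is undefined
gf_mul <- function(f, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.integer(a), n)
  b <- rep_len(as.integer(b), n)
  r <- integer(n)
  z <- a == 0L | b == 0L
  if (!all(z))
    r[!z] <- f$exp[(f$log[a[!z] + 1L] + f$log[b[!z] + 1L]) + 1L]
  r
}

gf_inv <- function(f, a) {
  if (any(a == 0L)) stop("division by zero in GF(2^m)")
  f$exp[(f$q - 1L - f$log[a + 1L]) %% (f$q - 1L) + 1L]
}

gf_div <- function(f, a, b) gf_mul(f, a, gf_inv(f, b))

gf_pow_alpha <- function(f, e) f$exp[(e %% (f$q - 1L)) + 1L]   # alpha^e

# --- polynomials, ascending coefficient order (coef of x^0 first) ---

gf_poly_mul <- function(f, p, q) {
  r <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    seg <- i:(i + length(q) - 1L)
    r[seg] <- bitwXor(r[seg], gf_mul(f, rep(p[i], length(q)), q))
  }
  r
}

# evaluate polynomial at a single point (Horner, ascending order)
gf_poly_eval <- function(f, p, x) {
  acc <- 0L
  for (i in rev(seq_along(p))) acc <- bitwXor(gf_mul(f, acc, x), p[i])
  acc
}

# formal derivative over GF(2): odd-power coefficients shift down
gf_poly_deriv <- function(p) {
  if (length(p) <= 1L) return(0L)
  d <- p[-1L]
  d[seq_along(d) %% 2L == 0L] <- 0L
  d
}
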
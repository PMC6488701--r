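#' Reed-Solomon redundancy configuration
#'
#' Parity is computed column-wise over codon values: fragments are grouped
#' into blocks, and for each codon column the block's values form a
#' Reed-Solomon codeword over GF(2^b), whose parity symbols become the parity
#' fragments' codons. Parity fragments are re-encoded through the codon table
#' and obey the same homopolymer rule as data fragments.
#'
#' @param r Parity fraction in `[0, 1)`; total parity count is
#'   `ceil(r * n_data)`. Ignored when `parity_count` is given.
#' @param parity_count Explicit total parity fragment count.
#' @return An object of class `redundancy_config`.
#' @examples
#' redundancy_config(r = 0.10)
#' @export
redundancy_config <- function(r = 0.10, parity_count = NULL) {
  if (is.null(parity_count)) {
    stopifnot(r >= 0, r < 1)
  } else {
    parity_count <- as.integer(parity_count)
    stopifnot(parity_count >= 0L)
  }
  structure(list(r = r, parity_count = parity_count),
            class = "redundancy_config")
}

# distribute n items over nb groups as evenly as possible
even_split <- function(n, nb) {
  base <- n %/% nb
  extra <- n %% nb
  as.integer(rep(base, nb) + (seq_len(nb) <= extra))
}

# block layout: total parity from config; blocks sized within the field limit
rs_layout <- function(n_data, config, b) {
  p_total <- if (!is.null(config$parity_count)) config$parity_count else
    as.integer(ceiling(config$r * n_data))
  if (p_total == 0L)
    return(list(data_rows = n_data, parity_rows = 0L))
  nmax <- as.integer(2^b - 1L)
  n_blocks <- ceiling((n_data + p_total) / nmax)
  if (p_total %/% n_blocks >= nmax)
    stop("parity count exceeds the GF(2^", b, ") codeword limit")
  list(data_rows = even_split(n_data, n_blocks),
       parity_rows = even_split(p_total, n_blocks))
}

#' Add Reed-Solomon parity fragments
#'
#' Groups the data fragments into blocks (block length bounded by the
#' GF(2^b) codeword limit `2^b - 1`), computes parity symbols per codon
#' column, and appends parity fragments with addresses continuing after the
#' data. The manifest is updated with the block layout so the decoder can
#' locate codewords.
#'
#' @param encoded A list with `fragments` and `manifest` as returned by
#'   [encode_data()].
#' @param config A [redundancy_config()].
#' @return A list with `fragments` (data + parity) and the updated
#'   `manifest`.
#' @export
add_parity <- function(encoded, config) {
  frags <- encoded$fragments
  manifest <- encoded$manifest
  stopifnot(inherits(frags, "dna_fragments"),
            inherits(config, "redundancy_config"),
            all(frags$kind == "data"))
  table <- manifest_table(manifest)
  b <- table$b
  n_data <- length(frags)
  layout <- rs_layout(n_data, config, b)
  p_total <- sum(layout$parity_rows)
  if (p_total == 0L) return(list(fragments = frags, manifest = manifest))
  g <- frags$geometry
  if (n_data + p_total > 4^g$address_chars)
    stop("parity fragments exceed the address space; widen the address")
  f <- gf_field(b)
  vm <- values_from_payload(frags$payload, frags$address, table)
  stopifnot(!anyNA(vm))
  parity_vm <- matrix(NA_integer_, nrow = p_total, ncol = g$n_codons)
  d_off <- c(0L, cumsum(layout$data_rows))
  p_off <- c(0L, cumsum(layout$parity_rows))
  for (blk in seq_along(layout$data_rows)) {
    drows <- (d_off[blk] + 1L):d_off[blk + 1L]
    prow <- layout$parity_rows[blk]
    if (prow == 0L) next
    parity_vm[(p_off[blk] + 1L):p_off[blk + 1L], ] <-
      rs_encode_columns(f, vm[drows, , drop = FALSE], prow)
  }
  p_index <- n_data:(n_data + p_total - 1L)
  p_address <- make_address(p_index, g$address_chars)
  p_payload <- payload_from_values(parity_vm, p_address, table)
  all_frags <- dna_fragments(
    frags$alphabet, g,
    index = c(frags$index, p_index),
    address = c(frags$address, p_address),
    payload = rbind(frags$payload, p_payload),
    kind = c(frags$kind, rep("parity", p_total)))
  manifest$rs <- layout
  manifest$n_parity <- p_total
  list(fragments = all_frags, manifest = manifest)
}

# generator polynomial with roots alpha^0 .. alpha^(P-1), ascending coeffs
rs_generator <- function(f, P) {
  g <- 1L
  for (i in 0:(P - 1L)) g <- gf_poly_mul(f, g, c(gf_pow_alpha(f, i), 1L))
  g
}

# systematic encoding of all columns of a message matrix (rows = symbols in
# codeword order, first row = highest power); returns P x C parity matrix
rs_encode_columns <- function(f, msg, P) {
  C <- ncol(msg)
  g <- rs_generator(f, P)            # length P+1, monic
  gc <- rev(g[seq_len(P)])           # g_{P-1} .. g_0
  reg <- matrix(0L, nrow = P, ncol = C)
  for (i in seq_len(nrow(msg))) {
    fb <- bitwXor(msg[i, ], reg[1L, ])
    nz <- fb != 0L
    shifted <- rbind(reg[-1L, , drop = FALSE], 0L)
    if (any(nz)) {
      add <- matrix(0L, nrow = P, ncol = C)
      add[, nz] <- matrix(
        f$exp[(rep(f$log[fb[nz] + 1L], each = P) +
                 ifelse(gc == 0L, NA_integer_, f$log[gc + 1L])) + 1L],
        nrow = P)
      add[is.na(add)] <- 0L
      reg <- matrix(bitwXor(shifted, add), nrow = P)
    } else reg <- shifted
  }
  reg
}

# syndromes S_i = r(alpha^i), i = 0..P-1, for every column of a received
# matrix (rows = codeword symbols, first row = highest power)
rs_syndromes <- function(f, rec, P) {
  C <- ncol(rec)
  S <- matrix(0L, nrow = P, ncol = C)
  for (i in 0:(P - 1L)) {
    a <- gf_pow_alpha(f, i)
    acc <- integer(C)
    for (j in seq_len(nrow(rec)))
      acc <- bitwXor(gf_mul(f, acc, a), rec[j, ])
    S[i + 1L, ] <- acc
  }
  S
}

# Berlekamp-Massey on (modified) syndromes; returns error locator (ascending)
rs_berlekamp_massey <- function(f, S) {
  C_ <- 1L; B <- 1L; L <- 0L; m <- 1L; b <- 1L
  n <- length(S)
  for (i in seq_len(n)) {
    d <- S[i]
    if (L > 0L)
      for (j in seq_len(min(L, length(C_) - 1L)))
        d <- bitwXor(d, gf_mul(f, C_[j + 1L], S[i - j]))
    if (d == 0L) {
      m <- m + 1L
    } else if (2L * L <= i - 1L) {
      Told <- C_
      coef <- gf_div(f, d, b)
      shiftB <- c(integer(m), gf_mul(f, rep(coef, length(B)), B))
      len <- max(length(C_), length(shiftB))
      C_ <- bitwXor(c(C_, integer(len - length(C_))),
                    c(shiftB, integer(len - length(shiftB))))
      L <- i - L
      B <- Told
      b <- d
      m <- 1L
    } else {
      coef <- gf_div(f, d, b)
      shiftB <- c(integer(m), gf_mul(f, rep(coef, length(B)), B))
      len <- max(length(C_), length(shiftB))
      C_ <- bitwXor(c(C_, integer(len - length(C_))),
                    c(shiftB, integer(len - length(shiftB))))
      m <- m + 1L
    }
  }
  # trim trailing zeros
  while (length(C_) > 1L && C_[length(C_)] == 0L) C_ <- C_[-length(C_)]
  list(lambda = C_, L = L)
}

# syndromes of a sparse error pattern: positions (1-based rows) + magnitudes,
# S_i = sum_j mag_j * alpha^(i*(n-j)); used to verify corrections cheaply
rs_sparse_syndromes <- function(f, n, P, pos, mag) {
  S <- matrix(0L, nrow = P, ncol = if (is.matrix(mag)) ncol(mag) else 1L)
  if (!is.matrix(mag)) mag <- matrix(mag, ncol = 1L)
  for (i in 0:(P - 1L)) {
    acc <- integer(ncol(mag))
    for (t in seq_along(pos)) {
      w <- gf_pow_alpha(f, i * (n - pos[t]))
      acc <- bitwXor(acc, gf_mul(f, mag[t, ], w))
    }
    S[i + 1L, ] <- acc
  }
  S
}

# erasure locator polynomial Gamma(x) = prod (1 - X_e x), ascending coeffs
rs_erasure_locator <- function(f, n, erasures) {
  gamma <- 1L
  for (j in erasures) gamma <- gf_poly_mul(f, gamma, c(1L, gf_pow_alpha(f, n - j)))
  gamma
}

# polynomial-times-syndrome-matrix product truncated mod x^P:
# p is a polynomial (ascending), S a P x C syndrome matrix per column
rs_poly_times_S <- function(f, p, S, P) {
  C <- ncol(S)
  out <- matrix(0L, nrow = P, ncol = C)
  for (i in seq_along(p)) {
    if (i > P) break
    if (p[i] == 0L) next
    rows <- i:P
    out[rows, ] <- bitwXor(out[rows, , drop = FALSE],
                           gf_mul(f, p[i], S[seq_len(P - i + 1L), , drop = FALSE]))
  }
  out
}

# evaluate a coefficient matrix (rows = ascending coefficients, one polynomial
# per column) at a scalar point
rs_eval_columns <- function(f, M, x) {
  acc <- integer(ncol(M))
  for (i in rev(seq_len(nrow(M)))) acc <- bitwXor(gf_mul(f, acc, x), M[i, ])
  acc
}

# erasure-only correction applied to every column at once; returns the
# magnitude matrix (|erasures| x C) -- caller verifies and falls back to the
# per-column errors-and-erasures path where verification fails
rs_erasure_magnitudes <- function(f, S, n, erasures) {
  psi <- rs_erasure_locator(f, n, erasures)
  P <- nrow(S)
  omega <- rs_poly_times_S(f, psi, S, P)
  dpsi <- gf_poly_deriv(psi)
  mag <- matrix(0L, nrow = length(erasures), ncol = ncol(S))
  for (t in seq_along(erasures)) {
    j <- erasures[t]
    xinv <- gf_pow_alpha(f, -(n - j))
    xj <- gf_pow_alpha(f, n - j)
    denom <- gf_poly_eval(f, dpsi, xinv)
    if (denom == 0L) return(NULL)
    num <- rs_eval_columns(f, omega, xinv)
    mag[t, ] <- gf_mul(f, xj, gf_div(f, num, rep(denom, length(num))))
  }
  mag
}

# full errors-and-erasures correction for one column given its syndromes;
# returns list(pos, mag) or NULL when the capability is exceeded
rs_correct_column <- function(f, S, n, P, erasures) {
  E <- length(erasures)
  if (E > P) return(NULL)
  gamma <- rs_erasure_locator(f, n, erasures)
  xi <- gf_poly_mul(f, gamma, S)[seq_len(P)]
  bm <- rs_berlekamp_massey(f, if (E < P) xi[(E + 1L):P] else integer(0L))
  if (2L * bm$L > P - E) return(NULL)
  psi <- gf_poly_mul(f, bm$lambda, gamma)
  pos <- erasures
  if (bm$L > 0L) {                       # Chien search for the unknown errors
    err_pos <- integer(0L)
    for (j in setdiff(seq_len(n), erasures)) {
      xinv <- gf_pow_alpha(f, -(n - j))
      if (gf_poly_eval(f, bm$lambda, xinv) == 0L) err_pos <- c(err_pos, j)
    }
    if (length(err_pos) != length(bm$lambda) - 1L) return(NULL)
    pos <- c(erasures, err_pos)
  }
  if (length(pos) == 0L) return(list(pos = integer(0L), mag = integer(0L)))
  omega <- gf_poly_mul(f, psi, S)[seq_len(P)]
  dpsi <- gf_poly_deriv(psi)
  mag <- integer(length(pos))
  for (t in seq_along(pos)) {
    j <- pos[t]
    xinv <- gf_pow_alpha(f, -(n - j))
    denom <- gf_poly_eval(f, dpsi, xinv)
    if (denom == 0L) return(NULL)
    mag[t] <- gf_mul(f, gf_pow_alpha(f, n - j),
                     gf_div(f, gf_poly_eval(f, omega, xinv), denom))
  }
  # verify: syndromes of the correction must cancel the received syndromes
  fix <- rs_sparse_syndromes(f, n, P, pos, matrix(mag, ncol = 1L))
  if (any(bitwXor(fix[, 1L], S) != 0L)) return(NULL)
  list(pos = pos, mag = mag)
}

# decode all columns of one block; rec rows = codeword symbols (data then
# parity, first row = highest power); era = 1-based erased row indices
rs_decode_block <- function(f, rec, P, era) {
  if (P == 0L) {
    if (length(era) > 0L) return(NULL)
    return(list(rec = rec, n_errors = 0L))
  }
  n <- nrow(rec)
  rec[era, ] <- 0L
  S <- rs_syndromes(f, rec, P)
  dirty <- colSums(S != 0L) > 0L
  n_err <- 0L
  if (length(era) > 0L && any(dirty)) {
    mag <- rs_erasure_magnitudes(f, S[, dirty, drop = FALSE], n, era)
    if (!is.null(mag)) {
      fix <- rs_sparse_syndromes(f, n, P, era, mag)
      resid <- matrix(bitwXor(fix, S[, dirty, drop = FALSE]), nrow = P)
      ok <- colSums(resid != 0L) == 0L
      cols <- which(dirty)[ok]
      for (t in seq_along(era))
        rec[era[t], cols] <- bitwXor(rec[era[t], cols], mag[t, ok])
      dirty[cols] <- FALSE
    }
  }
  for (cc in which(dirty)) {             # residual unknown errors, per column
    corr <- rs_correct_column(f, S[, cc], n, P, era)
    if (is.null(corr)) return(NULL)
    keep <- !(corr$pos %in% era)
    n_err <- n_err + sum(keep & corr$mag != 0L)
    for (t in seq_along(corr$pos))
      rec[corr$pos[t], cc] <- bitwXor(rec[corr$pos[t], cc], corr$mag[t])
  }
  list(rec = rec, n_errors = n_err)
}

#' Recover data fragments from a damaged pool
#'
#' Rebuilds every Reed-Solomon block from the fragments present: fragments
#' whose address is absent are erasures, fragments listed in `erasures`
#' (e.g. failed codon validation) are erasures, and any remaining corrupted
#' codon values are located and corrected as unknown errors, provided
#' `erasures + 2 * errors <= parity` per block.
#'
#' @param fragments A [dna_fragments()] containing the surviving fragments
#'   (data and parity, any order, possibly incomplete).
#' @param manifest The `design_manifest` (with RS layout) from [add_parity()].
#' @param erasures Integer vector of global fragment indices to treat as
#'   erased even if present.
#' @return A list with `fragments` (the corrected data fragments, complete
#'   and in order) and `stats` (per-block erasure and correction counts).
#' @export
recover <- function(fragments, manifest, erasures = integer(0L)) {
  table <- manifest_table(manifest)
  b <- table$b
  f <- gf_field(b)
  g <- manifest_geometry(manifest)
  layout <- manifest$rs
  n_data <- manifest$n_data
  n_total <- n_data + manifest$n_parity
  vm <- matrix(NA_integer_, nrow = n_total, ncol = g$n_codons)
  keep <- fragments$index < n_total & !(fragments$index %in% erasures)
  if (any(keep)) {
    vals <- values_from_payload(fragments$payload[keep, , drop = FALSE],
                                fragments$address[keep], table)
    vals[rowSums(is.na(vals)) > 0L, ] <- NA_integer_   # invalid codon => erase
    vm[fragments$index[keep] + 1L, ] <- vals
  }
  if (is.null(layout) || manifest$n_parity == 0L) {
    missing <- which(rowSums(is.na(vm[seq_len(n_data), , drop = FALSE])) > 0L) - 1L
    if (length(missing) > 0L)
      stop_unrecoverable("no redundancy; missing or invalid data fragments: ",
                         paste(missing, collapse = ", "))
    return(list(fragments = rebuild_data_fragments(vm, manifest, table),
                stats = data.frame(block = integer(0L), erasures = integer(0L),
                                   errors = integer(0L))))
  }
  d_off <- c(0L, cumsum(layout$data_rows))
  p_off <- c(0L, cumsum(layout$parity_rows))
  nb <- length(layout$data_rows)
  stats <- data.frame(block = seq_len(nb), erasures = 0L, errors = 0L)
  for (blk in seq_len(nb)) {
    drows <- if (layout$data_rows[blk] > 0L)
      (d_off[blk] + 1L):d_off[blk + 1L] else integer(0L)
    prows <- if (layout$parity_rows[blk] > 0L)
      n_data + ((p_off[blk] + 1L):p_off[blk + 1L]) else integer(0L)
    rows <- c(drows, prows)
    P <- layout$parity_rows[blk]
    block <- vm[rows, , drop = FALSE]
    era <- which(rowSums(is.na(block)) > 0L)
    if (length(era) > P)
      stop_unrecoverable("block ", blk, ": ", length(era),
                         " erasures exceed parity ", P)
    out <- rs_decode_block(f, block, P, era)
    if (is.null(out))
      stop_unrecoverable("block ", blk,
                         ": error/erasure capability exceeded")
    stats$erasures[blk] <- length(era)
    stats$errors[blk] <- out$n_errors
    vm[rows, ] <- out$rec
  }
  list(fragments = rebuild_data_fragments(vm, manifest, table), stats = stats)
}

rebuild_data_fragments <- function(vm, manifest, table) {
  g <- manifest_geometry(manifest)
  n_data <- manifest$n_data
  index <- seq_len(n_data) - 1L
  address <- make_address(index, g$address_chars)
  payload <- payload_from_values(vm[seq_len(n_data), , drop = FALSE],
                                 address, table)
  dna_fragments(table$alphabet, g, index, address, payload,
                rep("data", n_data))
}

stop_unrecoverable <- function(...) {
  stop(structure(class = c("dnastore_unrecoverable", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1L))))
}
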
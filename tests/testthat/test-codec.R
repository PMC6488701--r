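test_that("addresses are base-4 strings that round-trip", {
  expect_equal(make_address(0L, 3L), "AAA")
  expect_equal(make_address(45L, 3L), "GTC")   # 45 = 2*16 + 3*4 + 1
  expect_equal(make_address(63L, 3L), "TTT")
  idx <- c(0L, 1L, 7L, 255L, 4095L)
  expect_equal(address_to_index(make_address(idx, 6L)), idx)
})

test_that("bit helpers round-trip with MSB-first packing", {
  x <- as.raw(c(0x00, 0x01, 0x80, 0xff, 0xa5))
  bits <- dnastore:::bytes_to_bits(x)
  expect_equal(length(bits), 40L)
  expect_equal(bits[1:8], c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(bits[17:24], c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
  expect_identical(dnastore:::bits_to_bytes(bits), x)
  for (b in c(5L, 7L, 11L, 13L)) {
    v <- dnastore:::bits_to_values(bits, b)
    expect_true(all(v >= 0L & v < 2^b))
    expect_equal(dnastore:::values_to_bits(v, b)[seq_along(bits)], bits)
  }
})

test_that("codon tables carry the derived bits per codon", {
  expected <- c(pure4 = 5L, ws6 = 7L, iupac15 = 11L, ratio21 = 13L)
  adm <- c(pure4 = 48L, ws6 = 180L, iupac15 = 3150L, ratio21 = 8820L)
  for (nm in names(expected)) {
    tab <- build_codon_table(standard_alphabet(nm))
    expect_equal(tab$b, expected[[nm]])
    expect_equal(tab$n_admissible, adm[[nm]])
    k <- tab$alphabet$k
    expect_equal(tab$n_admissible, (k - 1L) * k^2)
  }
})

test_that("admissible codon counts match brute-force enumeration", {
  for (nm in c("pure4", "ws6", "iupac15", "ratio21")) {
    al <- standard_alphabet(nm)
    k <- al$k
    grid <- expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))
    for (ctx in c(1L, k)) {
      expect_equal(sum(grid$x != ctx), (k - 1L) * k^2)
    }
  }
})

test_that("codon tables are bijective and respect the context rule", {
  for (nm in c("pure4", "ws6", "iupac15")) {
    tab <- build_codon_table(standard_alphabet(nm))
    k <- tab$alphabet$k
    for (ctx in seq_len(k)) {
      codons <- tab$enc[ctx, ]
      expect_equal(anyDuplicated(codons), 0L)
      # first character of every assigned codon differs from the context
      expect_true(all(codons %/% (k * k) + 1L != ctx))
      # dec inverts enc
      expect_equal(tab$dec[ctx, codons + 1L], 0:(2^tab$b - 1L))
    }
  }
})

test_that("codon tables are deterministic across builds", {
  a <- build_codon_table(standard_alphabet("iupac15"))
  b <- build_codon_table(standard_alphabet("iupac15"))
  expect_identical(a$enc, b$enc)
  expect_identical(a$dec, b$dec)
})

test_that("scalar codon encode/decode round-trips and rejects bad input", {
  tab <- build_codon_table(standard_alphabet("ws6"))
  for (v in c(0L, 1L, 100L, 127L)) {
    codon <- encode_codon(v, "A", tab)
    expect_length(codon, 3L)
    expect_false(codon[1L] == "A")
    expect_equal(decode_codon(codon, "A", tab), v)
  }
  expect_error(encode_codon(128L, "A", tab), "out of range")
  expect_error(encode_codon(5L, "Z", tab), "not a character")
  expect_error(decode_codon(c("A", "A", "A"), "A", tab), "invalid codon")
})

test_that("the 854-byte demo encodes to 45 fragments at 3.37 bits/char", {
  payload <- random_payload(854L, 7)
  enc <- encode_data(payload, preset_geometry("oligo85"),
                     standard_alphabet("iupac15"))
  expect_equal(length(enc$fragments), 45L)
  cap <- capacity_report(854L, enc$fragments)
  expect_equal(round(cap$capacity, 2), 3.37)
  expect_identical(decode_data(enc$fragments, enc$manifest), payload)
})

test_that("encode/decode round-trips for every alphabet", {
  geo <- fragment_geometry(5L, 3L)
  for (nm in c("pure4", "ws6", "iupac15", "ratio21")) {
    payload <- random_payload(151L, 11)
    enc <- encode_data(payload, geo, standard_alphabet(nm))
    expect_identical(decode_data(enc$fragments, enc$manifest), payload)
  }
})

test_that("no designed fragment contains a character run of four", {
  for (nm in c("pure4", "iupac15", "ratio21")) {
    payload <- random_payload(200L, 13)
    enc <- encode_data(payload, fragment_geometry(6L, 3L),
                       standard_alphabet(nm))
    expect_lte(max_design_run(enc$fragments), 3L)
  }
})

test_that("encoding rejects payloads exceeding the address space", {
  expect_error(
    encode_data(random_payload(4000L, 17), fragment_geometry(14L, 3L),
                standard_alphabet("iupac15")),
    "address space")
})

test_that("capacity never exceeds the theoretical alphabet capacity", {
  for (nm in c("pure4", "ws6", "iupac15", "ratio21")) {
    al <- standard_alphabet(nm)
    payload <- random_payload(350L, 19)
    enc <- encode_data(payload, fragment_geometry(10L, 3L), al)
    expect_lte(capacity_report(350L, enc$fragments)$capacity,
               theoretical_capacity(al))
  }
})

test_that("capacity_report computes physical density from molecule counts", {
  cap <- capacity_report(854L, 45L, preset_geometry("oligo85"),
                         molecules_per_fragment = 1e7)
  expect_true(is.finite(cap$density) && cap$density > 0)
  expect_true(is.na(capacity_report(854L, 45L,
                                    preset_geometry("oligo85"))$density))
})

test_that("manifests round-trip through YAML", {
  payload <- random_payload(120L, 23)
  enc <- encode_data(payload, fragment_geometry(4L, 3L),
                     standard_alphabet("iupac15"))
  path <- withr::local_tempfile(fileext = ".yml")
  write_manifest(enc$manifest, path)
  back <- read_manifest(path)
  expect_equal(back$byte_length, 120L)
  expect_equal(back$n_data, enc$manifest$n_data)
  expect_equal(back$alphabet$symbols, enc$manifest$alphabet$symbols)
  expect_identical(decode_data(enc$fragments, back), payload)
})

test_that("design FASTA round-trips, including ratio variants", {
  geo <- fragment_geometry(4L, 3L)
  for (nm in c("iupac15", "ratio21")) {
    al <- standard_alphabet(nm)
    enc <- encode_data(random_payload(64L, 29), geo, al)
    fa <- withr::local_tempfile(fileext = ".fasta")
    va <- withr::local_tempfile(fileext = ".tsv")
    write_design_fasta(enc$fragments, fa, variants_path = va)
    back <- read_design_fasta(fa, al, geo, variants_path = va)
    expect_equal(back$payload, enc$fragments$payload)
    expect_equal(back$address, enc$fragments$address)
  }
})

test_that("geometry presets match the published layouts", {
  g85 <- preset_geometry("oligo85")
  expect_equal(g85$total_chars, 85L)
  expect_equal(g85$read_chars, 45L)
  g160 <- preset_geometry("oligo160")
  expect_equal(g160$total_chars, 160L)
  expect_equal(g160$read_chars, 120L)
  g200 <- preset_geometry("sim200")
  expect_equal(g200$total_chars, 200L)
  expect_equal(g200$read_chars, 160L)
  expect_equal(g200$pad_chars, 1L)
})
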
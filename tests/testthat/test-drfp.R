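test_that("single-atom and small-molecule shingles match hand enumeration", {
  expect_identical(circular_shingles("C", max_radius = 0L), "C")
  expect_identical(circular_shingles("C", max_radius = 2L), "C")
  # ethanol at radius 1: atom environments are C (x2 centers, set-collapsed),
  # O, the C-C pair, the C-O pair, and the full C-C-O environment
  expect_setequal(circular_shingles("CCO", max_radius = 1L),
                  c("C", "O", "CC", "CO", "CCO"))
})

test_that("radius-0 shingle count never exceeds the heavy-atom count", {
  for (smi in c("CCO", "c1ccccc1Cl", "CC(=O)OC", "C[N+](=O)[O-]")) {
    expect_lte(length(circular_shingles(smi, max_radius = 0L)),
               crxnfp:::.n_heavy_atoms(smi))
  }
})

test_that("identity reactions give degenerate fingerprints", {
  fp <- drfp(canonicalize_reaction("CCO>>CCO"), n_bits = 64L)
  expect_true(fp$degenerate)
  expect_length(fp$on_bits, 0L)
})

test_that("equal reactions give identical fingerprints with Tanimoto 1", {
  a <- drfp(canonicalize_reaction("CCO>>CC=O"))
  b <- drfp(canonicalize_reaction("OCC>>O=CC"))
  expect_identical(a$on_bits, b$on_bits)
  expect_equal(tanimoto(a, b), 1)
})

test_that("fingerprints ignore component order and atom maps", {
  a <- drfp(canonicalize_reaction("CC(=O)OCC.O>>CC(=O)O.OCC"))
  b <- drfp(canonicalize_reaction("O.CC(=O)OCC>>OCC.CC(=O)O"))
  m <- drfp(canonicalize_reaction("[CH3:1]C(=O)OCC.O>>[CH3:1]C(=O)O.OCC"))
  expect_identical(a$on_bits, b$on_bits)
  expect_identical(a$on_bits, m$on_bits)
})

test_that("fingerprints equal the brute-force set-algebra oracle", {
  bm <- small_benchmark()
  rxns <- bm$reactions[seq_len(min(60L, length(bm$reactions)))]
  expect_gte(length(rxns), 50L)
  for (n_bits in c(64L, 2048L)) {
    for (r in rxns) {
      fp <- drfp(r, max_radius = 2L, n_bits = n_bits)
      expect_identical(fp$on_bits, oracle_drfp_bits(r, 2L, n_bits),
                       info = paste(r$smiles, n_bits))
    }
  }
})

test_that("tanimoto identities and symmetry hold", {
  a <- drfp(canonicalize_reaction("CCO>>CC=O"), n_bits = 64L)
  b <- drfp(canonicalize_reaction("Clc1ccccc1>>Nc1ccccc1"), n_bits = 64L)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  expect_gte(tanimoto(a, b), 0)
  expect_lte(tanimoto(a, b), 1)
  # hand case on synthetic fingerprints: {1,2,3} vs {2,3,4} -> 2/4
  x <- structure(list(n_bits = 8L, on_bits = c(1L, 2L, 3L), shingles = "x",
                      degenerate = FALSE), class = "crxnfp_fp")
  y <- structure(list(n_bits = 8L, on_bits = c(2L, 3L, 4L), shingles = "y",
                      degenerate = FALSE), class = "crxnfp_fp")
  expect_equal(tanimoto(x, y), 0.5)
  z <- structure(list(n_bits = 8L, on_bits = c(6L, 7L), shingles = "z",
                      degenerate = FALSE), class = "crxnfp_fp")
  expect_equal(tanimoto(x, z), 0)
})

test_that("a degenerate pair is an error, not a silent score", {
  d <- drfp(canonicalize_reaction("CCO>>CCO"), n_bits = 64L)
  expect_error(tanimoto(d, d), "degenerate")
})

test_that("mismatched fingerprint lengths are rejected", {
  a <- drfp(canonicalize_reaction("CCO>>CC=O"), n_bits = 64L)
  b <- drfp(canonicalize_reaction("CCO>>CC=O"), n_bits = 128L)
  expect_error(tanimoto(a, b), "lengths")
})

test_that("fnv1a32 matches published reference digests", {
  # reference values of the 32-bit FNV-1a test vectors
  expect_equal(fnv1a32(""), 2166136261)
  expect_equal(fnv1a32("a"), 3826002220)
  expect_equal(fnv1a32("foobar"), 3214735720)
  # agreement with the independently coded oracle on shingle-like strings
  strs <- c("C", "CCO", "c1ccccc1Cl", "[O-][N+](=O)C", "CC(=O)O")
  expect_equal(fnv1a32(strs),
               vapply(strs, oracle_fnv1a, numeric(1), USE.NAMES = FALSE))
})

test_that("hex encoding has the right width and bit placement", {
  fp <- structure(list(n_bits = 16L, on_bits = c(0L, 5L), shingles = "s",
                       degenerate = FALSE), class = "crxnfp_fp")
  expect_identical(fp_to_hex(fp), "0021")
})
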
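test_that("EC parsing and formatting round-trip, wildcards included", {
  e <- ec_parse("6.2.1.-")
  expect_identical(as.integer(e[1:3]), c(6L, 2L, 1L))
  expect_true(is.na(e[4]))
  expect_identical(attr(e, "depth"), 3L)
  expect_identical(format(e), "6.2.1.-")
  expect_identical(format(ec_parse("3.8.1.3")), "3.8.1.3")
  expect_identical(attr(ec_parse("6.2.1"), "depth"), 3L)
  expect_error(ec_parse("6.2.1.0"), "invalid")
  expect_error(ec_parse("6.-.1.2"), "wildcard")
  expect_error(ec_parse("1.2.3.4.5"), "1-4")
})

test_that("composite references accept any alternative", {
  ref <- ec_reference("3.8.1.3 AND 3.8.1.2")
  expect_length(ref, 2L)
  expect_true(ec_match(ec_parse("3.8.1.3"), ref, 4))
  expect_true(ec_match(ec_parse("3.8.1.2"), ref, 4))
  expect_false(ec_match(ec_parse("3.8.1.4"), ref, 4))
})

test_that("level matching follows the hierarchy and reference depth", {
  # same sub-subclass, different serial: match at 3, not at 4
  expect_true(ec_match(ec_parse("3.8.1.3"), ec_reference("3.8.1.2"), 3))
  expect_false(ec_match(ec_parse("3.8.1.3"), ec_reference("3.8.1.2"), 4))
  # a depth-3 reference accepts deeper predictions at level 3 (and 4)
  expect_true(ec_match(ec_parse("6.2.1.40"), ec_reference("6.2.1"), 3))
  expect_true(ec_match(ec_parse("6.2.1.40"), ec_reference("6.2.1"), 4))
  expect_false(ec_match(ec_parse("6.3.1.40"), ec_reference("6.2.1"), 2))
  # a wildcard prediction field blocks matching at that depth
  expect_false(ec_match(ec_parse("6.2.1.-"), ec_reference("6.2.1.40"), 4))
  expect_true(ec_match(ec_parse("6.2.1.-"), ec_reference("6.2.1.40"), 3))
  # missing prediction never matches
  expect_false(ec_match(NULL, ec_reference("1.1.1.1"), 1))
  expect_error(ec_match(ec_parse("1.1.1.1"), ec_reference("1.1.1.1"), 5),
               "1..4")
})

test_that("scoring counts missing predictions as errors", {
  refs <- c("1.1.1.1", "2.2.2.2", "3.3.3.3")
  preds <- list(ec_parse("1.1.1.1"), NULL, ec_parse("3.3.3.3"))
  expect_equal(score_ec_predictions(refs, preds, 4), 100 * 2 / 3)
  all_right <- list(ec_parse("1.1.1.1"), ec_parse("2.2.2.2"),
                    ec_parse("3.3.3.3"))
  expect_equal(score_ec_predictions(refs, all_right, 4), 100)
})

test_that("accuracy is non-increasing in the scoring level", {
  tab <- read_ec_benchmark()
  for (col in c("crxnfp", "theia", "claire")) {
    accs <- vapply(1:4, function(l) score_ec_table(tab, col, l), numeric(1))
    expect_true(all(diff(accs) <= 1e-12), info = col)
  }
})

test_that("self-queries return themselves at cosine 1", {
  bm <- small_benchmark()
  model <- init_encoder(
    encoder_config(build_vocab(bm$reactions), n_layers = 2L,
                   hidden_size = 16L, ffn_size = 24L, n_heads = 2L,
                   max_len = 120L), seed = 2L)
  idx <- build_reference_index(bm$reference[1:25, ], model)
  q <- canonicalize_reaction(bm$reference$reaction_smiles[3])
  res <- associate(q, idx, k = 5L, threshold = 0.5)
  expect_identical(res$status, "predicted")
  expect_identical(res$neighbors$source_id[1], bm$reference$source_id[3])
  expect_equal(res$neighbors$cosine[1], 1, tolerance = 1e-12)
  expect_true(all(diff(res$neighbors$cosine) <= 1e-12))
  expect_true(all(res$neighbors$cosine > 0.5))
  # the top-hit rule then recovers the reference's own EC annotation
  expect_identical(format(predict_ec(res)),
                   format(ec_parse(bm$reference$ec[3])))
})

test_that("raising the threshold never adds neighbours", {
  bm <- small_benchmark()
  model <- init_encoder(
    encoder_config(build_vocab(bm$reactions), n_layers = 2L,
                   hidden_size = 16L, ffn_size = 24L, n_heads = 2L,
                   max_len = 120L), seed = 2L)
  idx <- build_reference_index(bm$reference[1:25, ], model)
  q <- canonicalize_reaction(bm$reference$reaction_smiles[30])
  prev <- Inf
  for (th in c(-1, 0, 0.5, 0.9, 0.999)) {
    n <- nrow(associate(q, idx, k = 10L, threshold = th)$neighbors)
    expect_lte(n, prev)
    prev <- n
  }
  # an impossible threshold leaves no analogous reaction
  res <- associate(q, idx, k = 5L, threshold = 0.9999999)
  expect_identical(res$status, "no_analogous_reaction")
  expect_identical(nrow(res$neighbors), 0L)
  expect_null(predict_ec(res))
})

test_that("majority voting aggregates surviving neighbours", {
  res <- structure(list(
    query_id = "q", status = "predicted",
    neighbors = data.frame(
      source_id = c("r1", "r2", "r3"),
      cosine = c(0.9, 0.8, 0.7),
      ec = c("1.1.1.1", "3.5.1.4", "3.5.1.9"),
      stringsAsFactors = FALSE)), class = "crxnfp_association")
  expect_identical(format(predict_ec(res, "top")), "1.1.1.1")
  expect_identical(format(predict_ec(res, "majority", level = 2L)), "3.5.1.4")
})
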
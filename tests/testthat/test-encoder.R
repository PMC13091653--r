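tiny_config <- function(pooling = "mean") {
  rxns <- list(canonicalize_reaction("CCO>>CC=O"),
               canonicalize_reaction("CC(=O)OC>>CC(=O)O.CO"))
  encoder_config(build_vocab(rxns), n_layers = 2L, hidden_size = 8L,
                 ffn_size = 12L, n_heads = 2L, pooling = pooling,
                 max_len = 40L)
}

test_that("mean_pool averages only unmasked tokens", {
  v <- matrix(c(1, 2, 3, 4), 1, 4)
  expect_equal(mean_pool(v, TRUE), c(1, 2, 3, 4))
  m <- rbind(c(1, 1), c(-1, -1))
  expect_equal(mean_pool(m, c(TRUE, TRUE)), c(0, 0))
  # padded rows are excluded
  mp <- rbind(c(2, 4), c(9, 9), c(4, 2))
  expect_equal(mean_pool(mp, c(TRUE, FALSE, TRUE)), c(3, 3))
  expect_error(mean_pool(mp, c(FALSE, FALSE, FALSE)), "masked")
})

test_that("pooling a padded batch equals per-sequence means", {
  set.seed(1)
  lens <- c(3L, 5L, 2L)
  H <- 4L
  seqs <- lapply(lens, function(l) matrix(rnorm(l * H), l, H))
  Tmax <- max(lens)
  for (i in seq_along(seqs)) {
    padded <- rbind(seqs[[i]], matrix(0, Tmax - lens[i], H))
    mask <- c(rep(TRUE, lens[i]), rep(FALSE, Tmax - lens[i]))
    expect_equal(mean_pool(padded, mask), colMeans(seqs[[i]]))
  }
})

test_that("cosine identities hold and zero vectors are rejected", {
  a <- c(1, 2, 3)
  expect_equal(cosine(a, a), 1)
  expect_equal(cosine(a, -a), -1)
  expect_equal(cosine(c(1, 0), c(0, 1)), 0)
  expect_error(cosine(a, c(0, 0, 0)), "zero-norm")
})

test_that("analytic gradients agree with numerical gradients", {
  cfg <- tiny_config()
  m <- init_encoder(cfg, seed = 42L)
  ids_a <- crxnfp:::.reaction_ids(canonicalize_reaction("CCO>>CC=O"), cfg)
  ids_b <- crxnfp:::.reaction_ids(canonicalize_reaction("CC(=O)OC>>CC(=O)O.CO"), cfg)
  target <- 0.7
  loss_fn <- function(model) {
    fa <- crxnfp:::.encoder_fwd(model, ids_a)
    fb <- crxnfp:::.encoder_fwd(model, ids_b)
    (cosine(fa$pooled, fb$pooled) - target)^2
  }
  fa <- crxnfp:::.encoder_fwd(m, ids_a)
  fb <- crxnfp:::.encoder_fwd(m, ids_b)
  cs <- cosine(fa$pooled, fb$pooled)
  dcs <- 2 * (cs - target)
  g <- crxnfp:::.zero_grad(m$params)
  g <- crxnfp:::.encoder_bwd(m, fa, dcs * crxnfp:::.dcos_da(fa$pooled, fb$pooled, cs), g)
  g <- crxnfp:::.encoder_bwd(m, fb, dcs * crxnfp:::.dcos_da(fb$pooled, fa$pooled, cs), g)

  eps <- 1e-6
  set.seed(1)
  for (nm in c("tok", "pos", "L1.Wq", "L1.Wo", "L1.fW1", "L1.ln1_g",
               "L2.Wk", "L2.fW2", "L2.ln2_b", "lnf_g")) {
    for (ii in sample(length(m$params[[nm]]), 3L)) {
      m2 <- m
      m2$params[[nm]][ii] <- m2$params[[nm]][ii] + eps
      lp <- loss_fn(m2)
      m2$params[[nm]][ii] <- m2$params[[nm]][ii] - 2 * eps
      lm <- loss_fn(m2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(g[[nm]][ii], num, tolerance = 1e-4,
                   info = paste(nm, ii))
    }
  }
})

test_that("encoding is deterministic and has the configured width", {
  cfg <- tiny_config()
  m <- init_encoder(cfg, seed = 5L)
  rxns <- list(canonicalize_reaction("CCO>>CC=O"))
  e1 <- encode_reactions(rxns, m)
  e2 <- encode_reactions(rxns, m)
  expect_identical(e1, e2)
  expect_identical(dim(e1), c(1L, 8L))
  expect_true(all(is.finite(e1)))
})

test_that("mean and cls pooling differ on multi-token input", {
  m_mean <- init_encoder(tiny_config("mean"), seed = 5L)
  m_cls <- init_encoder(tiny_config("cls"), seed = 5L)
  rxns <- list(canonicalize_reaction("CCO>>CC=O"))
  expect_gt(max(abs(encode_reactions(rxns, m_mean) -
                    encode_reactions(rxns, m_cls))), 1e-8)
})

test_that("attention maps have layer-by-token shape and unit rows", {
  cfg <- tiny_config()
  m <- init_encoder(cfg, seed = 5L)
  rxn <- canonicalize_reaction("CCO>>CC=O")
  am <- attention_map(m, rxn)
  n_tok <- length(crxnfp:::.reaction_ids(rxn, cfg))
  expect_identical(dim(am), c(2L, n_tok))
  expect_equal(unname(rowSums(am)), c(1, 1), tolerance = 1e-12)
  # raw per-head attention rows are softmax outputs summing to 1
  fwd <- crxnfp:::.encoder_fwd(m, crxnfp:::.reaction_ids(rxn, cfg),
                               keep_attention = TRUE)
  for (l in seq_along(fwd$attn)) {
    for (A in fwd$attn[[l]]) {
      expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-12)
    }
  }
})

test_that("identical-reaction pairs anchor the loss at the transform ceiling", {
  # an identical pair has cosine exactly 1, so its squared error against the
  # maximal target 1 - e^(-5) is (e^(-5))^2; and the quadratic in the cosine
  # is minimized exactly at that target
  m <- init_encoder(tiny_config(), seed = 3L)
  cfg <- m$config
  ids <- crxnfp:::.reaction_ids(canonicalize_reaction("CCO>>CC=O"), cfg)
  e <- crxnfp:::.encoder_fwd(m, ids)$pooled
  target <- transform_score(1)
  expect_equal((cosine(e, e) - target)^2, exp(-5)^2, tolerance = 1e-12)
  cos_grid <- seq(-1, 1, length.out = 2001)
  expect_equal(cos_grid[which.min((cos_grid - target)^2)], target,
               tolerance = 1e-3)
})

test_that("zero training epochs leave the model untouched", {
  bm <- small_benchmark()
  m <- desk_encoder()
  cfg0 <- train_config(epochs = 0L, seed = 1L)
  res <- train_contrastive(bm$pairs, m, cfg0)
  expect_identical(res$model$params, m$params)
  expect_identical(res$steps_run, 0L)
})

test_that("checkpoints round-trip through the directory layout", {
  m <- init_encoder(tiny_config(), seed = 9L)
  dir <- withr::local_tempdir()
  save_encoder(m, dir)
  expect_true(all(file.exists(file.path(dir, c("config.json", "vocab.txt",
                                               "weights.tsv")))))
  m2 <- load_encoder(dir)
  expect_identical(m2$config$vocab, m$config$vocab)
  expect_equal(m2$params, m$params, tolerance = 1e-15)
  rxns <- list(canonicalize_reaction("CCO>>CC=O"))
  expect_equal(encode_reactions(rxns, m2), encode_reactions(rxns, m),
               tolerance = 1e-12)
})

test_that("training rejects bad inputs", {
  m <- init_encoder(tiny_config(), seed = 1L)
  expect_error(train_contrastive(data.frame(), m), "smiles_a")
  bad <- data.frame(smiles_a = "CCO>>CC=O", smiles_b = "CCO>>CC=O",
                    target = 1.5)
  expect_error(train_contrastive(bad, m), "\\[0, 1\\)")
})
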
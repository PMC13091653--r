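# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# small labeled corpus + stratified pairs + pseudo-annotated reference
small_benchmark <- function() {
  .memo("small_benchmark", function() {
    make_benchmark(n_per_class = 20L, seed = 7L, pair_scheme = bin_scheme(10L))
  })
}

# larger pair set for the training-improvement checks
training_benchmark <- function() {
  .memo("training_benchmark", function() {
    make_benchmark(n_per_class = 30L, seed = 7L,
                   pair_scheme = bin_scheme(250L, 1000L))
  })
}

# desk-scale encoder over the training corpus vocabulary
desk_encoder <- function(seed = 11L) {
  bm <- training_benchmark()
  vocab <- build_vocab(bm$reactions)
  cfg <- encoder_config(vocab, n_layers = 2L, hidden_size = 64L,
                        ffn_size = 128L, n_heads = 4L, pooling = "mean",
                        max_len = 120L)
  init_encoder(cfg, seed = seed)
}

# one shared fine-tuning run (used by the training-improvement and the
# classification-surrogate checks)
trained_desk_encoder <- function() {
  .memo("trained_desk_encoder", function() {
    bm <- training_benchmark()
    model <- desk_encoder()
    set.seed(99L)
    hold <- sample(nrow(bm$pairs), 300L)
    cfg <- train_config(max_lr = 5e-4, epochs = 2L, batch_size = 32L,
                        eval_every = 10L, patience_steps = 200L, seed = 3L)
    fit <- train_contrastive(bm$pairs[-hold, ], model, cfg)
    list(before = model, after = fit$model, fit = fit,
         heldout = bm$pairs[hold, ])
  })
}

# ---- independent oracles ---------------------------------------------------

# FNV-1a 32-bit reimplemented from the published constants with byte-wise
# (base-256 limb) modular multiplication, independent of the package's
# 16-bit-split implementation. Bytes only touch the low 8 bits in the xor.
oracle_fnv1a <- function(s) {
  two32 <- 4294967296
  prime <- 16777619
  h <- 2166136261
  for (byte in utf8ToInt(enc2utf8(s))) {
    low8 <- h %% 256
    h <- h - low8 + bitwXor(as.integer(low8), as.integer(byte))
    limbs <- c(h %% 256, (h %/% 256) %% 256, (h %/% 65536) %% 256,
               (h %/% 16777216) %% 256)
    acc <- 0
    for (k in 0:3) {
      contrib <- (limbs[k + 1] * prime) %% two32
      for (j in seq_len(k)) contrib <- (contrib * 256) %% two32
      acc <- (acc + contrib) %% two32
    }
    h <- acc
  }
  h
}

# brute-force differential fingerprint: plain set algebra over the listed
# environments of each side, oracle hash, mod fold
oracle_drfp_bits <- function(reaction, max_radius, n_bits) {
  side <- function(comps) {
    sh <- character(0)
    for (s in comps) sh <- union(sh, circular_shingles(s, max_radius))
    sh
  }
  r <- side(reaction$reactants)
  p <- side(reaction$products)
  sym <- union(setdiff(r, p), setdiff(p, r))
  if (!length(sym)) return(integer(0))
  sort(unique(vapply(sym, function(s) as.integer(oracle_fnv1a(s) %% n_bits),
                     integer(1), USE.NAMES = FALSE)))
}

# cosine k-NN by explicit per-pair loops (no matrix algebra)
oracle_knn <- function(ref, labels, query, k) {
  cos1 <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  out <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    sims <- vapply(seq_len(nrow(ref)), function(j) cos1(query[i, ], ref[j, ]),
                   numeric(1))
    ord <- order(sims, decreasing = TRUE)[seq_len(k)]
    votes <- table(labels[ord])
    top <- names(votes)[votes == max(votes)]
    out[i] <- if (length(top) == 1L) top else
      labels[ord][labels[ord] %in% top][1]
  }
  out
}
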
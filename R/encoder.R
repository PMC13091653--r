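# Transformer reaction encoder in base R: token + position embeddings,
# pre-layernorm multi-head self-attention blocks with GELU feed-forward
# sublayers, a final layernorm, and mean or [CLS] pooling. Backpropagation is
# hand-derived and checked against numerical gradients in the test suite.

.SPECIALS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]")

#' Build a token vocabulary from reactions
#'
#' Collects all SMILES tokens occurring in a corpus and prepends the special
#' tokens `[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`. Out-of-vocabulary tokens map to
#' `[UNK]` at encoding time.
#'
#' @param reactions list of `crxnfp_reaction` objects (or reaction SMILES).
#' @return character vector of tokens (the vocabulary, specials first).
#' @export
build_vocab <- function(reactions) {
  toks <- unique(unlist(lapply(reactions, function(r) {
    as.character(tokenize_reaction(r))
  })))
  c(.SPECIALS, sort(setdiff(toks, .SPECIALS)))
}

#' Encoder configuration
#'
#' The full-scale configuration mirrors the BERT-style reaction encoder the
#' method fine-tunes: 12 layers, hidden size 256, feed-forward size 512, four
#' attention heads, mean pooling. Desk-scale tests use smaller settings.
#'
#' @param vocab character vector from [build_vocab()].
#' @param n_layers number of transformer layers (default 12).
#' @param hidden_size embedding/hidden width (default 256); must be divisible
#'   by `n_heads`.
#' @param ffn_size feed-forward intermediate width (default 512).
#' @param n_heads attention heads per layer (default 4).
#' @param pooling `"mean"` (average of non-special token embeddings) or
#'   `"cls"` (first-token embedding).
#' @param max_len maximum token-sequence length including specials.
#' @return an `crxnfp_encoder_config` list.
#' @export
encoder_config <- function(vocab, n_layers = 12L, hidden_size = 256L,
                           ffn_size = 512L, n_heads = 4L,
                           pooling = c("mean", "cls"), max_len = 256L) {
  pooling <- match.arg(pooling)
  stopifnot(hidden_size %% n_heads == 0L, n_layers >= 1L,
            all(.SPECIALS %in% vocab))
  structure(list(vocab = vocab, n_layers = as.integer(n_layers),
                 hidden_size = as.integer(hidden_size),
                 ffn_size = as.integer(ffn_size),
                 n_heads = as.integer(n_heads), pooling = pooling,
                 max_len = as.integer(max_len)),
            class = "crxnfp_encoder_config")
}

#' Initialize an encoder with random weights
#'
#' Weights are drawn from N(0, 0.02^2) (the BERT initialization scale);
#' layernorm gains start at 1 and biases at 0. Fully deterministic per seed.
#'
#' @param config an `crxnfp_encoder_config`.
#' @param seed integer RNG seed.
#' @return a `crxnfp_encoder` model (config + named parameter list).
#' @export
init_encoder <- function(config, seed) {
  stopifnot(inherits(config, "crxnfp_encoder_config"))
  if (missing(seed)) stop("a seed is required for reproducible initialization")
  set.seed(seed)
  H <- config$hidden_size; FF <- config$ffn_size
  V <- length(config$vocab); L <- config$max_len
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)
  p <- list(tok = rn(V, H), pos = rn(L, H),
            lnf_g = rep(1, H), lnf_b = rep(0, H))
  for (l in seq_len(config$n_layers)) {
    pre <- paste0("L", l, ".")
    p[[paste0(pre, "Wq")]] <- rn(H, H); p[[paste0(pre, "bq")]] <- rep(0, H)
    p[[paste0(pre, "Wk")]] <- rn(H, H); p[[paste0(pre, "bk")]] <- rep(0, H)
    p[[paste0(pre, "Wv")]] <- rn(H, H); p[[paste0(pre, "bv")]] <- rep(0, H)
    p[[paste0(pre, "Wo")]] <- rn(H, H); p[[paste0(pre, "bo")]] <- rep(0, H)
    p[[paste0(pre, "ln1_g")]] <- rep(1, H); p[[paste0(pre, "ln1_b")]] <- rep(0, H)
    p[[paste0(pre, "ln2_g")]] <- rep(1, H); p[[paste0(pre, "ln2_b")]] <- rep(0, H)
    p[[paste0(pre, "fW1")]] <- rn(H, FF); p[[paste0(pre, "fb1")]] <- rep(0, FF)
    p[[paste0(pre, "fW2")]] <- rn(FF, H); p[[paste0(pre, "fb2")]] <- rep(0, H)
  }
  structure(list(config = config, params = p), class = "crxnfp_encoder")
}

#' @export
print.crxnfp_encoder <- function(x, ...) {
  cfg <- x$config
  cat("<reaction encoder: ", cfg$n_layers, " layers, hidden ",
      cfg$hidden_size, ", ffn ", cfg$ffn_size, ", ", cfg$n_heads,
      " heads, ", cfg$pooling, " pooling, vocab ", length(cfg$vocab),
      ">\n", sep = "")
  invisible(x)
}

# ---- numeric primitives ----------------------------------------------------

.addrow <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

.layernorm_fwd <- function(x, g, b, eps = 1e-12) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = .addrow(sweep(xhat, 2, g, `*`), b), xhat = xhat, inv = inv)
}

.layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * inv
  list(dx = dx, dg = dg, db = db)
}

.gelu <- function(x) x * stats::pnorm(x)
.gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

.softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Mean pooling of token vectors
#'
#' Arithmetic mean over the unmasked token vectors only; padding and other
#' masked positions are excluded.
#'
#' @param token_vectors numeric matrix, tokens by hidden.
#' @param attention_mask logical/0-1 vector, one entry per token; `TRUE`/1 =
#'   include.
#' @return the pooled vector.
#' @export
mean_pool <- function(token_vectors, attention_mask) {
  stopifnot(is.matrix(token_vectors),
            length(attention_mask) == nrow(token_vectors))
  keep <- as.logical(attention_mask)
  if (!any(keep)) stop("all tokens are masked; nothing to pool")
  colMeans(token_vectors[keep, , drop = FALSE])
}

#' Cosine similarity of two vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return cosine similarity in `[-1, 1]`.
#' @export
cosine <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("cosine undefined for a zero-norm vector")
  sum(a * b) / (na * nb)
}

# ---- forward / backward ----------------------------------------------------

# token ids (1-based into vocab) for one reaction, with [CLS]/[SEP] wrapping
.reaction_ids <- function(reaction, config) {
  toks <- as.character(tokenize_reaction(reaction))
  ids <- match(toks, config$vocab)
  ids[is.na(ids)] <- match("[UNK]", config$vocab)
  ids <- c(match("[CLS]", config$vocab), ids, match("[SEP]", config$vocab))
  if (length(ids) > config$max_len) {
    warning("token sequence truncated to max_len = ", config$max_len)
    ids <- c(ids[seq_len(config$max_len - 1L)], match("[SEP]", config$vocab))
  }
  ids
}

# forward pass for one id sequence; returns pooled vector plus caches needed
# for the backward pass and, optionally, per-layer attention matrices
.encoder_fwd <- function(model, ids, keep_attention = FALSE) {
  cfg <- model$config; p <- model$params
  H <- cfg$hidden_size; nh <- cfg$n_heads; dh <- H %/% nh
  T <- length(ids)
  x <- p$tok[ids, , drop = FALSE] + p$pos[seq_len(T), , drop = FALSE]
  layers <- vector("list", cfg$n_layers)
  attn <- if (keep_attention) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("L", l, ".")
    c1 <- .layernorm_fwd(x, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    h <- c1$y
    Q <- .addrow(h %*% p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]])
    K <- .addrow(h %*% p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]])
    V <- .addrow(h %*% p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]])
    A <- vector("list", nh)
    C <- matrix(0, T, H)
    for (hd in seq_len(nh)) {
      cols <- ((hd - 1L) * dh + 1L):(hd * dh)
      S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
      A[[hd]] <- .softmax_rows(S)
      C[, cols] <- A[[hd]] %*% V[, cols, drop = FALSE]
    }
    attn_out <- .addrow(C %*% p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
    x_mid <- x + attn_out
    c2 <- .layernorm_fwd(x_mid, p[[paste0(pre, "ln2_g")]],
                         p[[paste0(pre, "ln2_b")]])
    h2 <- c2$y
    u <- .addrow(h2 %*% p[[paste0(pre, "fW1")]], p[[paste0(pre, "fb1")]])
    a <- .gelu(u)
    f <- .addrow(a %*% p[[paste0(pre, "fW2")]], p[[paste0(pre, "fb2")]])
    x_out <- x_mid + f
    layers[[l]] <- list(c1 = c1, h = h, Q = Q, K = K, V = V, A = A, C = C,
                        x_mid = x_mid, c2 = c2, h2 = h2, u = u, a = a)
    if (keep_attention) attn[[l]] <- A
    x <- x_out
  }
  cf <- .layernorm_fwd(x, p$lnf_g, p$lnf_b)
  y <- cf$y
  pool_mask <- !(cfg$vocab[ids] %in% c("[CLS]", "[SEP]", "[PAD]"))
  pooled <- if (cfg$pooling == "mean") mean_pool(y, pool_mask) else y[1, ]
  list(pooled = pooled, y = y, cf = cf, layers = layers, ids = ids,
       pool_mask = pool_mask, attn = attn)
}

# backward pass: dpooled (vector) -> gradient list (same names as params)
.encoder_bwd <- function(model, fwd, dpooled, grad) {
  cfg <- model$config; p <- model$params
  H <- cfg$hidden_size; nh <- cfg$n_heads; dh <- H %/% nh
  T <- length(fwd$ids)
  dy <- matrix(0, T, H)
  if (cfg$pooling == "mean") {
    k <- sum(fwd$pool_mask)
    dy[fwd$pool_mask, ] <- matrix(dpooled / k, k, H, byrow = TRUE)
  } else {
    dy[1, ] <- dpooled
  }
  bf <- .layernorm_bwd(dy, fwd$cf, p$lnf_g)
  grad$lnf_g <- grad$lnf_g + bf$dg
  grad$lnf_b <- grad$lnf_b + bf$db
  dx <- bf$dx
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- paste0("L", l, ".")
    cc <- fwd$layers[[l]]
    # FFN sublayer: x_out = x_mid + gelu(LN2(x_mid) W1 + b1) W2 + b2
    df <- dx
    da <- df %*% t(p[[paste0(pre, "fW2")]])
    grad[[paste0(pre, "fW2")]] <- grad[[paste0(pre, "fW2")]] + t(cc$a) %*% df
    grad[[paste0(pre, "fb2")]] <- grad[[paste0(pre, "fb2")]] + colSums(df)
    du <- da * .gelu_grad(cc$u)
    dh2 <- du %*% t(p[[paste0(pre, "fW1")]])
    grad[[paste0(pre, "fW1")]] <- grad[[paste0(pre, "fW1")]] + t(cc$h2) %*% du
    grad[[paste0(pre, "fb1")]] <- grad[[paste0(pre, "fb1")]] + colSums(du)
    b2 <- .layernorm_bwd(dh2, cc$c2, p[[paste0(pre, "ln2_g")]])
    grad[[paste0(pre, "ln2_g")]] <- grad[[paste0(pre, "ln2_g")]] + b2$dg
    grad[[paste0(pre, "ln2_b")]] <- grad[[paste0(pre, "ln2_b")]] + b2$db
    dx_mid <- dx + b2$dx
    # attention sublayer: x_mid = x + (multi-head attn of LN1(x)) Wo + bo
    dattn <- dx_mid
    dC <- dattn %*% t(p[[paste0(pre, "Wo")]])
    grad[[paste0(pre, "Wo")]] <- grad[[paste0(pre, "Wo")]] + t(cc$C) %*% dattn
    grad[[paste0(pre, "bo")]] <- grad[[paste0(pre, "bo")]] + colSums(dattn)
    dQ <- matrix(0, T, H); dK <- matrix(0, T, H); dV <- matrix(0, T, H)
    for (hd in seq_len(nh)) {
      cols <- ((hd - 1L) * dh + 1L):(hd * dh)
      A <- cc$A[[hd]]
      dCh <- dC[, cols, drop = FALSE]
      dA <- dCh %*% t(cc$V[, cols, drop = FALSE])
      dV[, cols] <- t(A) %*% dCh
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- (dS %*% cc$K[, cols, drop = FALSE]) / sqrt(dh)
      dK[, cols] <- (t(dS) %*% cc$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    dhh <- dQ %*% t(p[[paste0(pre, "Wq")]]) +
           dK %*% t(p[[paste0(pre, "Wk")]]) +
           dV %*% t(p[[paste0(pre, "Wv")]])
    grad[[paste0(pre, "Wq")]] <- grad[[paste0(pre, "Wq")]] + t(cc$h) %*% dQ
    grad[[paste0(pre, "bq")]] <- grad[[paste0(pre, "bq")]] + colSums(dQ)
    grad[[paste0(pre, "Wk")]] <- grad[[paste0(pre, "Wk")]] + t(cc$h) %*% dK
    grad[[paste0(pre, "bk")]] <- grad[[paste0(pre, "bk")]] + colSums(dK)
    grad[[paste0(pre, "Wv")]] <- grad[[paste0(pre, "Wv")]] + t(cc$h) %*% dV
    grad[[paste0(pre, "bv")]] <- grad[[paste0(pre, "bv")]] + colSums(dV)
    b1 <- .layernorm_bwd(dhh, cc$c1, p[[paste0(pre, "ln1_g")]])
    grad[[paste0(pre, "ln1_g")]] <- grad[[paste0(pre, "ln1_g")]] + b1$dg
    grad[[paste0(pre, "ln1_b")]] <- grad[[paste0(pre, "ln1_b")]] + b1$db
    dx <- dx_mid + b1$dx
  }
  # embeddings
  for (t in seq_len(T)) {
    grad$tok[fwd$ids[t], ] <- grad$tok[fwd$ids[t], ] + dx[t, ]
  }
  grad$pos[seq_len(T), ] <- grad$pos[seq_len(T), , drop = FALSE] + dx
  grad
}

.zero_grad <- function(params) {
  lapply(params, function(x) if (is.matrix(x)) 0 * x else rep(0, length(x)))
}

# ---- public encoding API ---------------------------------------------------

#' Encode reactions into dense fingerprints
#'
#' Runs the encoder forward (deterministically; there is no dropout) and
#' returns one pooled embedding per reaction.
#'
#' @param reactions list of `crxnfp_reaction` objects.
#' @param model a `crxnfp_encoder`.
#' @return numeric matrix, reactions by `hidden_size`, rownames = reaction
#'   ids.
#' @export
encode_reactions <- function(reactions, model) {
  stopifnot(inherits(model, "crxnfp_encoder"))
  cfg <- model$config
  out <- matrix(NA_real_, length(reactions), cfg$hidden_size)
  rn <- character(length(reactions))
  for (i in seq_along(reactions)) {
    ids <- .reaction_ids(reactions[[i]], cfg)
    out[i, ] <- .encoder_fwd(model, ids)$pooled
    rn[i] <- reactions[[i]]$id %||% as.character(i)
  }
  rownames(out) <- rn
  out
}

#' Layer-wise attention map for a reaction
#'
#' For mean pooling, entry (l, t) is the attention received by token t in
#' layer l, averaged over heads and over all query positions; for [CLS]
#' pooling the query is fixed to the first position. Raw attention rows are
#' softmax outputs and sum to one before averaging.
#'
#' @param model a `crxnfp_encoder`.
#' @param reaction a `crxnfp_reaction` or reaction SMILES.
#' @param renormalize if `TRUE` (default) each output row is rescaled to sum
#'   to 1.
#' @return matrix `n_layers` by `n_tokens` with token colnames (specials
#'   included).
#' @export
attention_map <- function(model, reaction, renormalize = TRUE) {
  stopifnot(inherits(model, "crxnfp_encoder"))
  if (!inherits(reaction, "crxnfp_reaction")) {
    reaction <- canonicalize_reaction(reaction)
  }
  cfg <- model$config
  ids <- .reaction_ids(reaction, cfg)
  fwd <- .encoder_fwd(model, ids, keep_attention = TRUE)
  out <- matrix(0, cfg$n_layers, length(ids))
  for (l in seq_len(cfg$n_layers)) {
    heads <- fwd$attn[[l]]
    A <- Reduce(`+`, heads) / length(heads)   # head average, rows sum to 1
    out[l, ] <- if (cfg$pooling == "mean") colMeans(A) else A[1, ]
  }
  if (renormalize) out <- out / rowSums(out)
  colnames(out) <- cfg$vocab[ids]
  rownames(out) <- paste0("layer", seq_len(cfg$n_layers))
  out
}
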
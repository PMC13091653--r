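#' Training configuration for contrastive fine-tuning
#'
#' Defaults follow the method's fine-tuning recipe: peak learning rate 5e-5,
#' 10% of total steps as linear warm-up (then linear decay to zero), five
#' epochs, batch size 32, early stopping after 200 consecutive steps without
#' validation improvement.
#'
#' @param max_lr peak Adam learning rate.
#' @param warmup_fraction fraction of total steps used for linear warm-up.
#' @param epochs training epochs.
#' @param batch_size pairs per optimization step.
#' @param patience_steps early-stopping patience, in optimization steps.
#' @param eval_every validation-MSE evaluation cadence, in steps.
#' @param validation_fraction fraction of pairs held out for validation.
#' @param seed RNG seed controlling the split and shuffling.
#' @return a `crxnfp_train_config` list.
#' @export
train_config <- function(max_lr = 5e-5, warmup_fraction = 0.10, epochs = 5L,
                         batch_size = 32L, patience_steps = 200L,
                         eval_every = 50L, validation_fraction = 0.1,
                         seed = 1L) {
  stopifnot(max_lr > 0, warmup_fraction > 0, warmup_fraction < 1,
            epochs >= 0, batch_size >= 1, patience_steps >= 1,
            eval_every >= 1, validation_fraction > 0, validation_fraction < 1)
  structure(list(max_lr = max_lr, warmup_fraction = warmup_fraction,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 patience_steps = as.integer(patience_steps),
                 eval_every = as.integer(eval_every),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "crxnfp_train_config")
}

# learning rate at a 1-based step: linear warm-up to max_lr, then linear
# decay to zero at total_steps
.lr_at <- function(step, total_steps, max_lr, warmup_fraction) {
  warm <- max(1, ceiling(total_steps * warmup_fraction))
  if (step <= warm) return(max_lr * step / warm)
  max_lr * max(0, (total_steps - step) / max(1, total_steps - warm))
}

# mean squared error between embedding cosine and targets over a pair list
.pair_mse <- function(model, ids_a, ids_b, targets) {
  errs <- vapply(seq_along(targets), function(i) {
    ca <- .encoder_fwd(model, ids_a[[i]])$pooled
    cb <- .encoder_fwd(model, ids_b[[i]])$pooled
    (cosine(ca, cb) - targets[i])^2
  }, numeric(1))
  mean(errs)
}

# cosine gradient: d cos(a,b) / da
.dcos_da <- function(a, b, cs) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  b / (na * nb) - cs * a / (na * na)
}

#' Contrastive fine-tuning of a reaction encoder
#'
#' Minimizes the mean squared error between the cosine similarity of the two
#' pooled reaction embeddings of each pair and the pair's transformed
#' Tanimoto target. Optimization is Adam under a warm-up-then-linear-decay
#' schedule peaking at `max_lr`. Validation MSE is evaluated every
#' `eval_every` steps; training stops at the end of the epochs or once no
#' improvement has been seen for `patience_steps` consecutive steps.
#'
#' @param pairs data.frame with columns `smiles_a`, `smiles_b`, `target`
#'   (from [sample_pairs()] or a compatible file).
#' @param model a `crxnfp_encoder` (random-initialized or a loaded
#'   checkpoint).
#' @param cfg a `crxnfp_train_config`.
#' @return list with `model` (trained), `history` (data.frame of per-step
#'   train loss and periodic validation loss), `best_val`, `steps_run`,
#'   `stopped_early`.
#' @export
train_contrastive <- function(pairs, model, cfg = train_config()) {
  stopifnot(inherits(model, "crxnfp_encoder"),
            inherits(cfg, "crxnfp_train_config"),
            all(c("smiles_a", "smiles_b", "target") %in% names(pairs)))
  if (nrow(pairs) == 0L) stop("empty training set")
  if (any(pairs$target < 0 | pairs$target >= 1)) {
    stop("pair targets must lie in [0, 1)")
  }
  set.seed(cfg$seed)
  ecfg <- model$config

  # tokenize each unique reaction once
  uniq <- unique(c(pairs$smiles_a, pairs$smiles_b))
  id_tab <- lapply(uniq, function(s) {
    .reaction_ids(structure(list(smiles = s), class = "crxnfp_reaction"), ecfg)
  })
  names(id_tab) <- uniq

  n <- nrow(pairs)
  n_val <- max(1L, round(cfg$validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0L) stop("no training pairs left after validation split")

  ids_a <- id_tab[pairs$smiles_a]
  ids_b <- id_tab[pairs$smiles_b]
  targets <- pairs$target

  steps_per_epoch <- ceiling(length(tr_idx) / cfg$batch_size)
  total_steps <- cfg$epochs * steps_per_epoch
  if (total_steps == 0L) {
    return(list(model = model, history = data.frame(), best_val = NA_real_,
                steps_run = 0L, stopped_early = FALSE))
  }

  p <- model$params
  m1 <- .zero_grad(p); m2 <- .zero_grad(p)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  best_val <- .pair_mse(model, ids_a[val_idx], ids_b[val_idx], targets[val_idx])
  since_improve <- 0L
  step <- 0L
  hist_step <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)
  stopped_early <- FALSE

  for (ep in seq_len(cfg$epochs)) {
    order_ep <- sample(tr_idx)
    for (bstart in seq(1L, length(order_ep), by = cfg$batch_size)) {
      step <- step + 1L
      batch <- order_ep[bstart:min(bstart + cfg$batch_size - 1L, length(order_ep))]
      grad <- .zero_grad(p)
      loss <- 0
      model$params <- p
      for (i in batch) {
        fa <- .encoder_fwd(model, ids_a[[i]])
        fb <- .encoder_fwd(model, ids_b[[i]])
        cs <- cosine(fa$pooled, fb$pooled)
        err <- cs - targets[i]
        loss <- loss + err^2
        dcs <- 2 * err / length(batch)
        grad <- .encoder_bwd(model, fa, dcs * .dcos_da(fa$pooled, fb$pooled, cs), grad)
        grad <- .encoder_bwd(model, fb, dcs * .dcos_da(fb$pooled, fa$pooled, cs), grad)
      }
      loss <- loss / length(batch)
      if (!is.finite(loss)) {
        stop("non-finite training loss at step ", step,
             "; lower the learning rate or inspect the pair targets")
      }
      lr <- .lr_at(step, total_steps, cfg$max_lr, cfg$warmup_fraction)
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      for (nm in names(p)) {
        g <- grad[[nm]]
        m1[[nm]] <- beta1 * m1[[nm]] + (1 - beta1) * g
        m2[[nm]] <- beta2 * m2[[nm]] + (1 - beta2) * g * g
        p[[nm]] <- p[[nm]] - lr * (m1[[nm]] / bc1) /
          (sqrt(m2[[nm]] / bc2) + adam_eps)
      }
      hist_step <- c(hist_step, step)
      hist_train <- c(hist_train, loss)
      if (step %% cfg$eval_every == 0L) {
        model$params <- p
        v <- .pair_mse(model, ids_a[val_idx], ids_b[val_idx], targets[val_idx])
        hist_val <- c(hist_val, v)
        if (v < best_val) {
          best_val <- v
          since_improve <- 0L
        } else {
          since_improve <- since_improve + cfg$eval_every
        }
      } else {
        hist_val <- c(hist_val, NA_real_)
        since_improve <- since_improve  # counted at evaluation points
      }
      if (since_improve >= cfg$patience_steps) {
        stopped_early <- TRUE
        break
      }
    }
    if (stopped_early) break
  }
  model$params <- p
  list(model = model,
       history = data.frame(step = hist_step, train_loss = hist_train,
                            val_loss = hist_val),
       best_val = best_val, steps_run = step, stopped_early = stopped_early)
}

# ---- checkpoint I/O --------------------------------------------------------

#' Save an encoder checkpoint
#'
#' Writes a directory in the conventional layout: `config.json` (architecture
#' and pooling), `vocab.txt` (one token per line) and `weights.tsv`
#' (parameter name, shape, and whitespace-joined values per line).
#'
#' @param model a `crxnfp_encoder`.
#' @param dir output directory (created if needed).
#' @export
save_encoder <- function(model, dir) {
  stopifnot(inherits(model, "crxnfp_encoder"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  jsonlite::write_json(
    list(n_layers = cfg$n_layers, hidden_size = cfg$hidden_size,
         ffn_size = cfg$ffn_size, n_heads = cfg$n_heads,
         pooling = cfg$pooling, max_len = cfg$max_len),
    file.path(dir, "config.json"), auto_unbox = TRUE)
  writeLines(cfg$vocab, file.path(dir, "vocab.txt"), useBytes = TRUE)
  con <- file(file.path(dir, "weights.tsv"), "w")
  on.exit(close(con))
  for (nm in names(model$params)) {
    x <- model$params[[nm]]
    shape <- if (is.matrix(x)) paste(dim(x), collapse = "x") else
      as.character(length(x))
    writeLines(paste(nm, shape,
                     paste(sprintf("%.17g", as.numeric(x)),
                           collapse = " "), sep = "\t"), con)
  }
  invisible(dir)
}

#' Load an encoder checkpoint
#'
#' @param dir directory written by [save_encoder()].
#' @return a `crxnfp_encoder`.
#' @export
load_encoder <- function(dir) {
  cj <- jsonlite::read_json(file.path(dir, "config.json"))
  vocab <- readLines(file.path(dir, "vocab.txt"), encoding = "UTF-8")
  cfg <- encoder_config(vocab, n_layers = cj$n_layers,
                        hidden_size = cj$hidden_size, ffn_size = cj$ffn_size,
                        n_heads = cj$n_heads, pooling = cj$pooling,
                        max_len = cj$max_len)
  lines <- readLines(file.path(dir, "weights.tsv"))
  p <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    toks <- strsplit(parts[3], " +")[[1]]
    vals <- as.numeric(toks[nzchar(toks)])
    if (grepl("x", parts[2], fixed = TRUE)) {
      d <- as.integer(strsplit(parts[2], "x", fixed = TRUE)[[1]])
      p[[parts[1]]] <- matrix(vals, d[1], d[2])
    } else {
      p[[parts[1]]] <- vals
    }
  }
  structure(list(config = cfg, params = p), class = "crxnfp_encoder")
}
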
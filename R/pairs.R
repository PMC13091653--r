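#' Exponential transform of a Tanimoto similarity
#'
#' Maps a raw Tanimoto similarity `t` to `1 - exp(-5 * t)`. Reaction-pair
#' Tanimoto similarities concentrate between 0 and 0.3; the transform shifts
#' the distribution rightward while keeping values in `[0, 1)`, improving
#' resolution among low-to-moderate similarity pairs without saturating. The
#' coefficient 5 is part of the method definition.
#'
#' @param tanimoto numeric vector in `[0, 1]`.
#' @return transformed scores in `[0, 1 - exp(-5)]`.
#' @export
#' @examples
#' transform_score(c(0, 0.5, 1))
transform_score <- function(tanimoto) {
  if (any(tanimoto < 0 | tanimoto > 1 | is.na(tanimoto))) {
    stop("tanimoto values must lie in [0, 1]")
  }
  1 - exp(-5 * tanimoto)
}

#' Inverse of the similarity transform
#'
#' @param target transformed scores in `[0, 1 - exp(-5)]`.
#' @return the raw Tanimoto values.
#' @export
inverse_transform_score <- function(target) {
  if (any(target < 0 | target >= 1 | is.na(target))) {
    stop("targets must lie in [0, 1)")
  }
  -log(1 - target) / 5
}

#' Seven-bin stratification scheme for contrastive pair sampling
#'
#' Bin boundaries on the transformed-score scale are
#' `0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 1.0`: six narrow bins and one broad last
#' bin for the rarer high-similarity pairs. At full scale the quotas are
#' 100000 pairs for each narrow bin and 400000 for the last; desk-scale runs
#' pass smaller quotas with the same 1:4 ratio.
#'
#' @param quota pairs per narrow bin.
#' @param last_bin_quota pairs for the broad `[0.6, 1]` bin (default
#'   `4 * quota`).
#' @return a `crxnfp_bins` object with `boundaries` and `quotas`.
#' @export
bin_scheme <- function(quota = 100000L, last_bin_quota = 4L * quota) {
  stopifnot(quota >= 1L, last_bin_quota >= 1L)
  structure(list(
    boundaries = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 1.0),
    quotas = c(rep(as.integer(quota), 6L), as.integer(last_bin_quota))),
    class = "crxnfp_bins")
}

#' Stratified sampling of contrastive reaction pairs
#'
#' Draws unordered reaction pairs uniformly at random, computes their drfp
#' Tanimoto similarity and its transformed score, and keeps each pair in the
#' first bin whose quota is not yet filled and whose half-open interval
#' `[lo, hi)` (last bin closed at 1) contains the transformed score.
#' Degenerate reactions (empty fingerprints) are excluded. Sampling stops
#' when all quotas are filled or after `max_draw_factor` times the total
#' quota of unsuccessful draws, in which case underfilled bins are reported
#' with a warning.
#'
#' @param reactions list of `crxnfp_reaction` objects.
#' @param scheme a `crxnfp_bins` scheme.
#' @param seed integer RNG seed (required; sampling is fully reproducible).
#' @param max_radius,n_bits drfp parameters.
#' @param max_draw_factor cap on total draws, as a multiple of the total
#'   quota (default 50).
#' @return a data.frame with columns `id_a`, `id_b`, `smiles_a`, `smiles_b`,
#'   `tanimoto`, `target`, `bin`.
#' @export
sample_pairs <- function(reactions, scheme = bin_scheme(10L), seed,
                         max_radius = 2L, n_bits = 2048L,
                         max_draw_factor = 50L) {
  stopifnot(inherits(scheme, "crxnfp_bins"))
  if (missing(seed)) stop("a seed is required for reproducible pair sampling")
  fps <- lapply(reactions, drfp, max_radius = max_radius, n_bits = n_bits)
  keep <- !vapply(fps, function(f) f$degenerate, logical(1))
  if (sum(keep) < 2L) stop("fewer than two non-degenerate reactions")
  reactions <- reactions[keep]
  fps <- fps[keep]
  n <- length(reactions)
  ids <- vapply(seq_along(reactions), function(i) {
    reactions[[i]]$id %||% as.character(i)
  }, character(1))

  lo <- scheme$boundaries[-length(scheme$boundaries)]
  hi <- scheme$boundaries[-1]
  quotas <- scheme$quotas
  filled <- integer(length(quotas))
  max_draws <- max_draw_factor * sum(quotas)

  seen <- new.env(parent = emptyenv())
  rows_i <- integer(0); rows_j <- integer(0)
  rows_t <- numeric(0); rows_bin <- integer(0)

  set.seed(seed)
  draws <- 0L
  while (any(filled < quotas) && draws < max_draws) {
    draws <- draws + 1L
    ij <- sample.int(n, 2L, replace = FALSE)
    i <- min(ij); j <- max(ij)
    key <- paste0(i, "_", j)
    if (!is.null(seen[[key]])) next
    t_raw <- tanimoto(fps[[i]], fps[[j]])
    tgt <- transform_score(t_raw)
    b <- findInterval(tgt, scheme$boundaries, rightmost.closed = TRUE,
                      left.open = FALSE)
    b <- min(max(b, 1L), length(quotas))
    if (filled[b] >= quotas[b]) next
    seen[[key]] <- TRUE
    filled[b] <- filled[b] + 1L
    rows_i <- c(rows_i, i); rows_j <- c(rows_j, j)
    rows_t <- c(rows_t, t_raw); rows_bin <- c(rows_bin, b)
  }
  if (any(filled < quotas)) {
    short <- which(filled < quotas)
    warning("bins underfilled after ", draws, " draws: ",
            paste0("[", lo[short], ",", hi[short], ") ",
                   filled[short], "/", quotas[short], collapse = "; "))
  }
  data.frame(
    id_a = ids[rows_i], id_b = ids[rows_j],
    smiles_a = vapply(reactions[rows_i], function(r) r$smiles, character(1)),
    smiles_b = vapply(reactions[rows_j], function(r) r$smiles, character(1)),
    tanimoto = rows_t,
    target = transform_score(rows_t),
    bin = rows_bin,
    stringsAsFactors = FALSE)
}

#' Histogram diagnostics for a pair set
#'
#' Counts pairs per 0.05-wide bucket on both the raw Tanimoto scale and the
#' transformed scale.
#'
#' @param pairs a data.frame from [sample_pairs()].
#' @return a data.frame with `bucket_lo`, `bucket_hi`, `n_raw`,
#'   `n_transformed`.
#' @export
pair_stats <- function(pairs) {
  stopifnot(all(c("tanimoto", "target") %in% names(pairs)))
  breaks <- seq(0, 1, by = 0.05)
  cut_counts <- function(x) {
    idx <- findInterval(x, breaks, rightmost.closed = TRUE, left.open = FALSE)
    idx <- pmin(pmax(idx, 1L), length(breaks) - 1L)
    tabulate(idx, nbins = length(breaks) - 1L)
  }
  data.frame(bucket_lo = breaks[-length(breaks)], bucket_hi = breaks[-1],
             n_raw = cut_counts(pairs$tanimoto),
             n_transformed = cut_counts(pairs$target))
}
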
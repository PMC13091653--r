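# Enzyme Commission numbers, similarity-gated association of reactions to an
# EC-annotated reference set, and hierarchical EC-level scoring.

#' Parse an EC number
#'
#' Accepts 1 to 4 dot-separated fields; trailing fields may be absent or the
#' wildcard `-` (e.g. `"6.2.1"`, `"6.2.1.-"`, `"3.8.1.3"`). Parsing and
#' formatting round-trip.
#'
#' @param x a single EC string.
#' @return a `crxnfp_ec` object: integer vector of length 4 with `NA` for
#'   wildcard/absent fields, and attribute `depth` = number of specified
#'   leading fields.
#' @export
ec_parse <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  parts <- strsplit(trimws(x), ".", fixed = TRUE)[[1]]
  if (length(parts) < 1L || length(parts) > 4L) {
    stop("EC number must have 1-4 fields: '", x, "'")
  }
  fields <- rep(NA_integer_, 4L)
  for (i in seq_along(parts)) {
    if (parts[i] == "-" || parts[i] == "") next
    v <- suppressWarnings(as.integer(parts[i]))
    if (is.na(v) || v <= 0L) stop("invalid EC field '", parts[i], "' in '", x, "'")
    fields[i] <- v
  }
  spec <- which(!is.na(fields))
  depth <- if (length(spec)) max(spec) else 0L
  if (depth > 0L && any(is.na(fields[seq_len(depth)]))) {
    stop("wildcard before a specified field in '", x, "'")
  }
  structure(fields, depth = depth, n_written = length(parts),
            class = "crxnfp_ec")
}

#' Format an EC number
#'
#' @param x a `crxnfp_ec`.
#' @param ... unused.
#' @return the EC string, with `-` for wildcard fields that were written.
#' @export
format.crxnfp_ec <- function(x, ...) {
  n <- attr(x, "n_written") %||% 4L
  parts <- vapply(seq_len(n), function(i) {
    if (is.na(x[i])) "-" else as.character(x[i])
  }, character(1))
  paste(parts, collapse = ".")
}

#' @export
print.crxnfp_ec <- function(x, ...) {
  cat("<EC ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Parse an EC reference (possibly composite)
#'
#' Reference annotations may list several acceptable EC numbers joined by
#' `AND` (enzyme complexes / alternative assignments); a prediction matching
#' any alternative is scored correct.
#'
#' @param x a reference string, e.g. `"3.8.1.3 AND 3.8.1.2"`.
#' @return a `crxnfp_ec_ref`: list of `crxnfp_ec` alternatives.
#' @export
ec_reference <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  alts <- trimws(strsplit(x, "\\s+AND\\s+")[[1]])
  alts <- alts[nzchar(alts)]
  if (!length(alts)) stop("empty EC reference")
  structure(lapply(alts, ec_parse), class = "crxnfp_ec_ref")
}

#' Hierarchical EC match at a level
#'
#' A prediction matches a reference at level `L` when, for some reference
#' alternative, the first `min(L, reference depth)` fields agree and are all
#' specified on both sides. A reference specified only to depth `d < L`
#' defines its own maximum scoring depth: the prediction is truncated to `d`
#' fields for the comparison (so reference `6.2.1` accepts prediction
#' `6.2.1.40` at level 3 and 4). A wildcard or absent field on the
#' prediction side at or before the effective level means no match.
#'
#' @param predicted a `crxnfp_ec`, or `NULL`/`NA` for no prediction.
#' @param reference a `crxnfp_ec_ref` (or EC string).
#' @param level 1 to 4.
#' @return logical.
#' @export
ec_match <- function(predicted, reference, level) {
  if (!is.numeric(level) || length(level) != 1L || level < 1 || level > 4) {
    stop("level must be in 1..4")
  }
  level <- as.integer(level)
  if (is.null(predicted) || (length(predicted) == 1L && is.na(predicted))) {
    return(FALSE)
  }
  if (is.character(predicted)) predicted <- ec_parse(predicted)
  if (is.character(reference)) reference <- ec_reference(reference)
  stopifnot(inherits(predicted, "crxnfp_ec"), inherits(reference, "crxnfp_ec_ref"))
  for (alt in reference) {
    eff <- min(level, attr(alt, "depth"))
    if (eff < 1L) next
    idx <- seq_len(eff)
    if (any(is.na(predicted[idx])) || any(is.na(alt[idx]))) next
    if (all(predicted[idx] == alt[idx])) return(TRUE)
  }
  FALSE
}

#' Score EC predictions at a hierarchy level
#'
#' Percent of rows whose prediction matches the reference at the given level.
#' Rows without a prediction (e.g. no sufficiently similar reference
#' reaction) stay in the denominator and count as incorrect.
#'
#' @param references list of `crxnfp_ec_ref` (or character vector).
#' @param predictions list of `crxnfp_ec` / EC strings; `NA` or `""` = no
#'   prediction.
#' @param level 1 to 4.
#' @return accuracy in percent (0-100).
#' @export
score_ec_predictions <- function(references, predictions, level) {
  if (is.character(references)) references <- lapply(references, ec_reference)
  stopifnot(length(references) == length(predictions))
  ok <- vapply(seq_along(references), function(i) {
    pred <- predictions[[i]]
    if (is.character(pred) && (!nzchar(pred) || is.na(pred))) pred <- NULL
    ec_match(pred, references[[i]], level)
  }, logical(1))
  100 * sum(ok) / length(ok)
}

#' Load the packaged fluorinated-biotransformation EC benchmark
#'
#' A 23-row benchmark of enzymatic biotransformation reactions of fluorinated
#' micropollutants and their transformation products, each with a reference
#' EC assignment and the published predictions of three methods (similarity
#' search with contrastive reaction fingerprints, and the supervised
#' classifiers Theia and CLAIRE). Empty prediction cells mean the method
#' returned no prediction for that reaction.
#'
#' @return data.frame with columns `reaction`, `ec_reference`, `claire`,
#'   `theia`, `crxnfp`.
#' @export
read_ec_benchmark <- function() {
  path <- system.file("extdata", "fluorinated_ec_benchmark.tsv",
                      package = "crxnfp", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, comment.char = "",
                    fileEncoding = "UTF-8")
}

#' Score a prediction column of an EC benchmark table
#'
#' @param table data.frame as from [read_ec_benchmark()].
#' @param column name of the prediction column to score.
#' @param level EC level 1-4.
#' @return accuracy in percent.
#' @export
score_ec_table <- function(table, column, level) {
  stopifnot(column %in% names(table), "ec_reference" %in% names(table))
  preds <- lapply(table[[column]], function(p) {
    if (is.na(p) || !nzchar(trimws(p))) NULL else ec_parse(trimws(p))
  })
  score_ec_predictions(table$ec_reference, preds, level)
}

# ---- similarity association ------------------------------------------------

#' Build a searchable reference index of annotated reactions
#'
#' Embeds every annotated reference reaction with the encoder and stores the
#' embeddings alongside their EC and protein annotations for cosine search.
#'
#' @param annotated data.frame with columns `source_id`, `reaction_smiles`,
#'   `ec` and optionally `uniprot_accessions` (semicolon-joined).
#' @param model a `crxnfp_encoder`.
#' @return a `crxnfp_ref_index`.
#' @export
build_reference_index <- function(annotated, model) {
  stopifnot(all(c("source_id", "reaction_smiles", "ec") %in% names(annotated)),
            inherits(model, "crxnfp_encoder"))
  if (nrow(annotated) == 0L) stop("empty reference set")
  reactions <- lapply(seq_len(nrow(annotated)), function(i) {
    canonicalize_reaction(annotated$reaction_smiles[i],
                          id = as.character(annotated$source_id[i]))
  })
  emb <- encode_reactions(reactions, model)
  structure(list(embeddings = emb, annotations = annotated, model = model),
            class = "crxnfp_ref_index")
}

#' Associate a query reaction with annotated reference reactions
#'
#' Embeds the query, ranks all reference reactions by cosine similarity,
#' keeps the top `k`, and drops neighbours at or below the similarity
#' threshold. If no neighbour survives, the query is flagged
#' `no_analogous_reaction` (no enzyme can be proposed from the reference
#' set).
#'
#' @param query a `crxnfp_reaction` or reaction SMILES.
#' @param index a `crxnfp_ref_index`.
#' @param k neighbours retrieved before thresholding (default 5).
#' @param threshold cosine threshold; neighbours must exceed it (default
#'   0.5).
#' @return a `crxnfp_association`: list with `query_id`, `status`
#'   (`"predicted"` or `"no_analogous_reaction"`) and `neighbors` (data.frame
#'   `source_id`, `cosine`, `ec`, sorted by descending cosine).
#' @export
associate <- function(query, index, k = 5L, threshold = 0.5) {
  stopifnot(inherits(index, "crxnfp_ref_index"), k >= 1L,
            threshold >= -1, threshold <= 1)
  if (!inherits(query, "crxnfp_reaction")) {
    query <- canonicalize_reaction(query)
  }
  q <- encode_reactions(list(query), index$model)[1, ]
  ref <- index$embeddings
  sims <- as.numeric((ref / sqrt(rowSums(ref^2))) %*% (q / sqrt(sum(q^2))))
  ord <- order(sims, decreasing = TRUE)[seq_len(min(k, length(sims)))]
  keep <- ord[sims[ord] > threshold]
  neighbors <- data.frame(
    source_id = as.character(index$annotations$source_id[keep]),
    cosine = sims[keep],
    ec = as.character(index$annotations$ec[keep]),
    stringsAsFactors = FALSE)
  structure(list(query_id = query$id %||% query$smiles,
                 status = if (nrow(neighbors)) "predicted" else "no_analogous_reaction",
                 neighbors = neighbors),
            class = "crxnfp_association")
}

#' @export
print.crxnfp_association <- function(x, ...) {
  cat("<association ", x$query_id, ": ", x$status, ">\n", sep = "")
  if (nrow(x$neighbors)) print(x$neighbors)
  invisible(x)
}

#' Predict an EC number from an association result
#'
#' The default rule takes the EC of the top-ranked surviving neighbour; the
#' `"majority"` rule votes among surviving neighbours at the requested EC
#' level (ties broken by the better-ranked class). Returns `NULL` when the
#' association found no analogous reaction.
#'
#' @param result a `crxnfp_association`.
#' @param rule `"top"` (default) or `"majority"`.
#' @param level EC level for majority voting (default 3).
#' @return a `crxnfp_ec` or `NULL`.
#' @export
predict_ec <- function(result, rule = c("top", "majority"), level = 3L) {
  rule <- match.arg(rule)
  stopifnot(inherits(result, "crxnfp_association"))
  if (result$status == "no_analogous_reaction") return(NULL)
  if (rule == "top") return(ec_parse(result$neighbors$ec[1]))
  keys <- vapply(result$neighbors$ec, function(e) {
    f <- ec_parse(e)
    paste(f[seq_len(min(level, attr(f, "depth")))], collapse = ".")
  }, character(1))
  votes <- table(keys)
  top <- names(votes)[votes == max(votes)]
  best <- which(keys %in% top)[1]
  ec_parse(result$neighbors$ec[best])
}
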
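#' @importFrom ChemmineOB convertFormat
NULL

#' Canonicalize one or more SMILES strings
#'
#' Converts SMILES to Open Babel canonical SMILES. Atom-map numbers are
#' dropped on output, so mapped and unmapped forms of the same structure
#' canonicalize identically. Canonicalization is idempotent.
#'
#' @param smiles character vector of SMILES strings (single components, no
#'   `.`-joined mixtures required, though mixtures are accepted).
#' @return character vector of canonical SMILES, same length as `smiles`.
#' @export
#' @examples
#' \donttest{
#' canonicalize_smiles(c("OCC", "[CH3:1][OH:2]"))  # "CCO" "CO"
#' }
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  bad <- !nzchar(smiles) | is.na(smiles)
  if (any(bad)) {
    stop("empty or NA SMILES at position ", which(bad)[1])
  }
  out <- .ob_canonical_batch(smiles)
  if (length(out) != length(smiles) || any(!nzchar(out))) {
    # batch misalignment or failures: redo one at a time to name the offender
    out <- vapply(smiles, function(s) {
      r <- .ob_canonical_batch(s)
      if (length(r) != 1L || !nzchar(r)) {
        stop("unparsable SMILES: '", s, "'", call. = FALSE)
      }
      r
    }, character(1), USE.NAMES = FALSE)
  }
  out
}

# One convertFormat round trip; returns one canonical SMILES per parsed record.
.ob_canonical_batch <- function(smiles) {
  raw <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, collapse = "\n"))
  )
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  sub("\t.*$", "", lines)
}

#' Parse and canonicalize a reaction SMILES
#'
#' Accepts the two-field `reactants>>products` form or the three-field
#' `reactants>agents>products` dialect. Atom maps are stripped, every
#' component is canonicalized, and components are sorted lexicographically
#' within each side, so two writings of the same reaction yield the same
#' canonical string. Agents are retained in the record but excluded from the
#' canonical reaction string (and downstream from fingerprinting/encoding).
#'
#' @param raw_reaction_smiles a single reaction SMILES string.
#' @param id optional identifier attached to the record.
#' @param label optional class label.
#' @return an object of class `crxnfp_reaction` with elements `id`,
#'   `reactants`, `products`, `agents` (canonical SMILES character vectors),
#'   `smiles` (the canonical `reactants>>products` string) and `label`.
#' @export
#' @examples
#' \donttest{
#' rxn <- canonicalize_reaction("[CH3:1][OH:2]>>[CH3:1]Cl")
#' rxn$smiles  # "CO>>CCl"
#' }
canonicalize_reaction <- function(raw_reaction_smiles, id = NULL, label = NULL) {
  stopifnot(is.character(raw_reaction_smiles), length(raw_reaction_smiles) == 1L)
  s <- trimws(raw_reaction_smiles)
  fields <- strsplit(s, ">", fixed = TRUE)[[1]]
  if (length(fields) != 3L) {
    stop("reaction SMILES must contain '>>' or 'a>b>c': '", s, "'")
  }
  split_side <- function(side) {
    if (!nzchar(side)) return(character(0))
    comps <- strsplit(side, ".", fixed = TRUE)[[1]]
    comps[nzchar(comps)]
  }
  reactants <- split_side(fields[1])
  agents    <- split_side(fields[2])
  products  <- split_side(fields[3])
  if (length(reactants) < 1L || length(products) < 1L) {
    stop("reaction needs at least one reactant and one product: '", s, "'")
  }
  reactants <- sort(canonicalize_smiles(reactants))
  products  <- sort(canonicalize_smiles(products))
  agents    <- if (length(agents)) sort(canonicalize_smiles(agents)) else character(0)
  rxn <- structure(
    list(id = id, reactants = reactants, products = products,
         agents = agents,
         smiles = paste0(paste0(reactants, collapse = "."), ">>",
                         paste0(products, collapse = ".")),
         label = label),
    class = "crxnfp_reaction")
  rxn
}

#' @export
print.crxnfp_reaction <- function(x, ...) {
  cat("<reaction", if (!is.null(x$id)) paste0("[", x$id, "]") else "", "> ",
      x$smiles, "\n", sep = "")
  if (length(x$agents)) cat("  agents: ", paste(x$agents, collapse = "."), "\n", sep = "")
  if (!is.null(x$label)) cat("  label: ", x$label, "\n", sep = "")
  invisible(x)
}

#' Swap the two sides of a reaction
#'
#' Returns the reverse reaction (products become reactants). Used as a
#' directionality diagnostic: the distribution of cosine similarities between
#' forward and reverse embeddings reports how direction-sensitive a trained
#' encoder is.
#'
#' @param reaction a `crxnfp_reaction`.
#' @return the reversed `crxnfp_reaction`.
#' @export
reverse_reaction <- function(reaction) {
  stopifnot(inherits(reaction, "crxnfp_reaction"))
  structure(
    list(id = reaction$id, reactants = reaction$products,
         products = reaction$reactants, agents = reaction$agents,
         smiles = paste0(paste0(reaction$products, collapse = "."), ">>",
                         paste0(reaction$reactants, collapse = ".")),
         label = reaction$label),
    class = "crxnfp_reaction")
}

# Regex SMILES tokenizer vocabulary convention: bracket atoms, two-letter
# halogens, ring-closure digits and %nn, bond/branch symbols, ">>" separator.
.smiles_token_regex <- paste0(
  "(\\[[^\\]]+\\]|Br|Cl|>>|%[0-9]{2}|",
  "[BCNOPSFIbcnops]|",
  "[0-9]|\\(|\\)|\\.|=|#|\\+|\\\\|/|:|~|@|\\?|\\*|\\$|-)"
)

#' Tokenize a reaction SMILES
#'
#' Splits the canonical reaction SMILES into SMILES tokens: bracket atoms and
#' two-character halogens are single tokens, ring-closure digits are their own
#' tokens, and `>>` is one separator token. Joining the tokens reproduces the
#' input string exactly.
#'
#' @param reaction a `crxnfp_reaction`, or a reaction SMILES string.
#' @return a character vector of tokens with attribute `separator` giving the
#'   position of the `>>` token.
#' @export
#' @examples
#' \donttest{
#' tokenize_reaction("CCO>>CC=O")
#' }
tokenize_reaction <- function(reaction) {
  s <- if (inherits(reaction, "crxnfp_reaction")) reaction$smiles else reaction
  stopifnot(is.character(s), length(s) == 1L)
  m <- gregexpr(.smiles_token_regex, s, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("no tokens found in '", s, "'")
  lens <- attr(m, "match.length")
  covered <- sum(lens)
  if (covered != nchar(s)) {
    # locate first uncovered character
    hit <- rep(FALSE, nchar(s))
    for (i in seq_along(m)) hit[m[i]:(m[i] + lens[i] - 1L)] <- TRUE
    pos <- which(!hit)[1]
    stop("untokenizable character '", substr(s, pos, pos), "' at position ",
         pos, " in '", s, "'")
  }
  tokens <- substring(s, m, m + lens - 1L)
  structure(tokens, separator = which(tokens == ">>"))
}

#' Read a reaction table
#'
#' Reads a TSV/CSV table of reactions with a header. The SMILES column is
#' required; id, label and EC columns are optional. Every reaction is parsed
#' and canonicalized.
#'
#' @param path file path.
#' @param format `"tsv"` or `"csv"`.
#' @param smiles_col,id_col,label_col,ec_col column names.
#' @return a list of `crxnfp_reaction` objects; if an EC column is present its
#'   values are attached as attribute `ec` on each reaction.
#' @export
read_reaction_table <- function(path, format = c("tsv", "csv"),
                                smiles_col = "reaction_smiles",
                                id_col = "id", label_col = "label",
                                ec_col = "ec") {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", fileEncoding = "UTF-8")
  if (!smiles_col %in% names(df)) {
    stop("missing required column '", smiles_col, "' in ", path)
  }
  has_id    <- id_col %in% names(df)
  has_label <- label_col %in% names(df)
  has_ec    <- ec_col %in% names(df)
  lapply(seq_len(nrow(df)), function(i) {
    rxn <- canonicalize_reaction(
      df[[smiles_col]][i],
      id = if (has_id) as.character(df[[id_col]][i]) else as.character(i),
      label = if (has_label) df[[label_col]][i] else NULL)
    if (has_ec) attr(rxn, "ec") <- df[[ec_col]][i]
    rxn
  })
}

#' Write a reaction table
#'
#' @param reactions list of `crxnfp_reaction` objects.
#' @param path output file path.
#' @param format `"tsv"` or `"csv"`.
#' @export
write_reaction_table <- function(reactions, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(
    id = vapply(reactions, function(r) as.character(r$id %||% NA_character_), character(1)),
    reaction_smiles = vapply(reactions, function(r) r$smiles, character(1)),
    label = vapply(reactions, function(r) {
      if (is.null(r$label)) NA_character_ else as.character(r$label)
    }, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Deduplicate reactions by canonical string
#'
#' Two reactions identical up to component order and atom mapping share a
#' canonical string and are collapsed to the first occurrence.
#'
#' @param reactions list of `crxnfp_reaction` objects.
#' @return the deduplicated list.
#' @export
dedupe_reactions <- function(reactions) {
  keys <- vapply(reactions, function(r) r$smiles, character(1))
  reactions[!duplicated(keys)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
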
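# Synthetic reaction corpora for download-free benchmarking. Scaffolds are
# small molecules built compositionally (alkyl chains with optional branches
# and aryl caps) carrying one functional group; transformation templates
# (hydrolyses, oxidations, substitutions typical of environmental
# biotransformations) rewrite the group into products. Reactions produced by
# one template share a reaction center, so their differential fingerprints
# are similar; across templates they are not - the structural premise behind
# the contrastive target.

# attachment prefixes: a prefix P yields the molecule paste0(P, core), with
# the core bonded to the last atom written in P
.alkyl_units <- c("C", "CC", "CCC", "C(C)C", "CC(C)", "CCCC", "CC(C)C")
.aryl_prefixes <- c("c1ccccc1", "Cc1ccccc1C", "c1ccccc1C", "c1ccc(C)cc1C",
                    "COc1ccccc1C", "c1ccccc1CC")

#' Built-in transformation templates
#'
#' Each template names a transformation class, the functional group it
#' requires, and a pseudo-EC label following real EC superclass semantics
#' (1.x oxidations/reductions, 2.x transfers, 3.x hydrolyses).
#'
#' @return data.frame describing the templates (`name`, `group`,
#'   `pseudo_ec`).
#' @export
reaction_templates <- function() {
  data.frame(
    name = c("ester_hydrolysis", "amide_hydrolysis", "alcohol_oxidation",
             "nitro_reduction", "aromatic_halide_amination", "O_demethylation"),
    group = c("ester", "amide", "primary_alcohol",
              "nitro", "aryl_chloride", "methyl_ether"),
    pseudo_ec = c("3.1.1.1", "3.5.1.4", "1.1.1.1",
                  "1.7.1.16", "2.6.1.99", "1.14.13.25"),
    stringsAsFactors = FALSE)
}

# functional-group cores, parameterized by the scaffold prefix (and a second
# substituent for two-sided groups)
.group_smiles <- function(group, prefix, r2) {
  switch(group,
    ester           = paste0(prefix, "C(=O)O", r2),
    amide           = paste0(prefix, "C(=O)N", r2),
    primary_alcohol = paste0(prefix, "CO"),
    nitro           = paste0(prefix, "[N+](=O)[O-]"),
    aryl_chloride   = paste0("Clc1ccc(", prefix, ")cc1"),
    methyl_ether    = paste0(prefix, "OC"),
    stop("unknown group '", group, "'"))
}

#' Generate synthetic scaffold molecules
#'
#' Builds `n` functionalized scaffolds deterministically per seed: each
#' carries one functional group drawn from the template set, attached to a
#' random alkyl/aryl prefix. Every scaffold SMILES is validated by
#' canonicalization.
#'
#' @param n number of scaffolds.
#' @param seed RNG seed.
#' @param groups functional groups to draw from (default: all template
#'   groups).
#' @return list of scaffold records: `smiles` (canonical), `group`, `prefix`,
#'   `r2` (second substituent for esters/amides, else `NA`).
#' @export
generate_scaffolds <- function(n, seed, groups = reaction_templates()$group) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    group <- sample(groups, 1L)
    base <- if (group == "aryl_chloride") {
      paste0(sample(.alkyl_units, 1L))
    } else if (stats::runif(1) < 0.3) {
      sample(.aryl_prefixes, 1L)
    } else {
      paste0(sample(.alkyl_units, sample(1:3, 1L), replace = TRUE),
             collapse = "")
    }
    r2 <- if (group %in% c("ester", "amide")) {
      paste0(sample(.alkyl_units, sample(1:2, 1L), replace = TRUE),
             collapse = "")
    } else NA_character_
    raw <- .group_smiles(group, base, r2)
    out[[i]] <- list(smiles = canonicalize_smiles(raw), group = group,
                     prefix = base, r2 = r2)
  }
  out
}

#' Apply a transformation template to a scaffold
#'
#' Rewrites the scaffold's functional group according to the template's graph
#' edit and returns the labeled reaction. A template applied to a scaffold
#' lacking its required group yields `NULL` (no reaction).
#'
#' @param scaffold a record from [generate_scaffolds()].
#' @param template a template name from [reaction_templates()].
#' @return a `crxnfp_reaction` with `label` = template name and attribute
#'   `ec` = the template's pseudo-EC, or `NULL` if the template does not
#'   apply.
#' @export
apply_template <- function(scaffold, template) {
  tpl <- reaction_templates()
  row <- tpl[tpl$name == template, ]
  if (nrow(row) != 1L) stop("unknown template '", template, "'")
  if (!identical(scaffold$group, row$group)) return(NULL)
  pfx <- scaffold$prefix; r2 <- scaffold$r2
  products <- switch(template,
    ester_hydrolysis = c(paste0(pfx, "C(=O)O"), paste0("O", r2)),
    amide_hydrolysis = c(paste0(pfx, "C(=O)O"), paste0("N", r2)),
    alcohol_oxidation = paste0(pfx, "C=O"),
    nitro_reduction = paste0(pfx, "N"),
    aromatic_halide_amination = paste0("Nc1ccc(", pfx, ")cc1"),
    O_demethylation = c(paste0(pfx, "O"), "C=O"))
  rxn <- canonicalize_reaction(
    paste0(scaffold$smiles, ">>", paste0(products, collapse = ".")),
    label = template)
  attr(rxn, "ec") <- row$pseudo_ec
  rxn
}

#' Generate a labeled benchmark corpus
#'
#' Produces, deterministically per seed: (a) a template-labeled reaction
#' corpus for classifier tests, (b) a stratified contrastive pair set via
#' [sample_pairs()], and (c) a pseudo-EC-annotated reference table for
#' association round trips. Duplicate reactions are removed after
#' canonicalization.
#'
#' @param n_per_class reactions per template (default 30).
#' @param templates template names (default all).
#' @param seed RNG seed.
#' @param pair_scheme a [bin_scheme()] for the pair file (default quotas
#'   10 per narrow bin, 40 for the last).
#' @param out_dir optional directory; when given, writes `reactions.tsv`,
#'   `pairs.tsv` and `reference.tsv` there.
#' @return list with `reactions` (list of labeled `crxnfp_reaction`),
#'   `pairs` (data.frame), `reference` (data.frame).
#' @export
make_benchmark <- function(n_per_class = 30L,
                           templates = reaction_templates()$name,
                           seed = 1L, pair_scheme = bin_scheme(10L),
                           out_dir = NULL) {
  tpl <- reaction_templates()
  tpl <- tpl[tpl$name %in% templates, ]
  reactions <- list()
  for (t in seq_len(nrow(tpl))) {
    # oversample scaffolds: duplicates collapse after canonicalization
    scaffolds <- generate_scaffolds(3L * n_per_class, seed + t,
                                    groups = tpl$group[t])
    made <- 0L
    for (sc in scaffolds) {
      if (made >= n_per_class) break
      rxn <- apply_template(sc, tpl$name[t])
      if (is.null(rxn)) next
      if (any(vapply(reactions, function(r) r$smiles == rxn$smiles, logical(1)))) next
      rxn$id <- paste0(tpl$name[t], "_", made + 1L)
      made <- made + 1L
      reactions[[length(reactions) + 1L]] <- rxn
    }
  }
  pairs <- sample_pairs(reactions, scheme = pair_scheme, seed = seed)
  reference <- data.frame(
    source_id = vapply(reactions, function(r) r$id, character(1)),
    reaction_smiles = vapply(reactions, function(r) r$smiles, character(1)),
    ec = vapply(reactions, function(r) attr(r, "ec"), character(1)),
    uniprot_accessions = "",
    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_reaction_table(reactions, file.path(out_dir, "reactions.tsv"))
    utils::write.table(pairs, file.path(out_dir, "pairs.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(reference, file.path(out_dir, "reference.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(reactions = reactions, pairs = pairs, reference = reference)
}
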
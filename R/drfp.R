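#' @importFrom ChemmineR smiles2sdf atomblock bondblock
NULL

# ---- molecular graph -------------------------------------------------------

# Parse one canonical SMILES into a light graph: element symbols, formal
# charges and a bond table (a1, a2, order). Bond orders come from the MDL
# (kekulized) connection table written by Open Babel.
.mol_graph <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elems <- sub("_.*$", "", rownames(ab))
  # MDL charge code column: 1..3 -> +3..+1, 5..7 -> -1..-3, 0/4 -> 0
  code <- if (ncol(ab) >= 5) as.integer(ab[, 5]) else integer(nrow(ab))
  charge <- integer(length(code))
  charge[code %in% 1:3] <- 4L - code[code %in% 1:3]
  charge[code %in% 5:7] <- 4L - code[code %in% 5:7]
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L) {
    matrix(integer(0), ncol = 3)  # bond-free molecule (single heavy atom)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  }
  n <- length(elems)
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (j in seq_len(nrow(bonds))) {
      a <- bonds[j, 1]; b <- bonds[j, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  list(elems = elems, charge = charge, bonds = bonds, adj = adj, n = n)
}

# Breadth-first atom distances from a center atom.
.bfs_dist <- function(g, center) {
  d <- rep(NA_integer_, g$n)
  d[center] <- 0L
  frontier <- center
  while (length(frontier)) {
    nxt <- integer(0)
    for (a in frontier) {
      for (b in g$adj[[a]]) {
        if (is.na(d[b])) {
          d[b] <- d[a] + 1L
          nxt <- c(nxt, b)
        }
      }
    }
    frontier <- nxt
  }
  d
}

# V2000 molfile text for a fragment (subset of atoms + bonds), with M CHG
# lines for formal charges; used to obtain a canonical SMILES per environment.
.fragment_molfile <- function(g, atoms, bond_rows) {
  idx <- match(seq_len(g$n), atoms)  # old -> new numbering
  na <- length(atoms)
  nb <- length(bond_rows)
  lines <- c("", " crxnfp fragment", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  for (a in atoms) {
    lines <- c(lines, sprintf(
      "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      g$elems[a]))
  }
  for (j in bond_rows) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              idx[g$bonds[j, 1]], idx[g$bonds[j, 2]],
                              g$bonds[j, 3]))
  }
  ch <- g$charge[atoms]
  chi <- which(ch != 0L)
  if (length(chi)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chi)),
                             paste0(sprintf("%4d%4d", chi, ch[chi]),
                                    collapse = "")))
  }
  c(lines, "M  END", "$$$$")
}

# cache: canonical SMILES + radius -> shingle set
.shingle_cache <- new.env(parent = emptyenv())

# heavy-atom count from SMILES tokens (bracket atoms and organic-subset
# element tokens; ring digits, bonds and branches are not atoms)
.n_heavy_atoms <- function(smiles) {
  toks <- tokenize_reaction(smiles)
  sum(grepl("^(\\[[^\\]]+\\]|Br|Cl|[BCNOPSFIbcnops])$", toks, perl = TRUE))
}

#' Circular substructure shingles of a molecule
#'
#' For every heavy atom and every radius `0..max_radius`, extracts the
#' atom-centered environment (all bonds whose nearer endpoint lies within
#' `radius - 1` of the center, together with their atoms) and converts it to a
#' canonical SMILES string. The result is the set (no multiplicity) of those
#' environment strings.
#'
#' @param smiles canonical SMILES of a single molecule.
#' @param max_radius maximum environment radius in bonds (default 2).
#' @return character vector: the sorted set of environment SMILES.
#' @export
#' @examples
#' \donttest{
#' circular_shingles("C", max_radius = 0)    # "C"
#' circular_shingles("CCO", max_radius = 1)
#' }
circular_shingles <- function(smiles, max_radius = 2L) {
  stopifnot(is.character(smiles), length(smiles) == 1L, max_radius >= 0L)
  key <- paste0(max_radius, "|", smiles)
  hit <- .shingle_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (.n_heavy_atoms(smiles) == 1L) {
    # a lone atom is its own (only) environment at every radius
    out <- canonicalize_smiles(smiles)
    .shingle_cache[[key]] <- out
    return(out)
  }
  g <- .mol_graph(smiles)
  blocks <- character(0)
  for (center in seq_len(g$n)) {
    d <- .bfs_dist(g, center)
    for (r in 0:max_radius) {
      atoms <- which(!is.na(d) & d <= r)
      bond_rows <- if (nrow(g$bonds)) {
        which(pmin(d[g$bonds[, 1]], d[g$bonds[, 2]]) <= r - 1L &
                !is.na(d[g$bonds[, 1]]) & !is.na(d[g$bonds[, 2]]) &
                d[g$bonds[, 1]] <= r & d[g$bonds[, 2]] <= r)
      } else integer(0)
      blocks <- c(blocks, .fragment_molfile(g, atoms, bond_rows))
    }
  }
  raw <- suppressWarnings(
    ChemmineOB::convertFormat("SDF", "CAN", paste0(blocks, collapse = "\n")))
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  frags <- sub("\t.*$", "", lines)
  frags <- frags[nzchar(frags)]
  out <- sort(unique(frags))
  .shingle_cache[[key]] <- out
  out
}

# ---- hashing ---------------------------------------------------------------

#' 32-bit FNV-1a hash of a string
#'
#' Stable, seedless string hash used to fold substructure shingles into a
#' fixed-length bit vector. Operates on UTF-8 bytes; identical across
#' platforms and sessions.
#'
#' @param s character vector.
#' @return numeric vector of hashes in `[0, 2^32)`.
#' @export
fnv1a32 <- function(s) {
  two32 <- 4294967296
  vapply(s, function(x) {
    bytes <- utf8ToInt(enc2utf8(x))
    h <- 2166136261
    for (b in bytes) {
      h <- bitwXor2_32(h, b)
      # h * 16777619 mod 2^32, split to stay within double precision
      h1 <- h %/% 65536
      h0 <- h %% 65536
      h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% two32
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# xor for values in [0, 2^32) held in doubles
bitwXor2_32 <- function(a, b) {
  hi_a <- a %/% 2147483648; lo_a <- a %% 2147483648
  hi_b <- b %/% 2147483648; lo_b <- b %% 2147483648
  lo <- bitwXor(as.integer(lo_a), as.integer(lo_b))
  hi <- (hi_a + hi_b) %% 2
  hi * 2147483648 + lo
}

# ---- differential reaction fingerprint -------------------------------------

#' Differential reaction fingerprint (drfp)
#'
#' Computes the symmetric difference between the circular-substructure shingle
#' sets of the reactant side and the product side (each side the union over
#' its components), then hashes every surviving shingle with FNV-1a and folds
#' modulo `n_bits` into a binary fingerprint. A reaction whose two sides have
#' identical shingle sets (no net structural change) yields an empty
#' fingerprint flagged as degenerate.
#'
#' @param reaction a `crxnfp_reaction` (agents are ignored).
#' @param max_radius maximum shingle radius (default 2).
#' @param n_bits fingerprint length (default 2048).
#' @return an object of class `crxnfp_fp`: list with `n_bits`, `on_bits`
#'   (sorted 0-based indices), `shingles` (the symmetric-difference set) and
#'   `degenerate` flag.
#' @export
#' @examples
#' \donttest{
#' fp <- drfp(canonicalize_reaction("CCO>>CC=O"), n_bits = 64)
#' fp$on_bits
#' }
drfp <- function(reaction, max_radius = 2L, n_bits = 2048L) {
  stopifnot(inherits(reaction, "crxnfp_reaction"), n_bits >= 1L)
  side_shingles <- function(comps) {
    out <- character(0)
    for (s in comps) out <- c(out, circular_shingles(s, max_radius))
    unique(out)
  }
  r <- side_shingles(reaction$reactants)
  p <- side_shingles(reaction$products)
  sym <- sort(union(setdiff(r, p), setdiff(p, r)))
  on <- if (length(sym)) sort(unique(fnv1a32(sym) %% n_bits)) else numeric(0)
  structure(list(n_bits = as.integer(n_bits), on_bits = as.integer(on),
                 shingles = sym, degenerate = length(sym) == 0L),
            class = "crxnfp_fp")
}

#' @export
print.crxnfp_fp <- function(x, ...) {
  cat("<drfp ", x$n_bits, " bits, ", length(x$on_bits), " on",
      if (x$degenerate) ", degenerate" else "", ">\n", sep = "")
  invisible(x)
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|A intersect B| / |A union B|` over on-bits. Both fingerprints must have
#' the same length and neither may be degenerate (an all-zero pair has no
#' defined similarity and is rejected rather than silently scored).
#'
#' @param a,b `crxnfp_fp` fingerprints.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "crxnfp_fp"), inherits(b, "crxnfp_fp"))
  if (a$n_bits != b$n_bits) stop("fingerprint lengths differ")
  if (a$degenerate && b$degenerate) {
    stop("both fingerprints are degenerate (empty); Tanimoto undefined")
  }
  inter <- length(intersect(a$on_bits, b$on_bits))
  uni <- length(union(a$on_bits, b$on_bits))
  inter / uni
}

#' Hex encoding of a fingerprint bitset
#'
#' @param fp a `crxnfp_fp`.
#' @return a hex string of `n_bits / 4` characters (bit 0 is the least
#'   significant bit of the last hex digit).
#' @export
fp_to_hex <- function(fp) {
  stopifnot(inherits(fp, "crxnfp_fp"))
  bits <- integer(fp$n_bits)
  bits[fp$on_bits + 1L] <- 1L
  nyb <- ceiling(fp$n_bits / 4)
  out <- character(nyb)
  for (i in seq_len(nyb)) {
    lo <- (i - 1L) * 4L
    v <- sum(bits[lo + 1:4] * c(1L, 2L, 4L, 8L), na.rm = TRUE)
    out[i] <- format.hexmode(v)
  }
  paste0(rev(out), collapse = "")
}
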
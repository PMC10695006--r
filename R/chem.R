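# Chemistry predicates for disassembled-cage components.
#
# SMILES parsing and canonicalisation go through OpenBabel (ChemmineOB);
# molecular graphs are recovered from the V2000 connection table
# (ChemmineR); automorphism generators come from igraph's BLISS backend.

# Characters a BB2 SMILES may contain after surrogate collapse. OpenBabel
# silently repairs some malformed strings (e.g. unbalanced branches), so a
# syntactic screen runs before the semantic parse.
.smiles_syntax_ok <- function(smiles) {
  if (!nzchar(smiles)) return(FALSE)
  toks <- tryCatch(smiles_tokens(smiles), error = function(e) NULL)
  if (is.null(toks) || !length(toks)) return(FALSE)
  if (paste(toks, collapse = "") != smiles) return(FALSE)
  # branch balance, no empty branches
  depth <- 0L
  prev <- ""
  for (tk in toks) {
    if (tk == "(") depth <- depth + 1L
    if (tk == ")") {
      depth <- depth - 1L
      if (depth < 0L || prev == "(") return(FALSE)
    }
    prev <- tk
  }
  if (depth != 0L) return(FALSE)
  # ring-closure digits must pair up
  digs <- toks[grepl("^[0-9]$|^%[0-9]{2}$", toks)]
  if (length(digs) && any(table(digs) %% 2L != 0L)) return(FALSE)
  # token inventory: bracket atoms, elements, bonds, branches, digits
  ok <- grepl(
    "^(\\[[^\\]]+\\]|Br|Cl|Si|[BCNOPSFIbcnops]|[0-9]|%[0-9]{2}|[-=#:/\\\\().@+])$",
    toks, perl = TRUE)
  all(ok)
}

.ob_convert <- function(from, to, source) {
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, source = source),
    error = function(e) ""
  )
  if (is.null(out) || is.na(out)) "" else out
}

#' Test whether a BB2 SMILES string is chemically valid
#'
#' A string is valid when it passes a syntactic screen (known token
#' inventory, balanced branches, paired ring closures) and OpenBabel parses
#' it into a non-empty molecule.
#'
#' @param smiles a SMILES string.
#' @return logical scalar.
#' @export
is_valid_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    return(FALSE)
  }
  if (!.smiles_syntax_ok(smiles)) return(FALSE)
  nzchar(trimws(.ob_convert("SMI", "CAN", smiles)))
}

#' Canonical SMILES form
#'
#' @param smiles a valid SMILES string.
#' @return the OpenBabel canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  if (!is_valid_smiles(smiles)) stop("not a valid SMILES: ", smiles)
  trimws(.ob_convert("SMI", "CAN", smiles))
}

#' Count reactive-site placeholder tokens in a BB2 skeleton
#'
#' A generated BB2 is precursor-valid if and only if it parses and carries
#' exactly two `[Lr]` site tokens.
#'
#' @param smiles a BB2 SMILES string.
#' @return non-negative integer count of `[Lr]` tokens.
#' @export
count_reaction_sites <- function(smiles) {
  if (!is_valid_smiles(smiles)) stop("unparseable SMILES: ", smiles)
  sum(smiles_tokens(smiles) == "[Lr]")
}

#' Precursor validity of a BB2 skeleton
#'
#' @param smiles a BB2 SMILES string.
#' @return TRUE iff the string parses and has exactly two site tokens.
#' @export
is_precursor_valid <- function(smiles) {
  is_valid_smiles(smiles) && count_reaction_sites(smiles) == 2L
}

# Heavy-atom molecular graph of a SMILES string (atom order preserved from
# the string). Returns element vector, aromatic-atom flags (lowercase atoms
# in the SMILES) and a bond data frame (i, j, order).
mol_graph <- function(smiles) {
  sdf_txt <- .ob_convert("SMI", "SDF", smiles)
  if (!nzchar(trimws(sdf_txt))) stop("cannot build molecular graph: ", smiles)
  lines <- strsplit(sdf_txt, "\n", fixed = TRUE)[[1]]
  sstr <- methods::new(methods::getClassDef("SDFstr", package = "ChemmineR"),
                       a = list(lines))
  sset <- suppressMessages(methods::as(sstr, "SDFset"))
  sdf <- sset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  atom_toks <- smiles_tokens(smiles)
  atom_pat <- "^(\\[[^\\]]+\\]|Br|Cl|Si|[BCNOPSFIbcnops])$"
  atom_toks <- atom_toks[grepl(atom_pat, atom_toks, perl = TRUE)]
  aromatic <- grepl("^[bcnops]$|^\\[[0-9]*[bcnops]", atom_toks, perl = TRUE)
  if (length(aromatic) != length(elements)) {
    # fall back: no aromatic flags when the atom count cannot be aligned
    aromatic <- rep(FALSE, length(elements))
  }
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  list(elements = elements, aromatic = aromatic, bonds = bonds)
}

# Bond colours: kekulised orders from the connection table, with bonds
# between two aromatic atoms that sit on a cycle recoloured as "aromatic"
# so that alternative Kekule assignments cannot break graph symmetry.
.bond_colors <- function(g) {
  n <- length(g$elements)
  ig <- igraph::make_graph(edges = as.vector(rbind(g$bonds$i, g$bonds$j)),
                           n = n, directed = FALSE)
  bridges <- igraph::bridges(ig)
  in_cycle <- !(seq_len(nrow(g$bonds)) %in% as.integer(bridges))
  col <- g$bonds$order
  arom <- g$aromatic[g$bonds$i] & g$aromatic[g$bonds$j] & in_cycle
  col[arom] <- 99L
  col
}

#' Atom symmetry classes (automorphism orbits) of a BB2 molecular graph
#'
#' Computes the orbit partition of the heavy-atom molecular graph under
#' colour-preserving graph automorphisms (vertex colour = element, edge
#' colour = bond order with aromatic bonds as their own class). Bond colours
#' are encoded by subdividing each bond with an auxiliary coloured vertex,
#' so the BLISS vertex-colour machinery respects them.
#'
#' @param smiles a valid SMILES string.
#' @return integer vector of orbit labels, one per heavy atom, in SMILES
#'   atom order.
#' @export
atom_orbits <- function(smiles) {
  g <- mol_graph(smiles)
  n <- length(g$elements)
  if (n == 1L) return(1L)
  bcol <- .bond_colors(g)
  nb <- nrow(g$bonds)
  # atoms 1..n, auxiliary bond vertices n+1..n+nb
  edges <- integer(0)
  for (k in seq_len(nb)) {
    edges <- c(edges, g$bonds$i[k], n + k, g$bonds$j[k], n + k)
  }
  ig <- igraph::make_graph(edges = edges, n = n + nb, directed = FALSE)
  vcol <- c(as.integer(factor(g$elements)),
            1000L + as.integer(factor(bcol)))
  gens <- igraph::automorphism_group(ig, colors = vcol)
  # orbits = connected components of the Schreier graph over the generators
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in gens) {
    p <- as.integer(p)[seq_len(n)]
    for (v in seq_len(n)) {
      a <- find(v); b <- find(p[v])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  as.integer(factor(roots))
}

#' Graph-symmetry test for a BB2 skeleton
#'
#' A di-topic edge precursor approximates the desired C2 molecular symmetry
#' when its two reactive sites fall in the same symmetry class
#' (graph-automorphism orbit) of the canonical form's molecular graph.
#'
#' @param smiles a precursor-valid BB2 SMILES (exactly two `[Lr]` tokens).
#' @return logical scalar.
#' @export
is_symmetric_bb2 <- function(smiles) {
  if (!is_precursor_valid(smiles)) {
    stop("not a precursor-valid BB2 (need parseable SMILES with exactly two [Lr] sites): ",
         smiles)
  }
  can <- canonical_smiles(smiles)
  g <- mol_graph(can)
  sites <- which(g$elements == "Lr")
  if (length(sites) != 2L) stop("site atoms not recovered from: ", can)
  orb <- atom_orbits(can)
  orb[sites[1]] == orb[sites[2]]
}
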
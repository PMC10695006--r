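# Synthetic cage fixtures.
#
# A grammar over divalent cores (arenes, heteroarenes, chains) and
# mirror-paired linker arms assembles BB2 skeletons that are guaranteed
# parseable with exactly two [Lr] sites; the symmetric fraction places the
# same arm on both mirror-equivalent attachment points of a symmetric
# core, so the C2 graph-symmetry predicate holds by construction.
# Labels follow a deterministic rule over the disassembled representation
# so that predictor recovery is a meaningful test.

# mirror-paired arms: `l` is written site->core, `r` core->site.
# `sig` distinguishes arm structures; two arms with different sig on the
# two ends of a core give structurally distinct site environments.
.bb2_arms <- list(
  list(l = "",      r = "",      sig = "0"),
  list(l = "C",     r = "C",     sig = "C1"),
  list(l = "CC",    r = "CC",    sig = "C2"),
  list(l = "CCC",   r = "CCC",   sig = "C3"),
  list(l = "C#C",   r = "C#C",   sig = "Y"),
  list(l = "C=C",   r = "C=C",   sig = "E"),
  list(l = "OC",    r = "CO",    sig = "OC"),
  list(l = "COC",   r = "COC",   sig = "COC"),
  list(l = "C(=O)", r = "C(=O)", sig = "ACY")
)

# core templates; {L} = "[Lr]" + left arm, {R} = right arm + "[Lr]".
# `sym` marks cores whose two attachment points are mirror-equivalent.
.bb2_cores <- list(
  list(t = "{L}c1ccc({R})cc1",                 sym = TRUE),   # para-arene
  list(t = "{L}c1cccc({R})c1",                 sym = TRUE),   # meta-arene
  list(t = "{L}c1ccc({R})o1",                  sym = TRUE),   # 2,5-furan
  list(t = "{L}c1ccc({R})s1",                  sym = TRUE),   # 2,5-thiophene
  list(t = "{L}c1cccc({R})n1",                 sym = TRUE),   # 2,6-pyridine
  list(t = "{L}C#C{R}",                        sym = TRUE),   # ethynylene
  list(t = "{L}CC{R}",                         sym = TRUE),   # ethylene
  list(t = "{L}c1ccc(-c2ccc({R})cc2)cc1",      sym = TRUE),   # 4,4'-biphenyl
  list(t = "{L}c1cc({R})cs1",                  sym = FALSE),  # 2,4-thiophene
  list(t = "{L}c1ccc({R})cn1",                 sym = FALSE)   # 2,5-pyridine
)

.assemble_bb2 <- function(core, arm_l, arm_r) {
  s <- sub("{L}", paste0("[Lr]", arm_l$l), core$t, fixed = TRUE)
  sub("{R}", paste0(arm_r$r, "[Lr]"), s, fixed = TRUE)
}

.bb2_heavy_atoms <- function(smiles) {
  g <- mol_graph(smiles)
  sum(g$elements != "Lr")
}

.bb2_has_ring <- function(smiles) {
  g <- mol_graph(smiles)
  nrow(g$bonds) >= length(g$elements)  # connected molecule: |E| >= |V|
}

# chain cores fuse with pure-chain arms: different arms can still yield a
# mirror-symmetric molecule (e.g. "" + C on -CC- gives [Lr]CCC[Lr]), so
# those pairs are kept out of the asymmetric stratum.
.degenerate_pair <- function(core_t, sig_i, sig_j) {
  chain_c <- c("0", "C1", "C2", "C3")
  (core_t == "{L}CC{R}" && sig_i %in% chain_c && sig_j %in% chain_c) ||
    (core_t == "{L}C#C{R}" && all(c(sig_i, sig_j) %in% c("0", "Y")))
}

# enumerate the full symmetric / asymmetric product spaces
.enumerate_grammar <- function() {
  sym <- character(0); asym <- character(0)
  for (core in .bb2_cores) {
    for (i in seq_along(.bb2_arms)) {
      for (j in seq_along(.bb2_arms)) {
        si <- .bb2_arms[[i]]$sig; sj <- .bb2_arms[[j]]$sig
        s <- .assemble_bb2(core, .bb2_arms[[i]], .bb2_arms[[j]])
        if (core$sym && si == sj) {
          if (i == j) sym <- c(sym, s)
        } else if (core$sym) {
          if (i < j && !.degenerate_pair(core$t, si, sj)) {
            asym <- c(asym, s)  # one orientation is enough
          }
        } else {
          if (i <= j) asym <- c(asym, s)
        }
      }
    }
  }
  list(sym = unique(sym), asym = unique(asym))
}

#' Grammar-generated BB2 skeletons
#'
#' Assembles di-topic skeleton SMILES from cores and mirror-paired arms.
#' Every output parses and carries exactly two `[Lr]` sites; the first
#' `round(n * symmetric_fraction)` are built mirror-symmetrically so the
#' graph-symmetry predicate holds for them by construction.
#'
#' @param n number of distinct skeletons.
#' @param symmetric_fraction fraction assembled symmetrically.
#' @param rng_seed seed controlling the (deterministic) sampling.
#' @param max_heavy_atoms optional cap on the heavy-atom count (site
#'   placeholders excluded).
#' @return character vector of `n` distinct BB2 SMILES; attribute
#'   `symmetric` carries the by-construction flags.
#' @export
make_bb2_grammar <- function(n, symmetric_fraction = 0.8, rng_seed = 1L,
                             max_heavy_atoms = Inf) {
  stopifnot(n >= 1, symmetric_fraction >= 0, symmetric_fraction <= 1)
  pool <- .enumerate_grammar()
  if (is.finite(max_heavy_atoms)) {
    keep <- function(v) {
      v[vapply(v, .bb2_heavy_atoms, 1L) <= max_heavy_atoms]
    }
    pool$sym <- keep(pool$sym); pool$asym <- keep(pool$asym)
  }
  n_sym <- round(n * symmetric_fraction)
  n_asym <- n - n_sym
  if (n_sym > length(pool$sym) || n_asym > length(pool$asym)) {
    stop(sprintf(
      "grammar exhausted: requested %d symmetric / %d asymmetric, have %d / %d",
      n_sym, n_asym, length(pool$sym), length(pool$asym)))
  }
  set.seed(rng_seed)
  out <- c(sample(pool$sym, n_sym), sample(pool$asym, n_asym))
  attr(out, "symmetric") <- rep(c(TRUE, FALSE), c(n_sym, n_asym))
  out
}

# fixed fixture pools; catalogs take the first n entries
.fixture_bb1_pool <- c(
  "Cc1cc(C)cc(C)c1",
  "OCc1cc(CO)cc(CO)c1",
  "Nc1cc(N)cc(N)c1",
  "O=Cc1cc(C=O)cc(C=O)c1",
  "C(c1ccccc1)(c1ccccc1)c1ccccc1",
  "CC(CN)(CN)CN",
  "Oc1cc(O)cc(O)c1",
  "C#Cc1cc(C#C)cc(C#C)c1"
)

.fixture_reaction_pool <- c(
  "alkyne_metathesis",
  "aldehyde2amine3",
  "amide_condensation",
  "alkene_metathesis",
  "imine_condensation",
  "boronic_ester"
)

#' Specification of a synthetic cage dataset
#'
#' The deterministic label rule declares a cage collapsed iff its BB2
#' skeleton has fewer than `heavy_atom_threshold` heavy atoms OR contains
#' no ring — except when the reaction is the designated rigid type, which
#' always yields a shape-persistent cage (mimicking the empirical
#' robustness of alkyne metathesis).
#'
#' @param n_bb1,n_reactions,n_bb2 catalog sizes.
#' @param n_cages number of cage records.
#' @param unlabeled_fraction fraction of labels blanked.
#' @param symmetric_fraction fraction of BB2 skeletons built symmetric.
#' @param heavy_atom_threshold label-rule size threshold.
#' @param rigid_reaction_id 0-based ordinal of the rigid reaction (NA to
#'   disable the exception).
#' @param rng_seed master seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_bb1 = 4L, n_reactions = 3L, n_bb2 = 60L,
                         n_cages = 500L, unlabeled_fraction = 0.3,
                         symmetric_fraction = 0.8,
                         heavy_atom_threshold = 9L,
                         rigid_reaction_id = 0L, rng_seed = 1L) {
  spec <- list(n_bb1 = as.integer(n_bb1),
               n_reactions = as.integer(n_reactions),
               n_bb2 = as.integer(n_bb2), n_cages = as.integer(n_cages),
               unlabeled_fraction = unlabeled_fraction,
               symmetric_fraction = symmetric_fraction,
               heavy_atom_threshold = as.integer(heavy_atom_threshold),
               rigid_reaction_id = rigid_reaction_id,
               rng_seed = as.integer(rng_seed))
  stopifnot(spec$n_bb1 >= 1, spec$n_bb1 <= length(.fixture_bb1_pool),
            spec$n_reactions >= 1,
            spec$n_reactions <= length(.fixture_reaction_pool),
            spec$n_bb2 >= 1, spec$n_cages >= 1,
            unlabeled_fraction >= 0, unlabeled_fraction <= 1,
            symmetric_fraction >= 0, symmetric_fraction <= 1)
  class(spec) <- "fixture_spec"
  spec
}

#' Evaluate the deterministic shape-persistence label rule
#'
#' @param bb2_smiles,reaction_id record fields.
#' @param spec a [fixture_spec()].
#' @return character vector over \{collapsed, not_collapsed\}.
#' @export
fixture_label_rule <- function(bb2_smiles, reaction_id, spec) {
  heavy <- vapply(bb2_smiles, .bb2_heavy_atoms, 1L, USE.NAMES = FALSE)
  ring <- vapply(bb2_smiles, .bb2_has_ring, TRUE, USE.NAMES = FALSE)
  fragile <- heavy < spec$heavy_atom_threshold | !ring
  rigid <- !is.na(spec$rigid_reaction_id) &
    reaction_id == spec$rigid_reaction_id
  ifelse(fragile & !rigid, "collapsed", "not_collapsed")
}

#' Generate a synthetic cage dataset
#'
#' Builds fixture BB1/reaction catalogs, a grammar-generated BB2 pool,
#' enumerates cages, labels them with the deterministic rule and blanks
#' the requested unlabeled fraction.
#'
#' @param spec a [fixture_spec()].
#' @return list with `records` (`cage_records`), `bb1`, `reactions`
#'   (catalogs), `bb2_pool` and the `spec`.
#' @export
make_dataset <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  bb1 <- bb1_catalog(.fixture_bb1_pool[seq_len(spec$n_bb1)])
  reactions <- reaction_catalog(
    .fixture_reaction_pool[seq_len(spec$n_reactions)])
  bb2_pool <- make_bb2_grammar(spec$n_bb2, spec$symmetric_fraction,
                               rng_seed = spec$rng_seed)
  records <- enumerate_cages(bb1, as.character(bb2_pool), reactions,
                             max_count = spec$n_cages,
                             rng_seed = spec$rng_seed)
  records$label <- fixture_label_rule(records$bb2_smiles,
                                      records$reaction_id, spec)
  if (spec$unlabeled_fraction > 0) {
    set.seed(spec$rng_seed + 1L)
    n_blank <- round(spec$unlabeled_fraction * nrow(records))
    records$label[sample.int(nrow(records), n_blank)] <- "unlabeled"
  }
  list(records = records, bb1 = bb1, reactions = reactions,
       bb2_pool = bb2_pool, spec = spec)
}

#' Search the label-rule threshold for a target class balance
#'
#' Scans `heavy_atom_threshold` values and returns the spec whose collapsed
#' fraction (before blanking) is closest to `target`; errors if no
#' threshold lands within `tol`.
#'
#' @param spec a [fixture_spec()]; @param target desired collapsed
#' fraction; @param tol acceptable deviation (default 0.05).
#' @return a recalibrated `fixture_spec`.
#' @export
calibrate_label_rule <- function(spec, target, tol = 0.05) {
  bb2_pool <- make_bb2_grammar(spec$n_bb2, spec$symmetric_fraction,
                               rng_seed = spec$rng_seed)
  bb1 <- bb1_catalog(.fixture_bb1_pool[seq_len(spec$n_bb1)])
  reactions <- reaction_catalog(
    .fixture_reaction_pool[seq_len(spec$n_reactions)])
  records <- enumerate_cages(bb1, as.character(bb2_pool), reactions,
                             max_count = spec$n_cages,
                             rng_seed = spec$rng_seed)
  heavy <- vapply(records$bb2_smiles, .bb2_heavy_atoms, 1L,
                  USE.NAMES = FALSE)
  best <- NULL; best_gap <- Inf
  for (thr in seq(min(heavy), max(heavy) + 1L)) {
    s2 <- spec; s2$heavy_atom_threshold <- as.integer(thr)
    frac <- mean(fixture_label_rule(records$bb2_smiles,
                                    records$reaction_id, s2) == "collapsed")
    gap <- abs(frac - target)
    if (gap < best_gap) { best <- s2; best_gap <- gap }
  }
  if (best_gap > tol) {
    stop(sprintf("no threshold reaches collapsed fraction %.2f +/- %.2f (best gap %.3f)",
                 target, tol, best_gap))
  }
  best
}
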
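# Two-step combinatorial augmentation: (1) assemble new di-topic BB2
# skeletons from a fragment library (divalent cores x mirror-paired arms,
# optionally decorated with monovalent substituents at mirror-equivalent
# ring positions), (2) enumerate hypothetical unlabeled cages over the
# enlarged BB2 pool. BB1 and reaction catalogs are never touched.

# decorated symmetric core: substituent D at both positions flanking the
# para axis, so mirror symmetry survives decoration.
.decorated_cores <- list(
  list(t = "{L}c1cc({D})c({R})c({D})c1", sym = TRUE),
  list(t = "{L}c1c({D})ccc({R})c1",      sym = FALSE)
)

#' Fragment library for BB2 augmentation
#'
#' @param cores list of divalent core templates (fields `t` with `{L}`,
#'   `{R}` and optionally `{D}` slots, and `sym`); defaults to the built-in
#'   grammar cores plus decorated arenes.
#' @param decorations character vector of monovalent substituent SMILES
#'   fragments for the `{D}` slots.
#' @return a `fragment_library` list.
#' @export
fragment_library <- function(cores = NULL, decorations = NULL) {
  if (is.null(cores)) cores <- c(.bb2_cores, .decorated_cores)
  if (is.null(decorations)) {
    decorations <- c("C", "F", "O", "OC", "N", "C#N", "Cl")
  }
  structure(list(cores = cores, arms = .bb2_arms,
                 decorations = decorations),
            class = "fragment_library")
}

.assemble_library_bb2 <- function(core, arm_l, arm_r, dec = NULL) {
  s <- .assemble_bb2(core, arm_l, arm_r)
  if (grepl("{D}", s, fixed = TRUE)) {
    if (is.null(dec)) return(NA_character_)
    s <- gsub("{D}", dec, s, fixed = TRUE)
  }
  s
}

# deterministic enumeration of the library product space
.enumerate_library <- function(library) {
  out <- character(0); sym <- logical(0)
  for (core in library$cores) {
    decs <- if (grepl("{D}", core$t, fixed = TRUE)) {
      library$decorations
    } else NA_character_
    for (dec in decs) {
      for (i in seq_along(library$arms)) {
        for (j in seq_along(library$arms)) {
          if (core$sym && i > j) next
          si <- library$arms[[i]]$sig; sj <- library$arms[[j]]$sig
          if (core$sym && si != sj && .degenerate_pair(core$t, si, sj)) next
          s <- .assemble_library_bb2(core, library$arms[[i]],
                                     library$arms[[j]],
                                     if (is.na(dec)) NULL else dec)
          if (is.na(s)) next
          out <- c(out, s)
          same <- library$arms[[i]]$sig == library$arms[[j]]$sig
          sym <- c(sym, core$sym && same)
        }
      }
    }
  }
  keep <- !duplicated(out)
  list(smiles = out[keep], sym = sym[keep])
}

#' Combinatorially enlarge a BB2 skeleton pool
#'
#' Returns `target_count` distinct precursor-valid BB2 skeletons: all the
#' seeds plus library-assembled products, sampled under the seed with
#' symmetric products preferred at the requested fraction. Distinctness is
#' judged on canonical SMILES.
#'
#' @param seed_bb2s character vector of existing BB2 skeletons.
#' @param library a [fragment_library()].
#' @param target_count desired pool size (>= number of seeds).
#' @param rng_seed seed.
#' @param symmetric_fraction preferred fraction of symmetric products among
#'   the newly added skeletons.
#' @return character vector of `target_count` BB2 SMILES (seeds first).
#' @export
augment_bb2_pool <- function(seed_bb2s, library = fragment_library(),
                             target_count, rng_seed = 1L,
                             symmetric_fraction = 0.8) {
  seed_bb2s <- as.character(seed_bb2s)
  stopifnot(target_count >= length(seed_bb2s))
  if (target_count == length(seed_bb2s)) return(seed_bb2s)
  seed_keys <- vapply(seed_bb2s, canonical_smiles, "", USE.NAMES = FALSE)
  pool <- .enumerate_library(library)
  valid <- vapply(pool$smiles, is_precursor_valid, TRUE, USE.NAMES = FALSE)
  pool$smiles <- pool$smiles[valid]; pool$sym <- pool$sym[valid]
  keys <- vapply(pool$smiles, canonical_smiles, "", USE.NAMES = FALSE)
  fresh <- !(keys %in% seed_keys) & !duplicated(keys)
  cand <- data.frame(smiles = pool$smiles[fresh], sym = pool$sym[fresh],
                     stringsAsFactors = FALSE)
  need <- target_count - length(seed_bb2s)
  if (nrow(cand) < need) {
    stop(sprintf("fragment library too small: need %d new skeletons, can assemble %d",
                 need, nrow(cand)))
  }
  set.seed(rng_seed)
  n_sym <- min(round(need * symmetric_fraction), sum(cand$sym))
  n_asym <- need - n_sym
  if (n_asym > sum(!cand$sym)) {  # rebalance if one stratum is short
    n_asym <- sum(!cand$sym); n_sym <- need - n_asym
  }
  pick_sym <- sample(which(cand$sym), n_sym)
  pick_asym <- sample(which(!cand$sym), n_asym)
  c(seed_bb2s, cand$smiles[sort(c(pick_sym, pick_asym))])
}

#' Enumerate hypothetical unlabeled cages
#'
#' Samples `max_count` distinct (BB1, BB2, reaction) combinations without
#' replacement from the full cartesian product, uniformly under the seed.
#'
#' @param bb1_catalog a `bb1_catalog`.
#' @param bb2_pool character vector of BB2 skeletons.
#' @param reactions a `reaction_catalog`.
#' @param max_count number of cages (at most `|BB1| * |BB2| * |reactions|`).
#' @param rng_seed seed.
#' @return unlabeled `cage_records`.
#' @export
enumerate_cages <- function(bb1_catalog, bb2_pool, reactions, max_count,
                            rng_seed = 1L) {
  stopifnot(inherits(bb1_catalog, "bb1_catalog"),
            inherits(reactions, "reaction_catalog"),
            length(bb2_pool) >= 1)
  n1 <- bb1_catalog$n; n2 <- length(bb2_pool); n3 <- reactions$n
  total <- as.double(n1) * n2 * n3
  if (max_count > total) {
    stop(sprintf("max_count %d exceeds the %d available combinations",
                 max_count, as.integer(total)))
  }
  set.seed(rng_seed)
  idx <- sample.int(total, max_count) - 1
  bb1_id <- idx %% n1
  bb2_i <- (idx %/% n1) %% n2
  rxn_id <- idx %/% (n1 * n2)
  cage_records(bb1_id, bb2_pool[bb2_i + 1], rxn_id, "unlabeled")
}

#' Write / read a fragment library as JSON
#'
#' @param library a `fragment_library`; @param path file path.
#' @name fragment_library_json
#' @export
write_fragment_library_json <- function(library, path) {
  jsonlite::write_json(
    list(cores = lapply(library$cores, function(cr) {
           list(template = cr$t, symmetric = cr$sym)
         }),
         arms = lapply(library$arms, function(a) a[c("l", "r", "sig")]),
         decorations = library$decorations),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname fragment_library_json
#' @export
read_fragment_library_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  lib <- fragment_library(
    cores = lapply(x$cores, function(cr) {
      list(t = cr$template, sym = isTRUE(cr$symmetric))
    }),
    decorations = unlist(x$decorations))
  lib$arms <- lapply(x$arms, function(a) {
    list(l = a$l, r = a$r, sig = a$sig)
  })
  lib
}
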
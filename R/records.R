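# Disassembled cage records and their catalogs.
#
# A Tri4Di6 cage is stored disassembled: a tri-topic vertex precursor (BB1,
# ordinal into a skeleton catalog), a di-topic edge precursor (BB2, SMILES
# with two [Lr] site tokens) and the dynamic covalent reaction type
# (ordinal). Shape-persistence labels are ternary:
# collapsed / not_collapsed / unlabeled.

.label_levels <- c("collapsed", "not_collapsed", "unlabeled")

#' Build a BB1 skeleton catalog
#'
#' @param skeletons character vector of tri-topic skeleton SMILES; order
#'   defines the 0-based ordinal ids used everywhere else.
#' @return a `bb1_catalog` object.
#' @export
bb1_catalog <- function(skeletons) {
  skeletons <- as.character(skeletons)
  stopifnot(length(skeletons) >= 1L, !anyDuplicated(skeletons))
  for (s in skeletons) {
    if (!is_valid_smiles(s)) stop("unparseable BB1 skeleton: ", s)
  }
  structure(list(skeletons = skeletons, n = length(skeletons)),
            class = "bb1_catalog")
}

#' Build a reaction-type catalog
#'
#' @param names character vector of reaction tags (e.g. "aldehyde2amine3");
#'   order defines 0-based ordinal ids.
#' @return a `reaction_catalog` object.
#' @export
reaction_catalog <- function(names) {
  names <- as.character(names)
  stopifnot(length(names) >= 1L, !anyDuplicated(names))
  structure(list(names = names, n = length(names)),
            class = "reaction_catalog")
}

#' Normalise a raw shape-persistence label
#'
#' "undetermined" cages are relabelled "collapsed" (removing label ambiguity
#' and making the target binary); missing/empty labels become "unlabeled".
#'
#' @param label character vector of raw labels.
#' @return character vector over \{collapsed, not_collapsed, unlabeled\}.
#' @export
relabel <- function(label) {
  raw <- tolower(trimws(as.character(label)))
  raw[is.na(label) | raw == ""] <- "unlabeled"
  map <- c(collapsed       = "collapsed",
           undetermined    = "collapsed",
           "non-collapsed" = "not_collapsed",
           "not collapsed" = "not_collapsed",
           not_collapsed   = "not_collapsed",
           unlabeled       = "unlabeled")
  unknown <- setdiff(unique(raw), names(map))
  if (length(unknown)) {
    stop("unknown label value(s): ", paste(unknown, collapse = ", "))
  }
  unname(map[raw])
}

#' Construct a table of disassembled cage records
#'
#' @param bb1_id integer vector of 0-based BB1 catalog ordinals.
#' @param bb2_smiles character vector of BB2 skeleton SMILES.
#' @param reaction_id integer vector of 0-based reaction ordinals.
#' @param label raw labels (passed through [relabel()]); default unlabeled.
#' @return a data.frame of class `cage_records`.
#' @export
cage_records <- function(bb1_id, bb2_smiles, reaction_id,
                         label = "unlabeled") {
  df <- data.frame(
    bb1_id = as.integer(bb1_id),
    bb2_smiles = as.character(bb2_smiles),
    reaction_id = as.integer(reaction_id),
    label = relabel(rep_len(label, length(bb1_id))),
    stringsAsFactors = FALSE
  )
  stopifnot(all(df$bb1_id >= 0L), all(df$reaction_id >= 0L))
  class(df) <- c("cage_records", "data.frame")
  df
}

#' Canonical identity key of a cage record
#'
#' Two records are the same cage iff they share the BB1 ordinal, the
#' canonical form of the BB2 skeleton and the reaction ordinal. Used for
#' novelty and uniqueness bookkeeping.
#'
#' @param bb1_id,bb2_smiles,reaction_id vectors describing records (or pass
#'   a `cage_records` data.frame as the single first argument).
#' @return character vector of keys.
#' @export
cage_key <- function(bb1_id, bb2_smiles = NULL, reaction_id = NULL) {
  if (is.data.frame(bb1_id)) {
    df <- bb1_id
    bb1_id <- df$bb1_id; bb2_smiles <- df$bb2_smiles
    reaction_id <- df$reaction_id
  }
  can <- vapply(as.character(bb2_smiles), canonical_smiles, "",
                USE.NAMES = FALSE)
  paste(as.integer(bb1_id), can, as.integer(reaction_id), sep = "|")
}

#' Write / read cage records as CSV
#'
#' Columns: `bb1_id`, `bb2_smiles`, `reaction`, `label` (empty string for
#' unlabeled). SMILES fields are quoted and never wrapped.
#'
#' @param records a `cage_records` data.frame.
#' @param path file path.
#' @name cage_csv
#' @export
write_cage_csv <- function(records, path) {
  out <- data.frame(
    bb1_id = records$bb1_id,
    bb2_smiles = records$bb2_smiles,
    reaction = records$reaction_id,
    label = ifelse(records$label == "unlabeled", "", records$label),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = 2L,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname cage_csv
#' @export
read_cage_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(bb2_smiles = "character",
                                       label = "character"),
                        fileEncoding = "UTF-8")
  need <- c("bb1_id", "bb2_smiles", "reaction", "label")
  if (!all(need %in% names(df))) {
    stop("cage CSV must have columns: ", paste(need, collapse = ", "))
  }
  cage_records(df$bb1_id, df$bb2_smiles, df$reaction, df$label)
}

#' Write / read catalogs as JSON sidecar files
#'
#' @param bb1 a `bb1_catalog`; @param reactions a `reaction_catalog`.
#' @param path file path.
#' @name catalog_json
#' @export
write_catalogs_json <- function(bb1, reactions, path) {
  jsonlite::write_json(
    list(bb1_skeletons = bb1$skeletons, reactions = reactions$names),
    path, auto_unbox = FALSE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname catalog_json
#' @export
read_catalogs_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(bb1 = bb1_catalog(x$bb1_skeletons),
       reactions = reaction_catalog(x$reactions))
}
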
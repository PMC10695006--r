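# Special tokens, in their fixed vocabulary order. [Lr] marks a reactive-site
# attachment point in an edge-precursor (BB2) skeleton.
.specials <- c("[pad]", "[sos]", "[eos]", "[Lr]")

# Versioned surrogate table: multi-character SMILES tokens are remapped to
# single-character surrogates before indexing, so the vocabulary is strictly
# character-level. Surrogate characters are chosen outside the SMILES
# alphabet used by the package's grammars.
.surrogate_version <- 1L
.surrogate_table <- c(
  "Br"   = "R",
  "Cl"   = "L",
  "Si"   = "X",
  "[nH]" = "Q",
  "[H]"  = "H",
  "@@"   = "$",
  "%10"  = "!",
  "%11"  = "?",
  "%12"  = "&"
)

#' Split a BB2 SMILES string into tokens
#'
#' Character-level tokenisation with multi-character tokens (`[Lr]` site
#' markers, bracket atoms, two-letter elements, `%nn` ring closures, `@@`)
#' kept intact.
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens.
#' @export
smiles_tokens <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) return(character(0))
  pat <- "\\[[^\\]]*\\]|Br|Cl|Si|%[0-9]{2}|@@|."
  m <- gregexpr(pat, smiles, perl = TRUE)[[1]]
  regmatches(smiles, list(m))[[1]]
}

.to_surrogate <- function(tokens) {
  hit <- tokens %in% names(.surrogate_table)
  tokens[hit] <- .surrogate_table[tokens[hit]]
  bad <- nchar(tokens) > 1L & !(tokens %in% .specials)
  if (any(bad)) {
    stop("no single-character surrogate for token(s): ",
         paste(unique(tokens[bad]), collapse = ", "))
  }
  tokens
}

.from_surrogate <- function(tokens) {
  rev_map <- stats::setNames(names(.surrogate_table), .surrogate_table)
  hit <- tokens %in% names(rev_map)
  tokens[hit] <- rev_map[tokens[hit]]
  tokens
}

#' Build a token vocabulary from a BB2 SMILES corpus
#'
#' The vocabulary always contains the four special tokens `[pad]`, `[sos]`,
#' `[eos]`, `[Lr]` (in that order), followed by the lexicographically sorted
#' single-character (surrogate-mapped) tokens occurring in the corpus.
#' Construction is deterministic and order-independent over the corpus.
#'
#' @param corpus character vector of BB2 SMILES strings (each must parse).
#' @param max_len maximum padded sequence length; by default the longest
#'   corpus tokenisation plus two (for `[sos]`/`[eos]`).
#' @param check_parse validate every corpus string chemically before
#'   tokenising.
#' @return an object of class `poc_vocab` with `tokens`, `index` (named
#'   integer map), `max_len` and the surrogate-table version.
#' @export
build_vocabulary <- function(corpus, max_len = NULL, check_parse = TRUE) {
  corpus <- unique(as.character(corpus))
  if (check_parse) {
    for (s in corpus) {
      if (!is_valid_smiles(s)) stop("unparseable SMILES in corpus: ", s)
    }
  }
  tok_lists <- lapply(corpus, function(s) .to_surrogate(smiles_tokens(s)))
  body <- unique(setdiff(as.character(unlist(tok_lists)), .specials))
  body <- sort(body, method = "radix")
  tokens <- c(.specials, body)
  if (is.null(max_len)) {
    max_len <- if (length(tok_lists)) {
      max(vapply(tok_lists, length, 1L)) + 2L
    } else 2L
  }
  structure(
    list(tokens = tokens,
         index = stats::setNames(seq_along(tokens), tokens),
         max_len = as.integer(max_len),
         surrogate_version = .surrogate_version),
    class = "poc_vocab"
  )
}

#' @export
print.poc_vocab <- function(x, ...) {
  cat(sprintf("<poc_vocab> %d tokens, max_len %d\n",
              length(x$tokens), x$max_len))
  invisible(x)
}

#' Encode a BB2 SMILES string as a fixed-length index sequence
#'
#' The sequence starts with `[sos]`, ends with a single `[eos]`, and is
#' padded with `[pad]` up to `vocab$max_len`. Indices are 1-based positions
#' in the vocabulary.
#'
#' @param smiles a BB2 SMILES string.
#' @param vocab a `poc_vocab`.
#' @return integer vector of length `vocab$max_len`.
#' @export
tokenize <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "poc_vocab"))
  toks <- .to_surrogate(smiles_tokens(smiles))
  unknown <- setdiff(toks, vocab$tokens)
  if (length(unknown)) {
    stop("token(s) not in vocabulary: ", paste(unknown, collapse = ", "))
  }
  n <- length(toks) + 2L
  if (n > vocab$max_len) {
    stop(sprintf("sequence of %d tokens exceeds max_len %d",
                 length(toks), vocab$max_len))
  }
  idx <- c(vocab$index[["[sos]"]],
           unname(vocab$index[toks]),
           vocab$index[["[eos]"]],
           rep(vocab$index[["[pad]"]], vocab$max_len - n))
  as.integer(idx)
}

#' Decode an index sequence back to a BB2 SMILES string
#'
#' Specials are stripped, decoding stops at the first `[eos]` (or at the end
#' of the sequence when no `[eos]` is present), and surrogate characters are
#' expanded back to their multi-character tokens.
#'
#' @param indices integer vector of vocabulary indices.
#' @param vocab a `poc_vocab`.
#' @return a SMILES string (possibly empty; possibly chemically invalid —
#'   validity is judged downstream).
#' @export
detokenize <- function(indices, vocab) {
  stopifnot(inherits(vocab, "poc_vocab"))
  indices <- as.integer(indices)
  if (any(indices < 1L | indices > length(vocab$tokens))) {
    stop("index out of vocabulary range")
  }
  toks <- vocab$tokens[indices]
  eos <- match("[eos]", toks)
  if (!is.na(eos)) toks <- toks[seq_len(eos - 1L)]
  toks <- toks[!(toks %in% c("[pad]", "[sos]", "[eos]"))]
  paste(.from_surrogate(toks), collapse = "")
}
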
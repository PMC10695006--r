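# Generation filter cascade and evaluation metrics.
#
# The filter screens a decoded cage in a fixed order — validity, novelty,
# precursor validity, number of reaction sites, symmetry — recording the
# first failing stage; the metric suite reports batch-level rates with the
# conditioning structure of the evaluation table (novelty, uniqueness and
# precursor validity conditioned on validity; symmetry conditioned on
# precursor validity).

.filter_stages <- c("validity", "novelty", "precursor_validity",
                    "reaction_sites", "symmetry")

#' Screen one decoded cage candidate through the filter cascade
#'
#' Stages in order: `validity` (BB2 SMILES parses), `novelty` (cage key not
#' in the reference set), `precursor_validity` (at least one recognised
#' `[Lr]` site token), `reaction_sites` (exactly two sites), `symmetry`
#' (both sites in one graph-automorphism orbit). The first failing stage is
#' recorded; every failure is an outcome, not an error.
#'
#' @param candidate single-row `cage_records` (or list with `bb1_id`,
#'   `bb2_smiles`, `reaction_id`).
#' @param reference_keys character vector of known [cage_key()] values.
#' @return list with `passed` (logical) and `failed_stage` (one of the
#'   stage names or "none").
#' @export
filter_cage <- function(candidate, reference_keys = character(0)) {
  bb2 <- candidate$bb2_smiles[1]
  if (!is_valid_smiles(bb2)) {
    return(list(passed = FALSE, failed_stage = "validity"))
  }
  key <- cage_key(candidate$bb1_id[1], bb2, candidate$reaction_id[1])
  if (key %in% reference_keys) {
    return(list(passed = FALSE, failed_stage = "novelty"))
  }
  n_sites <- count_reaction_sites(bb2)
  if (n_sites == 0L) {
    return(list(passed = FALSE, failed_stage = "precursor_validity"))
  }
  if (n_sites != 2L) {
    return(list(passed = FALSE, failed_stage = "reaction_sites"))
  }
  if (!is_symmetric_bb2(bb2)) {
    return(list(passed = FALSE, failed_stage = "symmetry"))
  }
  list(passed = TRUE, failed_stage = "none")
}

#' Generate cages with filter feedback
#'
#' Draws candidates from a sampler, screens each through [filter_cage()],
#' and on failure re-initiates generation until `n_required` cages pass or
#' the attempt budget is exhausted.
#'
#' @param sampler function(n, rng_seed) returning a `cage_records`-like
#'   data.frame of n candidates (e.g. prior sampling + decoding).
#' @param reference_keys known [cage_key()] values for the novelty stage.
#' @param n_required number of passing cages wanted.
#' @param max_attempts attempt budget (>= `n_required`).
#' @param rng_seed seed passed to the sampler per chunk.
#' @return list with `cages` (passing records), `log` (one row per attempt
#'   with its outcome stage), and `exhausted` (TRUE when the budget ran out
#'   before `n_required` passes).
#' @export
generate_with_filter <- function(sampler, reference_keys, n_required,
                                 max_attempts = 10L * n_required,
                                 rng_seed = 1L) {
  stopifnot(max_attempts >= n_required)
  accepted <- list()
  log_rows <- list()
  attempts <- 0L
  chunk_seed <- rng_seed
  while (length(accepted) < n_required && attempts < max_attempts) {
    n_draw <- min(n_required - length(accepted),
                  max_attempts - attempts)
    batch <- sampler(n_draw, chunk_seed)
    chunk_seed <- chunk_seed + 1L
    for (i in seq_len(nrow(batch))) {
      attempts <- attempts + 1L
      out <- filter_cage(batch[i, , drop = FALSE], reference_keys)
      log_rows[[attempts]] <- data.frame(
        attempt = attempts,
        bb2_smiles = batch$bb2_smiles[i],
        passed = out$passed,
        failed_stage = out$failed_stage,
        stringsAsFactors = FALSE)
      if (out$passed) {
        accepted[[length(accepted) + 1L]] <- batch[i, , drop = FALSE]
        if (length(accepted) >= n_required) break
      }
    }
  }
  cages <- if (length(accepted)) do.call(rbind, accepted) else NULL
  list(cages = cages,
       log = do.call(rbind, log_rows),
       exhausted = length(accepted) < n_required)
}

#' Generation-quality metrics for a decoded batch
#'
#' Validity over the whole batch; novelty (against the original and the
#' combined original+augmented reference sets), uniqueness and precursor
#' validity over the valid candidates; symmetry over the precursor-valid
#' candidates. Uniqueness counts canonically duplicated cages once.
#'
#' @param batch decoded `cage_records`.
#' @param reference_keys_original,reference_keys_combined [cage_key()]
#'   sets of the original and the original+augmented datasets.
#' @return a `generation_report` list of rates in `[0, 1]`.
#' @export
compute_metrics <- function(batch, reference_keys_original = character(0),
                            reference_keys_combined = character(0)) {
  stopifnot(nrow(batch) >= 1)
  valid <- vapply(batch$bb2_smiles, is_valid_smiles, TRUE,
                  USE.NAMES = FALSE)
  vb <- batch[valid, , drop = FALSE]
  report <- list(n_sampled = nrow(batch), validity = mean(valid))
  if (nrow(vb) == 0) {
    report <- c(report, list(novelty_original_given_valid = NA_real_,
                             novelty_combined_given_valid = NA_real_,
                             uniqueness_given_valid = NA_real_,
                             precursor_validity_given_valid = NA_real_,
                             symmetry_given_precursor_valid = NA_real_))
    class(report) <- "generation_report"
    return(report)
  }
  keys <- cage_key(vb)
  report$novelty_original_given_valid <-
    mean(!(keys %in% reference_keys_original))
  report$novelty_combined_given_valid <-
    mean(!(keys %in% reference_keys_combined))
  report$uniqueness_given_valid <- length(unique(keys)) / length(keys)
  pv <- vapply(vb$bb2_smiles, is_precursor_valid, TRUE, USE.NAMES = FALSE)
  report$precursor_validity_given_valid <- mean(pv)
  report$symmetry_given_precursor_valid <- if (any(pv)) {
    mean(vapply(vb$bb2_smiles[pv], is_symmetric_bb2, TRUE,
                USE.NAMES = FALSE))
  } else NA_real_
  class(report) <- "generation_report"
  report
}

#' @export
print.generation_report <- function(x, ...) {
  cat("Generation metrics (", x$n_sampled, " samples)\n", sep = "")
  fmt <- function(v) ifelse(is.na(v), "  NA", sprintf("%.3f", v))
  cat("  validity                          ", fmt(x$validity), "\n")
  cat("  novelty (original) | valid        ",
      fmt(x$novelty_original_given_valid), "\n")
  cat("  novelty (combined) | valid        ",
      fmt(x$novelty_combined_given_valid), "\n")
  cat("  uniqueness | valid                ",
      fmt(x$uniqueness_given_valid), "\n")
  cat("  precursor validity | valid        ",
      fmt(x$precursor_validity_given_valid), "\n")
  cat("  symmetry | precursor-valid        ",
      fmt(x$symmetry_given_precursor_valid), "\n")
  invisible(x)
}

#' Principal-component projection of latent vectors
#'
#' Centered linear PCA (no scaling), for latent-space diagnostics.
#'
#' @param latents matrix of latent vectors (rows = cages).
#' @param n_components number of components (default 2).
#' @return list with `coords` (rows x components) and
#'   `explained_variance_ratio`.
#' @export
pca_latent <- function(latents, n_components = 2L) {
  stopifnot(nrow(latents) >= n_components)
  pc <- stats::prcomp(latents, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(coords = pc$x[, seq_len(k), drop = FALSE],
       explained_variance_ratio =
         (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}
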
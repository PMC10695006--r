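# Training protocol: cyclic KL annealing, linear warm-up of the
# categorical-reconstruction and predictor terms, greedy dataset split,
# Adam, per-epoch loss curves.

#' Cyclically annealed KL weight
#'
#' Training is divided into `n_cycles` equal cycles. Within each cycle the
#' weight rises linearly from 0 to `beta_max` over the first
#' `ramp_fraction` of the cycle, then holds the maximum for the remainder.
#' Counters a collapsing posterior (KL vanishing) in autoregressive VAEs.
#'
#' @param epoch 0-based epoch index.
#' @param epochs total number of epochs.
#' @param n_cycles number of annealing cycles.
#' @param beta_max plateau value (default 0.0025).
#' @param ramp_fraction fraction of the cycle spent ramping (default 0.5).
#' @return scalar weight in `[0, beta_max]`.
#' @export
cyclic_beta <- function(epoch, epochs, n_cycles = 5L, beta_max = 0.0025,
                        ramp_fraction = 0.5) {
  stopifnot(epoch >= 0, epoch < epochs, ramp_fraction > 0,
            ramp_fraction <= 1)
  cycle_len <- epochs / n_cycles
  pos <- epoch %% cycle_len
  pmin(1, pos / (cycle_len * ramp_fraction)) * beta_max
}

#' Linear warm-up weight
#'
#' `epoch / (epochs - 1)`: 0 at the first epoch, 1 at the last. Applied to
#' the BB1+reaction reconstruction component and to the predictor loss, so
#' early training concentrates on the sequence reconstruction.
#'
#' @param epoch 0-based epoch index.
#' @param epochs total number of epochs.
#' @return scalar in `[0, 1]`.
#' @export
linear_weight <- function(epoch, epochs) {
  stopifnot(epoch >= 0, epoch < epochs)
  if (epochs == 1L) return(1)
  epoch / (epochs - 1)
}

#' Training configuration
#'
#' Defaults follow the reference protocol: 100 epochs, batch 64, Adam with
#' learning rate 1e-4, five annealing cycles to beta 0.0025, and the greedy
#' 90.0% / 99.8% original/augmented split.
#'
#' @param epochs,batch_size,learning_rate optimiser settings.
#' @param n_cycles,beta_max,ramp_fraction cyclic KL annealing.
#' @param gamma predictor loss weight.
#' @param w_bb2,w_bb1rxn reconstruction weights.
#' @param split_original,split_augmented training fractions.
#' @param rng_seed master seed for split, batching, eps draws and dropout.
#' @return a `poc_train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 64L,
                         learning_rate = 1e-4, n_cycles = 5L,
                         beta_max = 0.0025, ramp_fraction = 0.5,
                         gamma = 1, w_bb2 = 1, w_bb1rxn = 1,
                         split_original = 0.900, split_augmented = 0.998,
                         rng_seed = 1L) {
  cfg <- list(epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              n_cycles = as.integer(n_cycles),
              beta_max = beta_max, ramp_fraction = ramp_fraction,
              gamma = gamma, w_bb2 = w_bb2, w_bb1rxn = w_bb1rxn,
              split_original = split_original,
              split_augmented = split_augmented,
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$epochs >= 1, cfg$batch_size >= 1, learning_rate > 0,
            split_original > 0, split_original <= 1,
            split_augmented > 0, split_augmented <= 1)
  class(cfg) <- "poc_train_config"
  cfg
}

#' Greedy train/test split of original and augmented records
#'
#' `floor(split_original * N)` original records (and the corresponding
#' fraction of augmented records) are selected for training uniformly at
#' random under the config seed; the two complements become the held-out
#' sets. With the reference counts (35 802 originals at 90.0%) this yields
#' the 32 221 / 3581 partition.
#'
#' @param original labeled `cage_records`.
#' @param augmented unlabeled `cage_records` (may be NULL or empty).
#' @param config a [train_config()].
#' @return list `train`, `test_original`, `test_augmented`.
#' @export
split_dataset <- function(original, augmented = NULL, config = train_config()) {
  stopifnot(nrow(original) >= 1)
  set.seed(config$rng_seed)
  n_o <- nrow(original)
  k_o <- floor(config$split_original * n_o)
  idx_o <- sample.int(n_o, k_o)
  train <- original[idx_o, , drop = FALSE]
  test_o <- original[setdiff(seq_len(n_o), idx_o), , drop = FALSE]
  test_a <- NULL
  if (!is.null(augmented) && nrow(augmented) > 0) {
    n_a <- nrow(augmented)
    k_a <- floor(config$split_augmented * n_a)
    idx_a <- sample.int(n_a, k_a)
    train <- rbind(train, augmented[idx_a, , drop = FALSE])
    test_a <- augmented[setdiff(seq_len(n_a), idx_a), , drop = FALSE]
    class(test_a) <- c("cage_records", "data.frame")
  }
  rownames(train) <- NULL
  class(train) <- c("cage_records", "data.frame")
  class(test_o) <- c("cage_records", "data.frame")
  list(train = train, test_original = test_o, test_augmented = test_a)
}

.make_masks <- function(cfg, B, L) {
  p_ed <- cfg$encoder_decoder_dropout
  p_pr <- cfg$predictor_dropout
  h <- cfg$encoder_hidden
  list(
    cat = .dropout_mask(B, cfg$cat_hidden, p_ed),
    fuse = .dropout_mask(B, 2 * h + cfg$cat_hidden, p_ed),
    dec = if (p_ed > 0) {
      lapply(seq_len(L - 1L), function(t) {
        .dropout_mask(B, cfg$decoder_hidden, p_ed)
      })
    } else NULL,
    bb = .dropout_mask(B, cfg$head_hidden, p_ed),
    prd = .dropout_mask(B, cfg$predictor_hidden, p_pr)
  )
}

# evaluate the loss on a record set without dropout, z = posterior mean
.eval_loss <- function(model, records, weights) {
  b <- .prepare_batch(model, records)
  eps <- matrix(0, b$B, model$cfg$latent_dim)
  .vae_forward_backward(model$params, model$cfg, b, weights, eps,
                        masks = NULL, compute_grads = FALSE)$breakdown
}

#' Train the cage VAE jointly with the shape-persistence predictor
#'
#' Runs the Adam training loop with the cyclic KL annealing and linear
#' warm-up schedulers (indexed by epoch, constant within an epoch).
#' Unlabeled records contribute no predictor loss. Aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param model a `poc_vae`.
#' @param train_records training `cage_records` (labeled and unlabeled
#'   records mixed; batches are drawn uniformly at random).
#' @param config a [train_config()].
#' @param test_records optional held-out `cage_records`; per-epoch test
#'   loss curves are recorded when given.
#' @param checkpoint_path optional path; the trained model is saved there.
#' @param verbose print per-epoch losses.
#' @return list with `model` (trained) and `history` (one row per epoch of
#'   train/test loss terms and scheduler values).
#' @export
train_poc_vae <- function(model, train_records, config = train_config(),
                          test_records = NULL, checkpoint_path = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(model, "poc_vae"), nrow(train_records) >= 1)
  params <- model$params
  state <- adam_init(params)
  n <- nrow(train_records)
  L <- model$cfg$max_len
  set.seed(config$rng_seed)
  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs) - 1L) {
    beta <- cyclic_beta(ep, config$epochs, config$n_cycles,
                        config$beta_max, config$ramp_fraction)
    eta <- linear_weight(ep, config$epochs)
    w <- list(w_bb2 = config$w_bb2,
              w_bb1rxn = config$w_bb1rxn * eta,
              beta = beta,
              gamma = config$gamma * eta)
    ord <- sample.int(n)
    acc <- c(recon_bb2 = 0, recon_bb1rxn = 0, kl = 0, pred = 0, total = 0)
    nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      b <- .prepare_batch(model, train_records[idx, , drop = FALSE])
      eps <- matrix(stats::rnorm(b$B * model$cfg$latent_dim),
                    b$B, model$cfg$latent_dim)
      masks <- .make_masks(model$cfg, b$B, L)
      step <- .vae_forward_backward(params, model$cfg, b, w, eps, masks)
      if (!is.finite(step$breakdown$total)) {
        stop(sprintf("training diverged at epoch %d (total loss %s)",
                     ep, step$breakdown$total))
      }
      upd <- adam_step(params, step$grads, state, lr = config$learning_rate)
      params <- upd$params; state <- upd$state
      acc <- acc + unlist(step$breakdown)
      nb <- nb + 1L
    }
    model$params <- params
    row <- as.list(acc / nb)
    names(row) <- paste0("train_", names(acc))
    row$epoch <- ep; row$beta <- beta; row$eta <- eta
    if (!is.null(test_records) && nrow(test_records) > 0) {
      tb <- .eval_loss(model, test_records, w)
      row$test_recon_bb2 <- tb$recon_bb2
      row$test_pred <- tb$pred
      row$test_total <- tb$total
    }
    hist[[ep + 1L]] <- row
    if (verbose) {
      message(sprintf("epoch %3d  total %.4f  bb2 %.4f  kl %.2f  pred %.4f",
                      ep, row$train_total, row$train_recon_bb2,
                      row$train_kl, row$train_pred))
    }
  }
  history <- do.call(rbind, lapply(hist, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
  list(model = model, history = history)
}

#' Accuracy of the shape-persistence predictor on labeled records
#'
#' Encodes each record, takes the posterior mean and thresholds the
#' predicted collapse probability at 0.5.
#'
#' @param model a trained `poc_vae`.
#' @param records fully labeled `cage_records`.
#' @return fraction of correct binary decisions.
#' @export
evaluate_predictor <- function(model, records) {
  stopifnot(nrow(records) >= 1, all(records$label != "unlabeled"))
  post <- encode(model, records)
  p <- predict_persistence(model, post$mean)
  y <- as.integer(records$label == "collapsed")
  mean((p >= 0.5) == (y == 1L))
}

#' Exact-reconstruction rate under greedy decoding
#'
#' Each record is encoded, the posterior mean greedily decoded, and the
#' reconstruction counts as exact when the decoded BB2 SMILES string, the
#' BB1 ordinal and the reaction ordinal all match the input.
#'
#' @param model a trained `poc_vae`.
#' @param records `cage_records`.
#' @return list with `rate` and the per-record logical vector `exact`.
#' @export
reconstruction_rate <- function(model, records) {
  post <- encode(model, records)
  dec <- decode_bb2(model, post$mean, mode = "greedy")
  cat_dec <- decode_bb1_reaction(model, post$mean)
  exact <- dec$smiles == records$bb2_smiles &
    cat_dec$bb1_id == records$bb1_id &
    cat_dec$reaction_id == records$reaction_id
  list(rate = mean(exact), exact = exact, decoded = dec$smiles)
}

#' Save / load a model checkpoint
#'
#' A single RDS file holding a versioned header (package version, model
#' config) together with the vocabulary, catalogs and parameters.
#'
#' @param model a `poc_vae`; @param path file path.
#' @name checkpoint
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "poc_vae"))
  obj <- list(format = "poc_vae_checkpoint", format_version = 1L,
              package_version = as.character(utils::packageVersion("pocvae")),
              model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "poc_vae_checkpoint")) {
    stop("not a poc_vae checkpoint: ", path)
  }
  obj$model
}
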
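# The multi-component cage VAE.
#
# Architecture: the BB2 token sequence runs through a bidirectional GRU;
# BB1 and reaction ordinals run one-hot through an MLP branch. The two
# summaries are fused (concatenation + two affine maps) into a diagonal
# Gaussian posterior over the latent space. A single-direction GRU decodes
# the token sequence from z (z initialises the hidden state and is
# concatenated to every input embedding); an MLP head decodes BB1/reaction
# categoricals; an MLP predictor maps z to the probability of collapse.
# Everything is trained jointly under the beta-weighted ELBO plus a masked
# binary cross-entropy predictor term.

#' Model configuration
#'
#' Defaults follow the reference training setup: encoder hidden 256,
#' decoder hidden 384, latent 128, dropout 0.25 (encoder/decoder) and 0.5
#' (predictor). Desk-scale experiments typically shrink
#' `latent_dim`/`encoder_hidden`/`decoder_hidden`.
#'
#' @param vocab_size,n_bb1,n_reactions,max_len data dimensions.
#' @param latent_dim latent space size.
#' @param encoder_hidden,decoder_hidden GRU hidden-state sizes.
#' @param embedding_dim token embedding size.
#' @param cat_hidden hidden width of the categorical encoder branch.
#' @param head_hidden hidden width of the BB1/reaction decoder head.
#' @param predictor_hidden hidden width of the shape-persistence predictor.
#' @param encoder_decoder_dropout,predictor_dropout dropout rates.
#' @return a `poc_vae_config` list.
#' @export
poc_vae_config <- function(vocab_size, n_bb1, n_reactions, max_len,
                           latent_dim = 128L,
                           encoder_hidden = 256L,
                           decoder_hidden = 384L,
                           embedding_dim = 48L,
                           cat_hidden = 64L,
                           head_hidden = 64L,
                           predictor_hidden = 64L,
                           encoder_decoder_dropout = 0.25,
                           predictor_dropout = 0.5) {
  cfg <- list(vocab_size = as.integer(vocab_size),
              n_bb1 = as.integer(n_bb1),
              n_reactions = as.integer(n_reactions),
              max_len = as.integer(max_len),
              latent_dim = as.integer(latent_dim),
              encoder_hidden = as.integer(encoder_hidden),
              decoder_hidden = as.integer(decoder_hidden),
              embedding_dim = as.integer(embedding_dim),
              cat_hidden = as.integer(cat_hidden),
              head_hidden = as.integer(head_hidden),
              predictor_hidden = as.integer(predictor_hidden),
              encoder_decoder_dropout = encoder_decoder_dropout,
              predictor_dropout = predictor_dropout)
  stopifnot(all(unlist(cfg[1:11]) > 0),
            encoder_decoder_dropout >= 0, encoder_decoder_dropout < 1,
            predictor_dropout >= 0, predictor_dropout < 1)
  class(cfg) <- "poc_vae_config"
  cfg
}

.init_params <- function(cfg, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  e <- cfg$embedding_dim; h <- cfg$encoder_hidden; d <- cfg$decoder_hidden
  k <- cfg$latent_dim; V <- cfg$vocab_size
  cc <- cfg$cat_hidden; hh <- cfg$head_hidden; ph <- cfg$predictor_hidden
  ncat <- cfg$n_bb1 + cfg$n_reactions
  list(
    E = .nn_mat(V, e, scale = 0.1),
    eWi_f = .nn_mat(e, 3 * h), eWh_f = .nn_mat(h, 3 * h),
    ebi_f = .nn_zeros(3 * h), ebh_f = .nn_zeros(3 * h),
    eWi_b = .nn_mat(e, 3 * h), eWh_b = .nn_mat(h, 3 * h),
    ebi_b = .nn_zeros(3 * h), ebh_b = .nn_zeros(3 * h),
    cW1 = .nn_mat(ncat, cc), cb1 = .nn_zeros(cc),
    Wmu = .nn_mat(2 * h + cc, k), bmu = .nn_zeros(k),
    Wlv = .nn_mat(2 * h + cc, k, scale = 0.01), blv = .nn_zeros(k),
    W0 = .nn_mat(k, d), b0 = .nn_zeros(d),
    dWi = .nn_mat(e + k, 3 * d), dWh = .nn_mat(d, 3 * d),
    dbi = .nn_zeros(3 * d), dbh = .nn_zeros(3 * d),
    Wout = .nn_mat(d, V), bout = .nn_zeros(V),
    Wbr1 = .nn_mat(k, hh), bbr1 = .nn_zeros(hh),
    Wbb = .nn_mat(hh, cfg$n_bb1), bbb = .nn_zeros(cfg$n_bb1),
    Wrx = .nn_mat(hh, cfg$n_reactions), brx = .nn_zeros(cfg$n_reactions),
    Wp1 = .nn_mat(k, ph), bp1 = .nn_zeros(ph),
    Wp2 = .nn_mat(ph, 1), bp2 = .nn_zeros(1)
  )
}

#' Construct a cage VAE model
#'
#' @param vocab a `poc_vocab` built from the BB2 corpus.
#' @param bb1 a `bb1_catalog`.
#' @param reactions a `reaction_catalog`.
#' @param rng_seed seed for parameter initialisation.
#' @param ... overrides passed to [poc_vae_config()].
#' @return a `poc_vae` model object.
#' @export
poc_vae <- function(vocab, bb1, reactions, rng_seed = 1L, ...) {
  stopifnot(inherits(vocab, "poc_vocab"), inherits(bb1, "bb1_catalog"),
            inherits(reactions, "reaction_catalog"))
  cfg <- poc_vae_config(vocab_size = length(vocab$tokens),
                        n_bb1 = bb1$n, n_reactions = reactions$n,
                        max_len = vocab$max_len, ...)
  structure(list(cfg = cfg, vocab = vocab, bb1 = bb1,
                 reactions = reactions,
                 params = .init_params(cfg, rng_seed)),
            class = "poc_vae")
}

#' @export
print.poc_vae <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf(
    "<poc_vae> latent %d | enc %d (bi-GRU) | dec %d (GRU) | vocab %d | %d BB1 x %d reactions | %s parameters\n",
    x$cfg$latent_dim, x$cfg$encoder_hidden, x$cfg$decoder_hidden,
    x$cfg$vocab_size, x$cfg$n_bb1, x$cfg$n_reactions,
    format(n_par, big.mark = ",")))
  invisible(x)
}

# records -> padded token matrix, 1-based ordinals, binary collapse target
.prepare_batch <- function(model, records) {
  B <- nrow(records)
  Tm <- t(vapply(records$bb2_smiles, tokenize, integer(model$vocab$max_len),
                 vocab = model$vocab, USE.NAMES = FALSE))
  stopifnot(all(records$bb1_id < model$cfg$n_bb1),
            all(records$reaction_id < model$cfg$n_reactions))
  y <- ifelse(records$label == "collapsed", 1,
              ifelse(records$label == "not_collapsed", 0, NA_real_))
  list(Tm = Tm, bb1 = records$bb1_id + 1L, rxn = records$reaction_id + 1L,
       y = y, B = B)
}

.onehot <- function(idx, n) {
  m <- matrix(0, length(idx), n)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

.relu <- function(x) pmax(x, 0)

# encoder forward; masks: optional dropout masks (list: cat, fuse)
.encode_forward <- function(params, cfg, Tm, bb1, rxn, masks = NULL) {
  B <- nrow(Tm); L <- ncol(Tm); h <- cfg$encoder_hidden
  xs <- lapply(seq_len(L), function(t) {
    params$E[Tm[, t], , drop = FALSE]
  })
  h0 <- matrix(0, B, h)
  fw_f <- .gru_seq_forward(xs, h0, params$eWi_f, params$eWh_f,
                           params$ebi_f, params$ebh_f)
  fw_b <- .gru_seq_forward(rev(xs), h0, params$eWi_b, params$eWh_b,
                           params$ebi_b, params$ebh_b)
  Xcat <- cbind(.onehot(bb1, cfg$n_bb1), .onehot(rxn, cfg$n_reactions))
  a1 <- sweep(Xcat %*% params$cW1, 2L, params$cb1, "+")
  hcat <- .relu(a1)
  hcat_d <- if (!is.null(masks$cat)) hcat * masks$cat else hcat
  fused <- cbind(fw_f$h_final, fw_b$h_final, hcat_d)
  fused_d <- if (!is.null(masks$fuse)) fused * masks$fuse else fused
  mu <- sweep(fused_d %*% params$Wmu, 2L, params$bmu, "+")
  lv_pre <- sweep(fused_d %*% params$Wlv, 2L, params$blv, "+")
  lv <- pmin(pmax(lv_pre, -12), 12)
  list(mu = mu, lv = lv, lv_open = abs(lv_pre) < 12,
       cache = list(xs = xs, fw_f = fw_f, fw_b = fw_b, Xcat = Xcat,
                    hcat = hcat, hcat_d = hcat_d, fused_d = fused_d))
}

#' Encode cage records into latent posteriors
#'
#' Runs the bidirectional sequence encoder and the categorical branch and
#' fuses them into one diagonal-Gaussian posterior per cage (dropout
#' disabled).
#'
#' @param model a `poc_vae`.
#' @param records a `cage_records` data.frame.
#' @return list with `mean` and `log_variance` matrices (records x latent).
#' @export
encode <- function(model, records) {
  b <- .prepare_batch(model, records)
  enc <- .encode_forward(model$params, model$cfg, b$Tm, b$bb1, b$rxn)
  list(mean = enc$mu, log_variance = enc$lv)
}

#' Reparameterised sample from a latent posterior
#'
#' `z = mean + exp(log_variance / 2) * eps`, `eps ~ N(0, I)`.
#'
#' @param posterior list with `mean` and `log_variance` matrices.
#' @param rng_seed optional seed.
#' @return matrix of latent samples.
#' @export
reparameterize <- function(posterior, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  mu <- posterior$mean; lv <- posterior$log_variance
  eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  mu + exp(lv / 2) * eps
}

#' Kullback-Leibler divergence of the posterior from the standard normal
#'
#' Closed form for a diagonal Gaussian, `0.5 * sum(mu^2 + sigma^2 - 1 -
#' log sigma^2)`, summed over latent dimensions and averaged over the batch.
#'
#' @param posterior list with `mean` and `log_variance`.
#' @return non-negative scalar.
#' @export
kl_divergence <- function(posterior) {
  mu <- posterior$mean; lv <- posterior$log_variance
  0.5 * sum(mu^2 + exp(lv) - 1 - lv) / nrow(mu)
}

# decoder single step; tok: current input token indices (1-based)
.decode_step <- function(params, tok, z, h) {
  x <- cbind(params$E[tok, , drop = FALSE], z)
  step <- .gru_cell(x, h, params$dWi, params$dWh, params$dbi, params$dbh)
  logits <- sweep(step$h %*% params$Wout, 2L, params$bout, "+")
  list(h = step$h, logits = logits)
}

#' Decode BB2 token sequences from latent vectors
#'
#' Autoregressive GRU decoding starting from `[sos]`. In `teacher_forced`
#' mode the provided token matrix drives the inputs and per-position logits
#' are returned (for the loss); `greedy` takes the arg-max token at each
#' step; `multinomial` samples from the softmax.
#'
#' @param model a `poc_vae`.
#' @param z latent matrix (rows = samples).
#' @param mode decoding mode.
#' @param tokens token matrix (required for `teacher_forced`).
#' @param rng_seed seed for `multinomial` mode.
#' @return `teacher_forced`: list of per-position logits matrices.
#'   Otherwise a list with `indices` (matrix incl. `[sos]`) and `smiles`
#'   (character vector of decoded strings).
#' @export
decode_bb2 <- function(model, z,
                       mode = c("greedy", "multinomial", "teacher_forced"),
                       tokens = NULL, rng_seed = NULL) {
  mode <- match.arg(mode)
  p <- model$params; cfg <- model$cfg; vocab <- model$vocab
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  B <- nrow(z); L <- cfg$max_len
  h <- tanh(sweep(z %*% p$W0, 2L, p$b0, "+"))
  if (mode == "teacher_forced") {
    stopifnot(!is.null(tokens), ncol(tokens) == L)
    out <- vector("list", L - 1L)
    for (t in seq_len(L - 1L)) {
      st <- .decode_step(p, tokens[, t], z, h)
      h <- st$h
      out[[t]] <- st$logits
    }
    return(out)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sos <- vocab$index[["[sos]"]]; eos <- vocab$index[["[eos]"]]
  pad <- vocab$index[["[pad]"]]
  seqs <- matrix(pad, B, L)
  seqs[, 1L] <- sos
  tok <- rep(sos, B)
  done <- rep(FALSE, B)
  for (t in 2:L) {
    st <- .decode_step(p, tok, z, h)
    h <- st$h
    nxt <- if (mode == "greedy") {
      max.col(st$logits, ties.method = "first")
    } else {
      pr <- .softmax(st$logits)
      vapply(seq_len(B), function(i) {
        sample.int(ncol(pr), 1L, prob = pr[i, ])
      }, 1L)
    }
    nxt[done] <- pad
    seqs[, t] <- nxt
    done <- done | nxt == eos
    tok <- nxt
    tok[tok == pad] <- eos  # keep feeding a terminal token once finished
    if (all(done)) break
  }
  smiles <- vapply(seq_len(B), function(i) detokenize(seqs[i, ], vocab), "")
  list(indices = seqs, smiles = smiles)
}

#' Decode BB1 and reaction ordinals from latent vectors
#'
#' Categorical MLP head; arg-max is used at inference so generation can
#' never leave the catalogs.
#'
#' @param model a `poc_vae`.
#' @param z latent matrix.
#' @return list with `bb1_logits`, `reaction_logits`, and 0-based arg-max
#'   ids `bb1_id`, `reaction_id`.
#' @export
decode_bb1_reaction <- function(model, z) {
  p <- model$params
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  hb <- .relu(sweep(z %*% p$Wbr1, 2L, p$bbr1, "+"))
  lb <- sweep(hb %*% p$Wbb, 2L, p$bbb, "+")
  lr <- sweep(hb %*% p$Wrx, 2L, p$brx, "+")
  list(bb1_logits = lb, reaction_logits = lr,
       bb1_id = max.col(lb, ties.method = "first") - 1L,
       reaction_id = max.col(lr, ties.method = "first") - 1L)
}

#' Predicted probability of collapse from latent vectors
#'
#' MLP head on z; returns `P(collapsed | z)` (label 1 = collapse). The
#' probability of shape persistence is its complement.
#'
#' @param model a `poc_vae`.
#' @param z latent matrix or vector.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_persistence <- function(model, z) {
  p <- model$params
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  hp <- .relu(sweep(z %*% p$Wp1, 2L, p$bp1, "+"))
  u <- sweep(hp %*% p$Wp2, 2L, p$bp2, "+")
  as.vector(.sigmoid(u))
}

#' Loss weights
#'
#' @param beta KL weight (default 0.0025); @param gamma predictor weight
#' (default 1); @param w_bb2,w_bb1rxn reconstruction weights (default 1).
#' @return list of class `poc_loss_weights`.
#' @export
loss_weights <- function(beta = 0.0025, gamma = 1, w_bb2 = 1,
                         w_bb1rxn = 1) {
  stopifnot(beta >= 0, gamma >= 0, w_bb2 >= 0, w_bb1rxn >= 0)
  structure(list(beta = beta, gamma = gamma, w_bb2 = w_bb2,
                 w_bb1rxn = w_bb1rxn), class = "poc_loss_weights")
}

#' Multi-component loss breakdown
#'
#' Combines the per-token BB2 cross-entropy, the BB1 and reaction
#' cross-entropies, the KL term and the masked predictor binary
#' cross-entropy into the weighted training objective. All terms are
#' averaged over the batch; the predictor term averages over labeled
#' records only and is zero for an all-unlabeled batch.
#'
#' @param outputs list with `bb2_logits` (list of per-position logits),
#'   `bb1_logits`, `reaction_logits`, `pred_logit` (column of predictor
#'   pre-sigmoid values) and `posterior`.
#' @param targets list with `tokens` (padded matrix incl. `[sos]`),
#'   `bb1`, `reaction` (1-based), `y` (1 = collapsed, 0 = not collapsed,
#'   NA = unlabeled), `pad_index`.
#' @param weights a [loss_weights()] list.
#' @param label_mask logical vector marking labeled records; defaults to
#'   `!is.na(targets$y)`.
#' @return list of class `poc_loss_breakdown` with `recon_bb2`,
#'   `recon_bb1rxn`, `kl`, `pred`, `total`.
#' @export
compute_loss <- function(outputs, targets, weights,
                         label_mask = NULL) {
  Tm <- targets$tokens
  B <- nrow(Tm); L <- ncol(Tm)
  tgt <- Tm[, 2:L, drop = FALSE]
  msk <- (tgt != targets$pad_index) * 1
  loss_bb2 <- 0
  for (t in seq_len(L - 1L)) {
    loss_bb2 <- loss_bb2 +
      .ce_forward(outputs$bb2_logits[[t]], tgt[, t], msk[, t])$loss
  }
  recon_bb2 <- loss_bb2 / B
  recon_bb1rxn <- (.ce_forward(outputs$bb1_logits, targets$bb1)$loss +
                   .ce_forward(outputs$reaction_logits, targets$reaction)$loss) / B
  kl <- kl_divergence(outputs$posterior)
  if (is.null(label_mask)) label_mask <- !is.na(targets$y)
  pred <- 0
  if (any(label_mask)) {
    u <- as.vector(outputs$pred_logit)[label_mask]
    y <- targets$y[label_mask]
    p <- .sigmoid(u)
    pred <- mean(-(y * log(pmax(p, 1e-12)) +
                   (1 - y) * log(pmax(1 - p, 1e-12))))
  }
  total <- weights$w_bb2 * recon_bb2 + weights$w_bb1rxn * recon_bb1rxn +
    weights$beta * kl + weights$gamma * pred
  structure(list(recon_bb2 = recon_bb2, recon_bb1rxn = recon_bb1rxn,
                 kl = kl, pred = pred, total = total),
            class = "poc_loss_breakdown")
}

# Fused forward + backward pass for one training step. eps must be supplied
# so the pass is deterministic (enables finite-difference verification).
# weights here are the *effective* per-step weights (schedulers folded in).
.vae_forward_backward <- function(params, cfg, batch, weights, eps,
                                  masks = NULL, compute_grads = TRUE) {
  Tm <- batch$Tm; bb1 <- batch$bb1; rxn <- batch$rxn; y <- batch$y
  B <- nrow(Tm); L <- ncol(Tm)
  k <- cfg$latent_dim; e <- cfg$embedding_dim; h <- cfg$encoder_hidden
  pad <- 1L  # [pad] is always vocabulary index 1

  enc <- .encode_forward(params, cfg, Tm, bb1, rxn, masks)
  mu <- enc$mu; lv <- enc$lv
  z <- mu + exp(lv / 2) * eps
  kl <- 0.5 * sum(mu^2 + exp(lv) - 1 - lv) / B

  # sequence decoder (teacher forced)
  h0d_pre <- sweep(z %*% params$W0, 2L, params$b0, "+")
  h0d <- tanh(h0d_pre)
  dec_in <- Tm[, 1:(L - 1L), drop = FALSE]
  tgt <- Tm[, 2:L, drop = FALSE]
  msk <- (tgt != pad) * 1
  xs_d <- lapply(seq_len(L - 1L), function(t) {
    cbind(params$E[dec_in[, t], , drop = FALSE], z)
  })
  fw_d <- .gru_seq_forward(xs_d, h0d, params$dWi, params$dWh,
                           params$dbi, params$dbh)
  loss_bb2 <- 0
  dlogits_list <- vector("list", L - 1L)
  s_drop <- vector("list", L - 1L)
  for (t in seq_len(L - 1L)) {
    s <- fw_d$hs[[t]]
    if (!is.null(masks$dec)) s <- s * masks$dec[[t]]
    s_drop[[t]] <- s
    logits <- sweep(s %*% params$Wout, 2L, params$bout, "+")
    ce <- .ce_forward(logits, tgt[, t], msk[, t])
    loss_bb2 <- loss_bb2 + ce$loss
    dlogits_list[[t]] <- ce$dlogits
  }
  recon_bb2 <- loss_bb2 / B

  # BB1 + reaction head
  ab <- sweep(z %*% params$Wbr1, 2L, params$bbr1, "+")
  hb <- .relu(ab)
  hb_d <- if (!is.null(masks$bb)) hb * masks$bb else hb
  lb <- sweep(hb_d %*% params$Wbb, 2L, params$bbb, "+")
  lrx <- sweep(hb_d %*% params$Wrx, 2L, params$brx, "+")
  ce_b <- .ce_forward(lb, bb1)
  ce_r <- .ce_forward(lrx, rxn)
  recon_bb1rxn <- (ce_b$loss + ce_r$loss) / B

  # predictor (masked, semi-supervised)
  ap <- sweep(z %*% params$Wp1, 2L, params$bp1, "+")
  hp <- .relu(ap)
  hp_d <- if (!is.null(masks$prd)) hp * masks$prd else hp
  u <- sweep(hp_d %*% params$Wp2, 2L, params$bp2, "+")
  labeled <- !is.na(y)
  nlab <- sum(labeled)
  pu <- .sigmoid(as.vector(u))
  pred <- 0
  if (nlab > 0) {
    yy <- y[labeled]; pp <- pu[labeled]
    pred <- mean(-(yy * log(pmax(pp, 1e-12)) +
                   (1 - yy) * log(pmax(1 - pp, 1e-12))))
  }

  total <- weights$w_bb2 * recon_bb2 + weights$w_bb1rxn * recon_bb1rxn +
    weights$beta * kl + weights$gamma * pred
  breakdown <- structure(
    list(recon_bb2 = recon_bb2, recon_bb1rxn = recon_bb1rxn, kl = kl,
         pred = pred, total = total),
    class = "poc_loss_breakdown")
  if (!compute_grads) return(list(breakdown = breakdown))

  g <- lapply(params, function(p) p * 0)
  dz <- matrix(0, B, k)

  # sequence decoder backward
  dhs <- vector("list", L - 1L)
  for (t in seq_len(L - 1L)) {
    dlog <- (weights$w_bb2 / B) * dlogits_list[[t]]
    g$Wout <- g$Wout + t(s_drop[[t]]) %*% dlog
    g$bout <- g$bout + colSums(dlog)
    ds <- dlog %*% t(params$Wout)
    if (!is.null(masks$dec)) ds <- ds * masks$dec[[t]]
    dhs[[t]] <- ds
  }
  bk_d <- .gru_seq_backward(dhs, NULL, fw_d, params$dWi, params$dWh)
  g$dWi <- bk_d$dWi; g$dWh <- bk_d$dWh
  g$dbi <- bk_d$dbi; g$dbh <- bk_d$dbh
  for (t in seq_len(L - 1L)) {
    dx <- bk_d$dxs[[t]]
    g$E <- .emb_grad_add(g$E, dec_in[, t], dx[, 1:e, drop = FALSE])
    dz <- dz + dx[, (e + 1):(e + k), drop = FALSE]
  }
  dh0d <- bk_d$dh0 * (1 - h0d^2)
  g$W0 <- t(z) %*% dh0d
  g$b0 <- colSums(dh0d)
  dz <- dz + dh0d %*% t(params$W0)

  # BB1/reaction head backward
  dlb <- (weights$w_bb1rxn / B) * ce_b$dlogits
  dlr <- (weights$w_bb1rxn / B) * ce_r$dlogits
  g$Wbb <- t(hb_d) %*% dlb; g$bbb <- colSums(dlb)
  g$Wrx <- t(hb_d) %*% dlr; g$brx <- colSums(dlr)
  dhb <- dlb %*% t(params$Wbb) + dlr %*% t(params$Wrx)
  if (!is.null(masks$bb)) dhb <- dhb * masks$bb
  dab <- dhb * (ab > 0)
  g$Wbr1 <- t(z) %*% dab; g$bbr1 <- colSums(dab)
  dz <- dz + dab %*% t(params$Wbr1)

  # predictor backward
  if (nlab > 0) {
    du <- numeric(B)
    du[labeled] <- weights$gamma * (pu[labeled] - y[labeled]) / nlab
    du <- matrix(du, B, 1)
    g$Wp2 <- t(hp_d) %*% du; g$bp2 <- colSums(du)
    dhp <- du %*% t(params$Wp2)
    if (!is.null(masks$prd)) dhp <- dhp * masks$prd
    dap <- dhp * (ap > 0)
    g$Wp1 <- t(z) %*% dap; g$bp1 <- colSums(dap)
    dz <- dz + dap %*% t(params$Wp1)
  }

  # through the reparameterisation and the KL term
  dmu <- dz + weights$beta * mu / B
  dlv <- dz * eps * 0.5 * exp(lv / 2) +
    weights$beta * 0.5 * (exp(lv) - 1) / B
  dlv <- dlv * enc$lv_open

  cache <- enc$cache
  dfused_d <- dmu %*% t(params$Wmu) + dlv %*% t(params$Wlv)
  g$Wmu <- t(cache$fused_d) %*% dmu; g$bmu <- colSums(dmu)
  g$Wlv <- t(cache$fused_d) %*% dlv; g$blv <- colSums(dlv)
  if (!is.null(masks$fuse)) dfused_d <- dfused_d * masks$fuse
  cc <- cfg$cat_hidden
  dhF <- dfused_d[, 1:h, drop = FALSE]
  dhB <- dfused_d[, (h + 1):(2 * h), drop = FALSE]
  dhcat_d <- dfused_d[, (2 * h + 1):(2 * h + cc), drop = FALSE]
  if (!is.null(masks$cat)) dhcat_d <- dhcat_d * masks$cat
  da1 <- dhcat_d * (cache$hcat > 0)
  g$cW1 <- t(cache$Xcat) %*% da1; g$cb1 <- colSums(da1)

  bk_f <- .gru_seq_backward(NULL, dhF, cache$fw_f, params$eWi_f,
                            params$eWh_f)
  bk_b <- .gru_seq_backward(NULL, dhB, cache$fw_b, params$eWi_b,
                            params$eWh_b)
  g$eWi_f <- bk_f$dWi; g$eWh_f <- bk_f$dWh
  g$ebi_f <- bk_f$dbi; g$ebh_f <- bk_f$dbh
  g$eWi_b <- bk_b$dWi; g$eWh_b <- bk_b$dWh
  g$ebi_b <- bk_b$dbi; g$ebh_b <- bk_b$dbh
  for (t in seq_len(L)) {
    g$E <- .emb_grad_add(g$E, Tm[, t], bk_f$dxs[[t]])
    g$E <- .emb_grad_add(g$E, Tm[, L + 1L - t], bk_b$dxs[[t]])
  }

  list(breakdown = breakdown, grads = g, z = z)
}
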
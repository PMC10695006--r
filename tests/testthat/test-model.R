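make_tiny_model <- function(drop = 0) {
  ds <- make_dataset(fixture_spec(n_bb1 = 2L, n_reactions = 2L,
                                  n_bb2 = 10L, n_cages = 8L,
                                  rng_seed = 5L))
  vocab <- build_vocabulary(unique(ds$records$bb2_smiles))
  model <- poc_vae(vocab, ds$bb1, ds$reactions, rng_seed = 2L,
                   latent_dim = 6L, encoder_hidden = 8L,
                   decoder_hidden = 10L, embedding_dim = 6L,
                   cat_hidden = 6L, head_hidden = 6L, predictor_hidden = 6L,
                   encoder_decoder_dropout = drop,
                   predictor_dropout = drop)
  list(model = model, records = ds$records)
}

test_that("KL divergence matches the closed form and a MC estimate", {
  expect_identical(kl_divergence(list(mean = matrix(0, 1, 4),
                                      log_variance = matrix(0, 1, 4))), 0)
  expect_equal(kl_divergence(list(mean = matrix(1, 1, 1),
                                  log_variance = matrix(0, 1, 1))), 0.5)
  # MC oracle: E_q[log q(z) - log p(z)] over 1e6 draws
  set.seed(99)
  mu <- c(0.7, -1.2, 0.3); lv <- c(0.4, -0.8, 0.1)
  n <- 1e6
  z <- matrix(rnorm(3 * n, mean = rep(mu, each = n),
                    sd = rep(exp(lv / 2), each = n)), n, 3)
  logq <- sapply(1:3, function(j) {
    dnorm(z[, j], mu[j], exp(lv[j] / 2), log = TRUE)
  })
  logp <- dnorm(z, log = TRUE)
  mc <- mean(rowSums(logq - logp))
  closed <- kl_divergence(list(mean = matrix(mu, 1),
                               log_variance = matrix(lv, 1)))
  expect_lt(abs(mc - closed) / closed, 0.01)
  expect_gte(closed, 0)
})

test_that("reparameterisation has the right limits and moments", {
  mu <- matrix(c(1, -2, 0.5), 1)
  z0 <- reparameterize(list(mean = mu,
                            log_variance = matrix(-60, 1, 3)), 1L)
  expect_equal(as.vector(z0), as.vector(mu), tolerance = 1e-10)

  n <- 1e5
  post <- list(mean = matrix(rep(2, n), n, 1),
               log_variance = matrix(rep(log(0.25), n), n, 1))
  z <- reparameterize(post, 7L)
  se <- 0.5 / sqrt(n)
  expect_lt(abs(mean(z) - 2), 3 * se)

  expect_identical(reparameterize(post, 11L), reparameterize(post, 11L))
})

test_that("encoder output is deterministic with the documented shape", {
  tm <- make_tiny_model()
  post <- encode(tm$model, tm$records)
  expect_identical(dim(post$mean), c(nrow(tm$records), 6L))
  expect_identical(dim(post$log_variance), c(nrow(tm$records), 6L))
  expect_true(all(is.finite(post$mean)), all(is.finite(post$log_variance)))
  expect_identical(post, encode(tm$model, tm$records))
})

test_that("decoder modes honour their contracts", {
  tm <- make_tiny_model()
  z <- sample_prior(4, 6, rng_seed = 3)
  g1 <- decode_bb2(tm$model, z, mode = "greedy")
  g2 <- decode_bb2(tm$model, z, mode = "greedy")
  expect_identical(g1, g2)
  expect_true(all(g1$indices[, 1] == tm$model$vocab$index[["[sos]"]]))

  m1 <- decode_bb2(tm$model, z, mode = "multinomial", rng_seed = 5)
  m2 <- decode_bb2(tm$model, z, mode = "multinomial", rng_seed = 5)
  expect_identical(m1, m2)

  tf <- decode_bb2(tm$model, z[1:2, ], mode = "teacher_forced",
                   tokens = pocvae:::.prepare_batch(
                     tm$model, tm$records[1:2, ])$Tm)
  expect_length(tf, tm$model$cfg$max_len - 1L)
  expect_identical(ncol(tf[[1]]), length(tm$model$vocab$tokens))

  cats <- decode_bb1_reaction(tm$model, z)
  expect_identical(dim(cats$bb1_logits), c(4L, 2L))
  expect_identical(dim(cats$reaction_logits), c(4L, 2L))
  sm <- pocvae:::.softmax(cats$bb1_logits)
  expect_equal(rowSums(sm), rep(1, 4))
  expect_true(all(cats$bb1_id %in% 0:1))

  p <- predict_persistence(tm$model, z)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("loss bookkeeping matches hand computations", {
  # 2-position toy: vocab {pad sos eos a}, one record "a"
  # tokens: [sos a eos] -> targets (a, eos), both unmasked
  tokens <- matrix(c(2L, 4L, 3L), 1L)
  la <- matrix(c(0, 0, 1, 3), 1)    # position 1 logits, target index 4
  le <- matrix(c(0, 0, 2, 0), 1)    # position 2 logits, target index 3
  lb1 <- matrix(c(2, 0), 1)         # bb1 target 1
  lrx <- matrix(c(0, 0), 1)         # reaction target 2
  outputs <- list(
    bb2_logits = list(la, le),
    bb1_logits = lb1, reaction_logits = lrx,
    pred_logit = matrix(0, 1),
    posterior = list(mean = matrix(1, 1, 1),
                     log_variance = matrix(0, 1, 1)))
  targets <- list(tokens = tokens, bb1 = 1L, reaction = 2L, y = 1,
                  pad_index = 1L)
  w <- loss_weights(beta = 0.1, gamma = 2, w_bb2 = 1, w_bb1rxn = 0.5)
  lb <- compute_loss(outputs, targets, w)
  # hand: ce(la) = -log(e^3/(2 + e + e^3)), ce(le) = -log(e^2/(3 + e^2))
  ce1 <- -log(exp(3) / (2 + exp(1) + exp(3)))
  ce2 <- -log(exp(2) / (3 + exp(2)))
  expect_equal(lb$recon_bb2, ce1 + ce2)
  ceb <- -log(exp(2) / (exp(2) + 1)); cer <- -log(0.5)
  expect_equal(lb$recon_bb1rxn, ceb + cer)
  expect_equal(lb$kl, 0.5)
  expect_equal(lb$pred, -log(0.5))   # sigmoid(0) vs y = 1
  expect_equal(lb$total,
               1 * lb$recon_bb2 + 0.5 * lb$recon_bb1rxn +
                 0.1 * lb$kl + 2 * lb$pred)
})

test_that("predictor loss is masked to labeled records only", {
  one_pos <- matrix(c(0, 0, 0, 5), 1)
  outputs <- list(
    bb2_logits = list(one_pos, one_pos),
    bb1_logits = matrix(c(5, 0), 1), reaction_logits = matrix(c(5, 0), 1),
    pred_logit = matrix(2.7, 1),
    posterior = list(mean = matrix(0, 1, 1),
                     log_variance = matrix(0, 1, 1)))
  targets <- list(tokens = matrix(c(2L, 4L, 1L), 1), bb1 = 1L,
                  reaction = 1L, y = NA_real_, pad_index = 1L)
  lb <- compute_loss(outputs, targets, loss_weights())
  expect_identical(lb$pred, 0)

  # adding unlabeled records leaves the pred term unchanged
  two_pos <- rbind(c(0, 0, 0, 5), c(0, 0, 0, 5))
  out2 <- list(
    bb2_logits = list(two_pos, two_pos),
    bb1_logits = rbind(c(5, 0), c(5, 0)),
    reaction_logits = rbind(c(5, 0), c(5, 0)),
    pred_logit = matrix(c(2.7, -4), 2),
    posterior = list(mean = matrix(0, 2, 1),
                     log_variance = matrix(0, 2, 1)))
  tg1 <- list(tokens = matrix(c(2L, 4L, 1L), 1), bb1 = 1L, reaction = 1L,
              y = 1, pad_index = 1L)
  tg2 <- list(tokens = rbind(c(2L, 4L, 1L), c(2L, 4L, 1L)),
              bb1 = c(1L, 1L), reaction = c(1L, 1L),
              y = c(1, NA), pad_index = 1L)
  lb1 <- compute_loss(list(bb2_logits = list(one_pos, one_pos),
                           bb1_logits = matrix(c(5, 0), 1),
                           reaction_logits = matrix(c(5, 0), 1),
                           pred_logit = matrix(2.7, 1),
                           posterior = list(mean = matrix(0, 1, 1),
                                            log_variance =
                                              matrix(0, 1, 1))), tg1,
                      loss_weights())
  lb2 <- compute_loss(out2, tg2, loss_weights())
  expect_equal(lb2$pred, lb1$pred)
})

test_that("near-one-hot logits drive reconstruction terms to zero", {
  big <- 50
  outputs <- list(
    bb2_logits = list(matrix(c(0, 0, 0, big), 1),
                      matrix(c(0, 0, 0, big), 1)),
    bb1_logits = matrix(c(big, 0), 1),
    reaction_logits = matrix(c(0, big), 1),
    pred_logit = matrix(0, 1),
    posterior = list(mean = matrix(0, 1, 1),
                     log_variance = matrix(0, 1, 1)))
  targets <- list(tokens = matrix(c(2L, 4L, 1L), 1), bb1 = 1L,
                  reaction = 2L, y = NA_real_, pad_index = 1L)
  lb <- compute_loss(outputs, targets, loss_weights())
  expect_lt(lb$recon_bb2, 1e-10)
  expect_lt(lb$recon_bb1rxn, 1e-10)
})

test_that("an overfit model reproduces its training cages", {
  om <- overfit_model()
  post <- encode(om$model, om$records)
  dec <- decode_bb2(om$model, post$mean, mode = "greedy")
  expect_identical(dec$smiles, om$records$bb2_smiles)
  cats <- decode_bb1_reaction(om$model, post$mean)
  expect_identical(cats$bb1_id, om$records$bb1_id)
  expect_identical(cats$reaction_id, om$records$reaction_id)
  # records differing in their components get distinct posteriors
  expect_gt(min(dist(post$mean)), 1e-3)
})
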
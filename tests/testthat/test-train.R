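test_that("cyclic KL annealing follows the ramp-then-plateau shape", {
  epochs <- 100L; cycles <- 5L; bmax <- 0.0025
  b <- vapply(0:(epochs - 1L), cyclic_beta, 1, epochs = epochs,
              n_cycles = cycles, beta_max = bmax, ramp_fraction = 0.5)
  # zero at every cycle start
  starts <- seq(0L, epochs - 1L, by = epochs / cycles)
  expect_true(all(b[starts + 1L] == 0))
  # plateau value on the second half of every cycle
  plateau <- unlist(lapply(starts, function(s) s + 10:19))
  expect_true(all(b[plateau + 1L] == bmax))
  # worked ramp value: cycle length 20, ramp 10 epochs, epoch 5 -> half
  expect_equal(cyclic_beta(5, 100, 5, 0.0025, 0.5), 0.00125)
  # piecewise linear within the ramp: constant increments
  ramp <- b[2:10] - b[1:9]
  expect_equal(max(ramp) - min(ramp), 0, tolerance = 1e-15)
  expect_true(all(b >= 0 & b <= bmax))
})

test_that("linear warm-up runs 0 to 1 across training", {
  expect_identical(linear_weight(0, 100), 0)
  expect_identical(linear_weight(99, 100), 1)
  expect_equal(linear_weight(49, 100), 49 / 99)
  expect_identical(linear_weight(0, 1), 1)
  w <- vapply(0:99, linear_weight, 1, epochs = 100)
  expect_equal(diff(w), rep(1 / 99, 99))
})

test_that("split sizes follow floor arithmetic and seeds reproduce", {
  recs <- cage_records(rep(0L, 100), rep("[Lr]C[Lr]", 100), rep(0L, 100),
                       rep(c("collapsed", "not_collapsed"), 50))
  cfg <- train_config(split_original = 0.9, rng_seed = 3L)
  sp <- split_dataset(recs, NULL, cfg)
  expect_identical(nrow(sp$train), 90L)
  expect_identical(nrow(sp$test_original), 10L)
  sp2 <- split_dataset(recs, NULL, cfg)
  expect_identical(sp$train, sp2$train)
  # full-fraction split leaves an empty test set
  sp3 <- split_dataset(recs, NULL, train_config(split_original = 1))
  expect_identical(nrow(sp3$test_original), 0L)

  aug <- cage_records(rep(0L, 57), rep("[Lr]CC[Lr]", 57), rep(0L, 57))
  cfg4 <- train_config(split_original = 0.9, split_augmented = 0.8,
                       rng_seed = 5L)
  sp4 <- split_dataset(recs, aug, cfg4)
  expect_equal(nrow(sp4$train), 90 + floor(0.8 * 57))
  expect_equal(nrow(sp4$test_augmented), 57 - floor(0.8 * 57))
  # partitions are disjoint and exhaustive
  expect_identical(nrow(sp4$train) + nrow(sp4$test_original) +
                     nrow(sp4$test_augmented), 157L)
})

test_that("overfitting a 4-record batch drives the loss down", {
  ds <- make_dataset(fixture_spec(n_bb1 = 2L, n_reactions = 2L,
                                  n_bb2 = 6L, n_cages = 4L,
                                  unlabeled_fraction = 0, rng_seed = 9L))
  vocab <- build_vocabulary(unique(ds$records$bb2_smiles))
  model <- poc_vae(vocab, ds$bb1, ds$reactions, rng_seed = 4L,
                   latent_dim = 6L, encoder_hidden = 24L,
                   decoder_hidden = 32L, embedding_dim = 12L,
                   cat_hidden = 12L, head_hidden = 12L,
                   predictor_hidden = 12L,
                   encoder_decoder_dropout = 0, predictor_dropout = 0)
  fit <- train_poc_vae(model, ds$records,
                       train_config(epochs = 200L, batch_size = 4L,
                                    learning_rate = 5e-3, rng_seed = 1L))
  # 200 epochs x 1 batch = 200 optimisation steps
  tot <- fit$history$train_total
  expect_lt(tot[200], 0.2 * tot[1])
  # broadly decreasing: each quarter improves on the previous one
  q <- split(tot, rep(1:4, each = 50))
  means <- vapply(q, mean, 1)
  expect_true(all(diff(means) < 0))
  expect_gte(min(fit$history$train_kl), 0)
})

test_that("training on fixtures halves the loss and logs curves", {
  fm <- fixture_model()
  h <- fm$history
  expect_identical(nrow(h), 30L)
  expect_lt(h$train_total[30], 0.5 * h$train_total[1])
  expect_true(all(c("test_recon_bb2", "test_total") %in% names(h)))
  expect_true(all(is.finite(h$train_total)))
})

test_that("predictor evaluation thresholds posterior-mean probabilities", {
  fm <- fixture_model()
  lab <- fm$split$test_original[
    fm$split$test_original$label != "unlabeled", , drop = FALSE]
  acc <- evaluate_predictor(fm$model, lab)
  expect_gte(acc, 0); expect_lte(acc, 1)
  expect_identical(acc, evaluate_predictor(fm$model, lab))
  # an untrained model sits near chance level on balanced data
  ds <- fm$ds
  raw <- poc_vae(fm$model$vocab, ds$bb1, ds$reactions, rng_seed = 8L,
                 latent_dim = 12L, encoder_hidden = 48L,
                 decoder_hidden = 64L, embedding_dim = 24L)
  labeled <- ds$records[ds$records$label != "unlabeled", , drop = FALSE]
  acc_raw <- evaluate_predictor(raw, labeled)
  maj <- max(table(labeled$label)) / nrow(labeled)
  expect_lte(acc_raw, maj + 0.1)
  expect_error(evaluate_predictor(fm$model, ds$records), "unlabeled")
})

test_that("checkpoints round-trip the full model", {
  fm <- fixture_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fm$model, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, fm$model$params)
  expect_identical(m2$vocab$tokens, fm$model$vocab$tokens)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "not a poc_vae checkpoint")
})
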
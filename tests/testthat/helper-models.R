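# Shared, lazily trained fixture models (built once per test run).

.fixture_cache <- new.env(parent = emptyenv())

# small labeled fixture dataset shared across files
fixture_dataset <- function() {
  if (is.null(.fixture_cache$ds)) {
    .fixture_cache$ds <- make_dataset(
      fixture_spec(n_bb1 = 3L, n_reactions = 3L, n_bb2 = 30L,
                   n_cages = 150L, unlabeled_fraction = 0.2,
                   rng_seed = 7L))
  }
  .fixture_cache$ds
}

# modest jointly trained model over the fixture dataset
fixture_model <- function() {
  if (is.null(.fixture_cache$fit)) {
    ds <- fixture_dataset()
    vocab <- build_vocabulary(unique(ds$records$bb2_smiles))
    model <- poc_vae(vocab, ds$bb1, ds$reactions, rng_seed = 1L,
                     latent_dim = 12L, encoder_hidden = 48L,
                     decoder_hidden = 64L, embedding_dim = 24L,
                     cat_hidden = 24L, head_hidden = 24L,
                     predictor_hidden = 24L)
    tc <- train_config(epochs = 30L, batch_size = 32L,
                       learning_rate = 4e-3, rng_seed = 1L)
    sp <- split_dataset(ds$records, NULL, tc)
    fit <- train_poc_vae(model, sp$train, tc,
                         test_records = sp$test_original)
    .fixture_cache$fit <- list(model = fit$model, history = fit$history,
                               split = sp, ds = ds)
  }
  .fixture_cache$fit
}

# tiny model overfit on a handful of cages (dropout off, many steps)
overfit_model <- function() {
  if (is.null(.fixture_cache$overfit)) {
    ds <- make_dataset(fixture_spec(n_bb1 = 2L, n_reactions = 2L,
                                    n_bb2 = 8L, n_cages = 6L,
                                    unlabeled_fraction = 0,
                                    rng_seed = 3L))
    vocab <- build_vocabulary(unique(ds$records$bb2_smiles))
    model <- poc_vae(vocab, ds$bb1, ds$reactions, rng_seed = 5L,
                     latent_dim = 8L, encoder_hidden = 32L,
                     decoder_hidden = 48L, embedding_dim = 16L,
                     cat_hidden = 16L, head_hidden = 16L,
                     predictor_hidden = 16L,
                     encoder_decoder_dropout = 0, predictor_dropout = 0)
    tc <- train_config(epochs = 250L, batch_size = 6L,
                       learning_rate = 5e-3, n_cycles = 5L,
                       rng_seed = 2L)
    fit <- train_poc_vae(model, ds$records, tc)
    .fixture_cache$overfit <- list(model = fit$model, records = ds$records,
                                   history = fit$history)
  }
  .fixture_cache$overfit
}
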
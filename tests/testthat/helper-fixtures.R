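# Shared expensive fixtures, built lazily and cached for the session so
# several test files can reuse the same synthetic corpus and trained
# models.

.fixtures <- new.env(parent = emptyenv())

# Default synthetic study corpus: 200 images, 3-finding inventory.
fixture_corpus <- function() {
  if (is.null(.fixtures$manifest)) {
    dir <- file.path(tempdir(), "cxrgen-synth-default")
    .fixtures$manifest <- generate_synth_corpus(synth_spec(), dir)
  }
  .fixtures$manifest
}

# Small corpus for quick smoke tests.
fixture_small_corpus <- function() {
  if (is.null(.fixtures$small_manifest)) {
    dir <- file.path(tempdir(), "cxrgen-synth-small")
    .fixtures$small_manifest <-
      generate_synth_corpus(synth_spec(n_images = 40L, seed = 2L), dir)
  }
  .fixtures$small_manifest
}

# Trained model on the default corpus at the study hyper-parameters
# (Adam, lr 0.001, dropout 0.5, batch 16, <= 30 epochs).
fixture_model <- function(seed = 1L, use_attention = TRUE) {
  key <- paste0("model_", seed, "_", if (use_attention) "att" else "noatt")
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- cxrgen(
      fixture_corpus(), use_attention = use_attention,
      control = train_control(learning_rate = 0.001, batch_size = 16L,
                              max_epochs = 30L, dropout_p = 0.5,
                              seed = seed))
  }
  .fixtures[[key]]
}

# Cheap model on the small corpus for interface-level tests.
fixture_quick_model <- function() {
  if (is.null(.fixtures$quick_model)) {
    .fixtures$quick_model <- cxrgen(
      fixture_small_corpus(),
      control = train_control(batch_size = 8L, max_epochs = 5L, seed = 7L))
  }
  .fixtures$quick_model
}

fixture_heldout_bleu1 <- function(seed = 1L, use_attention = TRUE) {
  key <- paste0("bleu1_", seed, "_", if (use_attention) "att" else "noatt")
  if (is.null(.fixtures[[key]])) {
    ev <- evaluate_reports(fixture_model(seed, use_attention))
    .fixtures[[key]] <- ev$corpus$bleu1
  }
  .fixtures[[key]]
}
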
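# Shared fixtures for the suite: one toy config, one small training set,
# and a cache of trained denoisers so expensive models are trained at most
# once per variant/seed across test files.

toy_cfg <- toy_config()

.toy_train_cache <- new.env(parent = emptyenv())

toy_training_set <- function(n = 150, seed = 11) {
  key <- paste0("data_", n, "_", seed)
  if (is.null(.toy_train_cache[[key]]))
    .toy_train_cache[[key]] <- generate_toy_dataset(toy_cfg, n, seed = seed)
  .toy_train_cache[[key]]
}

# training protocol used for all trained-model evaluations in the suite
trained_model <- function(variant, seed = 1) {
  key <- paste0(variant, "_", seed)
  if (is.null(.toy_train_cache[[key]])) {
    .toy_train_cache[[key]] <- train_toy_denoiser(
      toy_training_set(), variant, epochs = 250, seed = seed,
      hidden = 48, lr = 0.008)
  }
  .toy_train_cache[[key]]
}

# random rows on the probability simplex (independent of package internals)
.runif_simplex_test <- function(n, D) {
  g <- matrix(stats::rexp(n * D), n, D)
  g / rowSums(g)
}

sample_from <- function(model, n_mols, seed, record = "none",
                        n_steps = 100) {
  generate(model, n_mols, model$size_histogram,
           sampler_config(model$variant, n_steps = n_steps, seed = seed,
                          record = record))
}

# cached 25-molecule recorded batch per (variant, seed), shared by the
# distribution-recovery and assignment-time checks
sampled_batch <- function(variant, seed) {
  key <- paste0("batch_", variant, "_", seed)
  if (is.null(.toy_train_cache[[key]])) {
    .toy_train_cache[[key]] <- sample_from(trained_model(variant, seed),
                                           25, seed + 100,
                                           record = "argmax")
  }
  .toy_train_cache[[key]]
}
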
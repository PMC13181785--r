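# Scaled-down study conditions shared by the workflow-level tests:
# 4,096-point spectra, 600 training / 150 validation samples per task and
# stage, 15 pretraining + 30 fine-tuning epochs, learning rate 1e-3,
# default network configuration.  Training is expensive, so trained models
# and their validation sets are cached for the duration of the test session.

.model_cache <- new.env(parent = emptyenv())

scaled_synth_config <- function(n_augment) {
  synth_config(n_points_choices = 4096L, n_augment_per_list = n_augment)
}

scaled_bases <- function() {
  if (is.null(.model_cache$bases))
    .model_cache$bases <- fixture_peaklists(2, seed = 11)
  .model_cache$bases
}

scaled_dataset <- function(task, seed, n_augment, pretrain) {
  build_dataset(scaled_bases(), scaled_synth_config(n_augment), task = task,
                seed = seed, pretrain = pretrain)$samples
}

# Train (once per session) the scaled-down classifier for a task; returns
# list(model, test) where test is a fresh held-out set never used for
# training or best-epoch selection.
scaled_trained <- function(task) {
  key <- paste0("trained_", task)
  if (is.null(.model_cache[[key]])) {
    base_seed <- if (task == "ph0") 1000L else 2000L
    pre_tr <- scaled_dataset(task, base_seed + 1L, 100L, TRUE)
    pre_va <- scaled_dataset(task, base_seed + 2L, 25L, TRUE)
    fin_tr <- scaled_dataset(task, base_seed + 3L, 100L, FALSE)
    fin_va <- scaled_dataset(task, base_seed + 4L, 25L, FALSE)
    test <- scaled_dataset(task, base_seed + 5L, 25L, FALSE)
    model <- build_model(net_config(), seed = 7, quiet = TRUE)
    tcfg <- train_config(epochs = 30, learning_rate = 1e-3,
                         lr_schedule = "cosine", keep_best = TRUE, seed = 42,
                         curriculum = "both")
    model <- train_curriculum(model, pre_tr, pre_va, fin_tr, fin_va, tcfg,
                              pretrain_epochs = 15)
    model$meta$task <- task
    .model_cache[[key]] <- list(model = model, test = test)
  }
  .model_cache[[key]]
}
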
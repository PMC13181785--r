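# Training (Adam, categorical cross-entropy, two-stage curriculum),
# inference, attention-map export, and checkpoint I/O for the classifiers.

#' Training configuration
#'
#' Defaults follow the standard training recipe: Adam with learning rate
#' 1e-4 and decoupled weight decay 1e-5, mini-batches of 4 spectra,
#' categorical cross-entropy, 400 epochs at full scale.  `curriculum` selects
#' whether [train_curriculum()] runs the pretraining stage (coarse phase
#' errors), the fine-tuning stage, or both.
#'
#' @param epochs Training epochs (per stage when used with a curriculum).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param weight_decay Decoupled weight-decay rate.
#' @param clip_norm Global gradient-norm clipping threshold (transformer
#'   training is prone to destabilizing steps without it); `Inf` disables.
#' @param lr_schedule `"constant"`, or `"cosine"` for a cosine decay of the
#'   learning rate to 10% of its initial value across the stage's epochs.
#' @param keep_best Restore the parameters of the epoch with the highest
#'   validation accuracy at the end of the stage (requires a validation set;
#'   epoch-to-epoch validation accuracy is noisy at small batch sizes, and
#'   best-epoch selection is the standard remedy).
#' @param input_noise Standard deviation of fresh Gaussian noise added to
#'   the normalized input channels of every training batch (label-preserving
#'   augmentation that stops the network from memorizing the fixed noise
#'   realization of each training spectrum; 0 disables).
#' @param seed Seed controlling shuffling, dropout and any init performed.
#' @param curriculum One of `"pretrain"`, `"finetune"`, `"both"`.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 400, batch_size = 4, learning_rate = 1e-4,
                         weight_decay = 1e-5, clip_norm = 1,
                         lr_schedule = "constant", keep_best = FALSE,
                         input_noise = 0, seed = 1, curriculum = "both") {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, weight_decay >= 0,
            clip_norm > 0, lr_schedule %in% c("constant", "cosine"),
            input_noise >= 0, curriculum %in% c("pretrain", "finetune", "both"))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 clip_norm = clip_norm, lr_schedule = lr_schedule,
                 keep_best = isTRUE(keep_best), input_noise = input_noise,
                 seed = as.integer(seed), curriculum = curriculum),
            class = "train_config")
}

# Convert a list of training_sample objects into stacked input arrays and an
# integer label vector (1 = negative, 2 = zero, 3 = positive).  All samples
# must share one length.
prepare_training_set <- function(samples, cfg) {
  stopifnot(length(samples) > 0)
  lens <- vapply(samples, function(s) length(s$spectrum$points), 1L)
  if (length(unique(lens)) != 1)
    stop("prepare_training_set: all samples must have the same length within a batch set")
  x <- lapply(samples, function(s) preprocess_input(s$spectrum, cfg))
  y <- vapply(samples, function(s) match(s$label, CLASS_LEVELS), 1L)
  if (any(is.na(y))) stop("prepare_training_set: invalid sample label")
  list(x = x, y = y, n = length(samples), len = lens[1])
}

stack_inputs <- function(xlist, idx) {
  L <- nrow(xlist[[idx[1]]]); Cin <- ncol(xlist[[idx[1]]])
  arr <- array(0, c(L, Cin, length(idx)))
  for (i in seq_along(idx)) arr[, , i] <- xlist[[idx[i]]]
  arr
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, wd) {
  state$t <- state$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr * gr
    upd <- (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
    params[[nm]] <- params[[nm]] - lr * upd - lr * wd * params[[nm]]
  }
  list(params = params, state = state)
}

# Cross-entropy loss and dlogits for integer labels y (B-vector).
ce_loss <- function(logits, y) {
  pr <- softmax_rows(logits)
  B <- nrow(logits)
  ll <- -mean(log(pmax(pr[cbind(seq_len(B), y)], 1e-12)))
  dl <- pr
  dl[cbind(seq_len(B), y)] <- dl[cbind(seq_len(B), y)] - 1
  list(loss = ll, dlogits = dl / B, probs = pr)
}

#' Train a classifier on one labeled dataset
#'
#' Runs mini-batch Adam with categorical cross-entropy.  Shuffling and
#' dropout are driven by `tcfg$seed`, so a run is fully reproducible.
#' Training aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model A [build_model()] result (possibly already trained).
#' @param train_samples,val_samples Lists of `training_sample` objects (the
#'   validation list may be `NULL`).
#' @param tcfg A [train_config()].
#' @param verbose Print a line per epoch.
#' @return The model with updated parameters and a `history` data frame
#'   (epoch, train loss/accuracy, validation loss/accuracy) appended to
#'   `model$history`.
#' @export
train <- function(model, train_samples, val_samples = NULL,
                  tcfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "tandem_model"), inherits(tcfg, "train_config"))
  if (length(train_samples) == 0) stop("train: empty training set")
  tr <- prepare_training_set(train_samples, model$cfg)
  va <- if (!is.null(val_samples) && length(val_samples) > 0)
    prepare_training_set(val_samples, model$cfg) else NULL
  st <- adam_init(model$params)
  hist <- list()
  best_acc <- -Inf
  best_params <- NULL
  for (ep in seq_len(tcfg$epochs)) {
    lr_ep <- if (tcfg$lr_schedule == "cosine")
      tcfg$learning_rate * (0.55 + 0.45 * cos(pi * (ep - 1) / max(1, tcfg$epochs - 1)))
    else tcfg$learning_rate
    ord <- with_seed(derive_seed(tcfg$seed, 7001, ep), sample.int(tr$n))
    nb <- ceiling(tr$n / tcfg$batch_size)
    tot_loss <- 0; tot_correct <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1) * tcfg$batch_size + 1):min(bi * tcfg$batch_size, tr$n)]
      x <- stack_inputs(tr$x, idx)
      if (tcfg$input_noise > 0)
        x <- x + with_seed(derive_seed(tcfg$seed, 7003, ep, bi),
                           stats::rnorm(length(x), 0, tcfg$input_noise))
      stp <- nn_step_cpp(model$params, unclass(model$cfg), x, tr$y[idx],
                         model$cfg$dropout,
                         derive_seed(tcfg$seed, 7002, ep, bi))
      if (!is.finite(stp$loss))
        stop(sprintf("train: loss diverged (non-finite) at epoch %d batch %d", ep, bi))
      grads <- stp$grads
      if (is.finite(tcfg$clip_norm)) {
        gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 1.0)))
        if (gn > tcfg$clip_norm)
          grads <- lapply(grads, function(g) g * (tcfg$clip_norm / gn))
      }
      up <- adam_step(model$params, grads, st, lr_ep, tcfg$weight_decay)
      model$params <- up$params; st <- up$state
      tot_loss <- tot_loss + stp$loss * length(idx)
      tot_correct <- tot_correct + sum(max.col(stp$probs) == tr$y[idx])
    }
    row <- data.frame(epoch = ep, train_loss = tot_loss / tr$n,
                      train_acc = tot_correct / tr$n,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(va)) {
      ev <- evaluate_set(model, va)
      row$val_loss <- ev$loss; row$val_acc <- ev$accuracy
      if (tcfg$keep_best && ev$accuracy > best_acc) {
        best_acc <- ev$accuracy
        best_params <- model$params
      }
    }
    hist[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f%s", ep, row$train_loss,
                      row$train_acc,
                      if (!is.null(va)) sprintf("  val_acc %.3f", row$val_acc) else ""))
  }
  if (tcfg$keep_best && !is.null(best_params)) model$params <- best_params
  model$history <- rbind(model$history, do.call(rbind, hist))
  model
}

# Loss/accuracy of a model on a prepared set (internal; batched forward).
evaluate_set <- function(model, prepped, batch = 16L) {
  n <- prepped$n
  loss <- 0; correct <- 0
  for (bi in seq_len(ceiling(n / batch))) {
    idx <- ((bi - 1) * batch + 1):min(bi * batch, n)
    fw <- nn_infer_cpp(model$params, unclass(model$cfg),
                       stack_inputs(prepped$x, idx), FALSE)
    cl <- ce_loss(fw$logits, prepped$y[idx])
    loss <- loss + cl$loss * length(idx)
    correct <- correct + sum(max.col(cl$probs) == prepped$y[idx])
  }
  list(loss = loss / n, accuracy = correct / n)
}

#' Evaluate a classifier on labeled samples
#'
#' @param model A trained model.
#' @param samples List of `training_sample` objects.
#' @return List with `accuracy`, `loss`, `confusion` (3 x 3 table,
#'   rows = truth) and `predicted` (class labels).
#' @export
evaluate <- function(model, samples) {
  pr <- prepare_training_set(samples, model$cfg)
  preds <- integer(pr$n)
  batch <- 16L
  for (bi in seq_len(ceiling(pr$n / batch))) {
    idx <- ((bi - 1) * batch + 1):min(bi * batch, pr$n)
    fw <- nn_infer_cpp(model$params, unclass(model$cfg),
                       stack_inputs(pr$x, idx), FALSE)
    preds[idx] <- max.col(softmax_rows(fw$logits))
  }
  ev <- evaluate_set(model, pr)
  conf <- table(factor(CLASS_LEVELS[pr$y], levels = CLASS_LEVELS),
                factor(CLASS_LEVELS[preds], levels = CLASS_LEVELS))
  list(accuracy = ev$accuracy, loss = ev$loss, confusion = conf,
       predicted = CLASS_LEVELS[preds])
}

#' Two-stage curriculum training
#'
#' Stage 1 trains on a coarse-error pretraining set (easier discrimination),
#' stage 2 continues from the pretrained weights on the fine-error set.
#' Which stages run is controlled by `tcfg$curriculum`.
#'
#' @param model A [build_model()] result.
#' @param pretrain_train,pretrain_val Pretraining-stage sample lists.
#' @param fine_train,fine_val Fine-tuning-stage sample lists.
#' @param tcfg A [train_config()]; `epochs` applies to the fine stage.
#' @param pretrain_epochs Epochs of the pretraining stage (defaults to
#'   `tcfg$epochs`).
#' @return The trained model (with combined history).
#' @export
train_curriculum <- function(model, pretrain_train, pretrain_val,
                             fine_train, fine_val, tcfg = train_config(),
                             pretrain_epochs = tcfg$epochs) {
  if (tcfg$curriculum %in% c("pretrain", "both")) {
    pt <- tcfg; pt$epochs <- as.integer(pretrain_epochs)
    pt$seed <- derive_seed(tcfg$seed, 1)
    model <- train(model, pretrain_train, pretrain_val, pt)
  }
  if (tcfg$curriculum %in% c("finetune", "both")) {
    ft <- tcfg; ft$seed <- derive_seed(tcfg$seed, 2)
    model <- train(model, fine_train, fine_val, ft)
  }
  model
}

#' Classify the sign of the phase error of a spectrum
#'
#' Deterministic at inference (no dropout).
#'
#' @param model A trained model.
#' @param spec A [spectrum1d()].
#' @return A list of class `classifier_output` with `probs` and `logits`
#'   (named 3-vectors over negative/zero/positive).
#' @export
predict_phase_class <- function(model, spec) {
  x <- preprocess_input(spec, model$cfg)
  fw <- nn_infer_cpp(model$params, unclass(model$cfg),
                     array(x, c(nrow(x), ncol(x), 1)), FALSE)
  logits <- drop(fw$logits)
  probs <- drop(softmax_rows(fw$logits))
  names(logits) <- names(probs) <- CLASS_LEVELS
  structure(list(probs = probs, logits = logits), class = "classifier_output")
}

#' @export
print.classifier_output <- function(x, ...) {
  cat(sprintf("<classifier_output: P(neg)=%.3f P(zero)=%.3f P(pos)=%.3f>\n",
              x$probs[1], x$probs[2], x$probs[3]))
  invisible(x)
}

#' Export per-layer, per-head self-attention maps
#'
#' @param model A trained model.
#' @param spec A [spectrum1d()].
#' @return Array of dimension `(n_layers, n_heads, n_tokens, n_tokens)`;
#'   every attention row is a probability distribution over tokens.
#' @export
attention_maps <- function(model, spec) {
  x <- preprocess_input(spec, model$cfg)
  fw <- nn_infer_cpp(model$params, unclass(model$cfg),
                     array(x, c(nrow(x), ncol(x), 1)), TRUE)
  fw$attention
}

# -- checkpoints -------------------------------------------------------------

#' Save a model checkpoint
#'
#' The checkpoint is a pair of files: `<path>.json` holds the network
#' configuration, metadata and the shape of every parameter tensor in order;
#' `<path>.bin` holds the concatenated parameter values as little-endian
#' float64.  Loading validates shapes against the embedded configuration.
#'
#' @param model A `tandem_model`.
#' @param path Checkpoint path without extension.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  shapes <- lapply(model$params, function(p) if (is.matrix(p)) dim(p) else length(p))
  manifest <- list(format = "nmrphaser-checkpoint-v1",
                   cfg = unclass(model$cfg), meta = model$meta,
                   n_params = model$n_params,
                   tensors = lapply(names(model$params), function(nm)
                     list(name = nm, shape = as.integer(shapes[[nm]]))))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (nm in names(model$params))
    writeBin(as.numeric(model$params[[nm]]), con, size = 8, endian = "little")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint path without extension (expects `<path>.json` and
#'   `<path>.bin`).
#' @return A `tandem_model`.
#' @export
load_checkpoint <- function(path) {
  jf <- paste0(path, ".json"); bf <- paste0(path, ".bin")
  if (!file.exists(jf) || !file.exists(bf))
    stop("load_checkpoint: missing ", jf, " or ", bf)
  man <- jsonlite::read_json(jf, simplifyVector = FALSE)
  if (!identical(man$format, "nmrphaser-checkpoint-v1"))
    stop("load_checkpoint: not a recognized checkpoint manifest")
  cfgl <- man$cfg
  cfg <- net_config(downsample_factor = cfgl$downsample_factor,
                    embed_dim = cfgl$embed_dim, n_layers = cfgl$n_layers,
                    n_heads = cfgl$n_heads,
                    rel_bias_buckets = cfgl$rel_bias_buckets,
                    max_field_of_view = cfgl$max_field_of_view,
                    dropout = cfgl$dropout,
                    conv_channels = unlist(cfgl$conv_channels),
                    conv_strides = unlist(cfgl$conv_strides),
                    conv_kernels = unlist(cfgl$conv_kernels),
                    mlp_mult = cfgl$mlp_mult, head_hidden = cfgl$head_hidden,
                    input_channels = cfgl$input_channels,
                    input_compression =
                      if (is.null(cfgl$input_compression)) 0
                      else cfgl$input_compression)
  con <- file(bf, "rb")
  on.exit(close(con))
  params <- list()
  for (tns in man$tensors) {
    shape <- unlist(tns$shape)
    n <- prod(shape)
    vals <- readBin(con, "numeric", n = n, size = 8, endian = "little")
    if (length(vals) != n)
      stop("load_checkpoint: truncated weight file at tensor ", tns$name)
    params[[tns$name]] <- if (length(shape) == 2) matrix(vals, shape[1], shape[2])
                          else vals
  }
  structure(list(cfg = cfg, params = params,
                 n_params = sum(vapply(params, length, 1L)),
                 meta = man$meta),
            class = "tandem_model")
}
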
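# Classifier architecture, gradients, training mechanics.

test_that("preprocessing normalizes, is scale invariant, and rejects bad input", {
  cfg <- tiny_net_config()
  s <- dense_spec(1024, 10, seed = 5)
  x <- preprocess_input(s, cfg)
  expect_equal(dim(x), c(1024L, 2L))
  expect_equal(max(abs(x[, 1])), 1)

  s10 <- s; s10$points <- s$points * 10
  expect_equal(preprocess_input(s10, cfg), x)

  zero <- spectrum1d(complex(real = numeric(64), imaginary = rnorm(64)))
  expect_error(preprocess_input(zero, cfg), "degenerate")

  long <- spectrum1d(complex(cfg$max_field_of_view + 32))
  expect_error(preprocess_input(long, cfg), "field of view")
})

test_that("relative position bias is shift invariant, signed, and bucketed", {
  cfg <- tiny_net_config()
  bm <- relative_position_bias(32, cfg)
  # depends only on i - j: constant along diagonals
  for (d in c(-5, 0, 3, 17))
    expect_length(unique(bm[row(bm) - col(bm) == d]), 1)
  # order sensitivity: transposed offsets map to different buckets
  expect_false(bm[5, 1] == bm[1, 5])
  # bucket indices live in 1 .. 2*rel_bias_buckets + 1, and the parameter
  # tensor holds exactly that many learned scalars per head
  expect_true(all(bm >= 1 & bm <= 2 * cfg$rel_bias_buckets + 1))
  m <- build_model(cfg, seed = 1, quiet = TRUE)
  expect_equal(nrow(m$params$t1_relb), 2 * cfg$rel_bias_buckets + 1)
})

test_that("the model accepts variable input lengths and outputs a 3-simplex", {
  cfg <- tiny_net_config()
  m <- build_model(cfg, seed = 2, quiet = TRUE)
  expect_gt(m$n_params, 0)
  expect_lt(m$n_params, 1e6)
  for (n in c(2048, 4096)) {
    out <- predict_phase_class(m, dense_spec(n, 10, seed = 6))
    expect_length(out$probs, 3)
    expect_equal(sum(out$probs), 1, tolerance = 1e-6)
    expect_true(all(out$probs >= 0))
  }
  expect_message(build_model(cfg, seed = 2), "trainable parameters")
})

test_that("compiled gradients match finite differences and the R reference", {
  cfg <- net_config(downsample_factor = 8, embed_dim = 8, n_layers = 2,
                    n_heads = 2, rel_bias_buckets = 4,
                    max_field_of_view = 1024, dropout = 0,
                    conv_channels = c(4, 6), conv_strides = c(2, 2, 2),
                    conv_kernels = c(5, 3, 3), mlp_mult = 2, head_hidden = 5,
                    input_channels = 2)
  m <- build_model(cfg, seed = 3, quiet = TRUE)
  set.seed(42)
  L <- 64; B <- 3
  x <- array(rnorm(L * 2 * B), c(L, 2, B))
  y <- c(1L, 2L, 3L)

  stp <- nn_step_cpp(m$params, unclass(cfg), x, y, 0, 1)

  # independent R implementation of the same architecture
  fw <- nn_forward(m, x, keep = TRUE)
  cl <- ce_loss(fw$logits, y)
  gR <- nn_backward(m, fw, cl$dlogits)
  expect_equal(stp$loss, cl$loss, tolerance = 1e-12)
  expect_equal(stp$logits, fw$logits, tolerance = 1e-12)
  for (nm in names(m$params))
    expect_equal(as.numeric(stp$grads[[nm]]), as.numeric(gR[[nm]]),
                 tolerance = 1e-10)

  # finite-difference oracle on a sample of entries from every tensor
  lossfn <- function(mm) nn_step_cpp(mm$params, unclass(cfg), x, y, 0, 1)$loss
  eps <- 1e-6
  set.seed(7)
  for (nm in names(m$params)) {
    ii <- sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))
    for (i in ii) {
      m2 <- m; m2$params[[nm]][i] <- m$params[[nm]][i] + eps
      m3 <- m; m3$params[[nm]][i] <- m$params[[nm]][i] - eps
      num <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
      ana <- stp$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("training reduces the loss on a toy set and is seed deterministic", {
  samples <- toy_training_set(n_per_class = 20, n_points = 512, seed = 14)
  expect_length(samples, 60)
  cfg <- tiny_net_config()
  m0 <- build_model(cfg, seed = 5, quiet = TRUE)
  tc <- train_config(epochs = 20, learning_rate = 1e-3, seed = 3)
  m1 <- train(m0, samples, NULL, tc)
  h <- m1$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])

  m2 <- train(m0, samples, NULL, tc)
  expect_equal(m1$history$train_loss, m2$history$train_loss, tolerance = 1e-6)

  expect_error(train(m0, list(), NULL, tc), "empty")
})

test_that("inference is deterministic and scale invariant", {
  cfg <- tiny_net_config()
  m <- build_model(cfg, seed = 9, quiet = TRUE)
  s <- dense_spec(1024, 12, seed = 3)
  p1 <- predict_phase_class(m, s)
  p2 <- predict_phase_class(m, s)
  expect_identical(p1$probs, p2$probs)
  s100 <- s; s100$points <- s$points * 100
  expect_equal(predict_phase_class(m, s100)$probs, p1$probs, tolerance = 1e-12)
})

test_that("attention maps are row-stochastic with length-dependent shape", {
  cfg <- tiny_net_config()
  m <- build_model(cfg, seed = 4, quiet = TRUE)
  a1 <- attention_maps(m, dense_spec(512, 8, seed = 2))
  expect_equal(dim(a1), c(cfg$n_layers, cfg$n_heads, 64, 64))
  for (l in seq_len(cfg$n_layers))
    for (hh in seq_len(cfg$n_heads))
      expect_equal(rowSums(a1[l, hh, , ]), rep(1, 64), tolerance = 1e-5)
  a2 <- attention_maps(m, dense_spec(1024, 8, seed = 2))
  expect_equal(dim(a2)[3], 128)
})

test_that("checkpoints round-trip weights, config and metadata", {
  cfg <- tiny_net_config()
  m <- build_model(cfg, seed = 8, quiet = TRUE)
  m$meta$task <- "ph0"
  path <- file.path(tempdir(), "ckpt_test")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$meta$task, "ph0")
  expect_equal(m2$cfg$embed_dim, cfg$embed_dim)
  for (nm in names(m$params))
    expect_equal(as.numeric(m2$params[[nm]]), as.numeric(m$params[[nm]]))
  s <- dense_spec(512, 6, seed = 1)
  expect_equal(predict_phase_class(m2, s)$probs,
               predict_phase_class(m, s)$probs, tolerance = 1e-12)
  expect_error(load_checkpoint(file.path(tempdir(), "nope")), "missing")
})
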
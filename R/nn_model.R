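# Sign-of-phase-error classifier: strided 1D convolutional front end
# (local lineshape features + sequence-length reduction) -> token embedding ->
# transformer encoder with a learned relative position bias (translation
# invariant, order and distance aware) -> global average pooling over tokens
# (so any input length up to the maximum field of view is accepted) ->
# fully connected 3-class head over {negative, zero, positive}.
#
# Implemented natively: forward and backward passes are hand-written around
# BLAS matrix products, trained with Adam (see nn_train.R).  The class index
# order is fixed as (negative, zero, positive) everywhere.

CLASS_LEVELS <- c("negative", "zero", "positive")

#' Network configuration
#'
#' @param downsample_factor Points per token produced by the convolutional
#'   front end (product of the conv strides).
#' @param embed_dim Token embedding dimension.
#' @param n_layers Number of transformer encoder layers.
#' @param n_heads Attention heads per layer.
#' @param rel_bias_buckets Log-spaced relative-distance buckets per direction;
#'   each head learns `2 * rel_bias_buckets + 1` bias scalars.
#' @param max_field_of_view Maximum input length in complex points; the
#'   maximum token count is `max_field_of_view / downsample_factor`.
#' @param dropout Dropout probability applied during training to the
#'   attention output and the MLP hidden layer (0 disables it).
#' @param conv_channels Channel widths of the conv layers before the final
#'   projection to `embed_dim`.
#' @param conv_strides Stride of each conv layer; must multiply to
#'   `downsample_factor`.
#' @param conv_kernels Kernel size of each conv layer.
#' @param mlp_mult Width multiplier of the transformer MLP hidden layer.
#' @param head_hidden Hidden width of the fully connected classification head.
#' @param input_channels 2 for (real, imaginary) input, 1 for real-only.
#' @param input_compression Amplitude-compression strength `c`: after
#'   normalization, channels are mapped through `asinh(c*x)/asinh(c)`,
#'   boosting the small-amplitude lineshape features (dips, tails) that carry
#'   the signature of sub-degree phase errors — the numerical analogue of a
#'   spectroscopist inspecting the spectrum at a few-hundred-fold vertical
#'   zoom.  0 disables compression.
#' @return A list of class `net_config`.
#' @export
net_config <- function(downsample_factor = 32, embed_dim = 64, n_layers = 4,
                       n_heads = 4, rel_bias_buckets = 32,
                       max_field_of_view = 131072, dropout = 0.1,
                       conv_channels = c(16, 32, 64),
                       conv_strides = c(4, 2, 2, 2),
                       conv_kernels = c(9, 5, 5, 5),
                       mlp_mult = 2, head_hidden = 32, input_channels = 2,
                       input_compression = 100) {
  if (prod(conv_strides) != downsample_factor)
    stop("net_config: conv_strides must multiply to downsample_factor")
  if (length(conv_kernels) != length(conv_strides))
    stop("net_config: conv_kernels and conv_strides must have equal length")
  if (length(conv_channels) != length(conv_strides) - 1)
    stop("net_config: need one fewer conv_channels than strides (last layer outputs embed_dim)")
  if (embed_dim %% n_heads != 0)
    stop("net_config: embed_dim must be divisible by n_heads")
  stopifnot(max_field_of_view %% downsample_factor == 0,
            dropout >= 0, dropout < 1, input_channels %in% c(1, 2),
            input_compression >= 0)
  structure(list(downsample_factor = downsample_factor, embed_dim = embed_dim,
                 n_layers = n_layers, n_heads = n_heads,
                 rel_bias_buckets = rel_bias_buckets,
                 max_field_of_view = max_field_of_view, n_classes = 3L,
                 dropout = dropout, conv_channels = conv_channels,
                 conv_strides = conv_strides, conv_kernels = conv_kernels,
                 mlp_mult = mlp_mult, head_hidden = head_hidden,
                 input_channels = input_channels,
                 input_compression = input_compression),
            class = "net_config")
}

#' Preprocess a spectrum into network input channels
#'
#' Produces an `N x 2` matrix of (real, imaginary) channels, both divided by
#' the maximum absolute value of the real part, so the representation is
#' invariant to uniform rescaling of the spectrum.
#'
#' @param spec A [spectrum1d()].
#' @param cfg A [net_config()] (supplies the field-of-view limit and channel count).
#' @return Numeric matrix with `N` rows and `cfg$input_channels` columns.
#' @export
preprocess_input <- function(spec, cfg = net_config()) {
  stopifnot(inherits(spec, "spectrum1d"))
  n <- length(spec$points)
  if (n > cfg$max_field_of_view)
    stop(sprintf("preprocess_input: spectrum has %d points, exceeding the maximum field of view of %d",
                 n, cfg$max_field_of_view))
  sc <- max(abs(Re(spec$points)))
  if (sc == 0) stop("preprocess_input: degenerate input (real part identically zero)")
  x <- cbind(Re(spec$points), Im(spec$points)) / sc
  x <- x[, seq_len(cfg$input_channels), drop = FALSE]
  if (cfg$input_compression > 0)
    x <- asinh(cfg$input_compression * x) / asinh(cfg$input_compression)
  x
}

# -- relative position bias --------------------------------------------------

# Signed log-spaced bucket index (1 .. 2B+1) for token offset d = i - j.
# Small offsets get exact buckets; larger ones share log-spaced buckets up to
# the maximum token distance.  Sign is preserved so the bias can distinguish
# left from right neighbours.
rel_bucket_index <- function(d, n_buckets, max_distance) {
  exact <- max(1L, n_buckets %/% 2L)
  ad <- abs(d)
  b <- integer(length(d))
  small <- ad > 0 & ad <= exact
  b[small] <- ad[small]
  big <- ad > exact
  if (any(big)) {
    lg <- exact + 1L +
      floor(log(ad[big] / exact) / log(max(max_distance, exact + 1) / exact) *
              (n_buckets - exact - 1L))
    b[big] <- pmin(as.integer(lg), n_buckets)
  }
  as.integer(n_buckets + 1L + sign(d) * b)
}

#' Relative-position attention-bias structure for a token count
#'
#' The attention bias `bias[i, j]` depends only on the offset `i - j`
#' (translation invariance) through one learned scalar per signed log-spaced
#' distance bucket, so sequential order (sign) and pairwise distance are both
#' captured.  This returns the `n_tokens x n_tokens` bucket-index matrix used
#' to expand the `2 * rel_bias_buckets + 1` learned scalars of each head into
#' a full bias matrix.
#'
#' @param n_tokens Number of tokens (>= 1).
#' @param cfg A [net_config()].
#' @return Integer matrix of bucket indices in `1 .. 2 * rel_bias_buckets + 1`.
#' @export
relative_position_bias <- function(n_tokens, cfg = net_config()) {
  stopifnot(n_tokens >= 1)
  maxd <- cfg$max_field_of_view %/% cfg$downsample_factor
  d <- outer(seq_len(n_tokens), seq_len(n_tokens), "-")
  matrix(rel_bucket_index(as.vector(d), cfg$rel_bias_buckets, maxd),
         n_tokens, n_tokens)
}

# -- parameter construction --------------------------------------------------

rand_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

#' Build an untrained classifier model
#'
#' Initializes all parameters (seeded) and reports the trainable parameter
#' count.  The model accepts any input length that is a multiple of the
#' downsample factor, up to the maximum field of view.
#'
#' @param cfg A [net_config()].
#' @param seed Integer seed for the parameter initialization.
#' @param quiet Suppress the parameter-count message.
#' @return A list of class `tandem_model` with fields `cfg`, `params`,
#'   `n_params` and `meta`.
#' @export
build_model <- function(cfg = net_config(), seed = 1, quiet = FALSE) {
  stopifnot(inherits(cfg, "net_config"))
  D <- cfg$embed_dim
  p <- list()
  with_seed(seed, {
    ch <- c(cfg$input_channels, cfg$conv_channels, D)
    for (l in seq_along(cfg$conv_strides)) {
      fan_in <- cfg$conv_kernels[l] * ch[l]
      p[[paste0("conv", l, "_W")]] <- rand_mat(fan_in, ch[l + 1], sqrt(2 / fan_in))
      p[[paste0("conv", l, "_b")]] <- numeric(ch[l + 1])
    }
    nb <- 2L * cfg$rel_bias_buckets + 1L
    for (l in seq_len(cfg$n_layers)) {
      pre <- paste0("t", l, "_")
      p[[paste0(pre, "ln1_g")]] <- rep(1, D)
      p[[paste0(pre, "ln1_b")]] <- numeric(D)
      p[[paste0(pre, "Wq")]] <- rand_mat(D, D, sqrt(1 / D))
      p[[paste0(pre, "Wk")]] <- rand_mat(D, D, sqrt(1 / D))
      p[[paste0(pre, "Wv")]] <- rand_mat(D, D, sqrt(1 / D))
      p[[paste0(pre, "Wo")]] <- rand_mat(D, D, sqrt(1 / D))
      p[[paste0(pre, "bo")]] <- numeric(D)
      p[[paste0(pre, "relb")]] <- matrix(0, nb, cfg$n_heads)
      p[[paste0(pre, "ln2_g")]] <- rep(1, D)
      p[[paste0(pre, "ln2_b")]] <- numeric(D)
      H <- D * cfg$mlp_mult
      p[[paste0(pre, "W1")]] <- rand_mat(D, H, sqrt(2 / D))
      p[[paste0(pre, "b1")]] <- numeric(H)
      p[[paste0(pre, "W2")]] <- rand_mat(H, D, sqrt(1 / H))
      p[[paste0(pre, "b2")]] <- numeric(D)
    }
    p[["lnf_g"]] <- rep(1, D)
    p[["lnf_b"]] <- numeric(D)
    p[["head_W1"]] <- rand_mat(D, cfg$head_hidden, sqrt(2 / D))
    p[["head_b1"]] <- numeric(cfg$head_hidden)
    p[["head_W2"]] <- rand_mat(cfg$head_hidden, cfg$n_classes,
                               sqrt(1 / cfg$head_hidden))
    p[["head_b2"]] <- numeric(cfg$n_classes)
  })
  n_params <- sum(vapply(p, length, 1L))
  if (!quiet)
    message(sprintf("build_model: %d trainable parameters (%d tensors)",
                    n_params, length(p)))
  structure(list(cfg = cfg, params = p, n_params = n_params,
                 meta = list(seed = seed, task = NULL, synth_config = NULL)),
            class = "tandem_model")
}

#' @export
print.tandem_model <- function(x, ...) {
  cat(sprintf("<tandem_model: %d params, %d transformer layers, %d heads, task = %s>\n",
              x$n_params, x$cfg$n_layers, x$cfg$n_heads,
              if (is.null(x$meta$task)) "untrained" else x$meta$task))
  invisible(x)
}

# -- caches (per input length) ----------------------------------------------

.nn_cache <- new.env(parent = emptyenv())

# im2col row-index matrix (T x K) into a (1:Lp)-padded input; 0 = zero pad.
conv_index <- function(L, K, stride) {
  key <- sprintf("ci_%d_%d_%d", L, K, stride)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Tn <- ceiling(L / stride)
  pad <- (K - 1L) %/% 2L
  idx <- outer(0:(Tn - 1) * stride - pad, 0:(K - 1), "+") + 1L  # T x K, 1-based
  idx[idx < 1 | idx > L] <- 0L
  .nn_cache[[key]] <- list(idx = idx, Tn = Tn)
  .nn_cache[[key]]
}

bucket_matrix <- function(n_tokens, cfg) {
  key <- sprintf("bm_%d_%d_%d", n_tokens, cfg$rel_bias_buckets,
                 cfg$max_field_of_view %/% cfg$downsample_factor)
  if (is.null(.nn_cache[[key]]))
    .nn_cache[[key]] <- relative_position_bias(n_tokens, cfg)
  .nn_cache[[key]]
}

# -- forward / backward ------------------------------------------------------

# One strided conv layer on a batch.
# x: array (L, Cin, B).  Returns list(y = array (T, Cout, B), cache).
conv_forward <- function(x, W, b, K, stride) {
  L <- dim(x)[1]; Cin <- dim(x)[2]; B <- dim(x)[3]
  ci <- conv_index(L, K, stride)
  Tn <- ci$Tn
  xz <- rbind(matrix(x, L, Cin * B), 0)          # (L+1, Cin*B); row L+1 = zeros
  idx <- ci$idx; idx[idx == 0L] <- L + 1L
  xcol <- xz[as.vector(idx), , drop = FALSE]     # (T*K, Cin*B)
  dim(xcol) <- c(Tn, K, Cin, B)
  xcol <- aperm(xcol, c(1, 4, 2, 3))             # (T, B, K, Cin)
  dim(xcol) <- c(Tn * B, K * Cin)
  y <- xcol %*% W
  y <- sweep(y, 2, b, "+")
  dim(y) <- c(Tn, B, ncol(W))
  y <- aperm(y, c(1, 3, 2))                      # (T, Cout, B)
  list(y = y, xcol = xcol, idx = idx, L = L, Cin = Cin, B = B, Tn = Tn, K = K)
}

conv_backward <- function(dy, W, cache) {
  Tn <- cache$Tn; B <- cache$B; K <- cache$K; Cin <- cache$Cin; L <- cache$L
  dy <- aperm(dy, c(1, 3, 2))                    # (T, B, Cout)
  dim(dy) <- c(Tn * B, dim(W)[2])
  dW <- crossprod(cache$xcol, dy)
  db <- colSums(dy)
  dxcol <- tcrossprod(dy, W)                     # (T*B, K*Cin)
  dim(dxcol) <- c(Tn, B, K, Cin)
  dxcol <- aperm(dxcol, c(1, 3, 4, 2))           # (T, K, Cin, B)
  dim(dxcol) <- c(Tn * K, Cin * B)
  acc <- rowsum(dxcol, group = as.vector(cache$idx))
  dxz <- matrix(0, L + 1, Cin * B)
  dxz[as.integer(rownames(acc)), ] <- acc
  dx <- dxz[seq_len(L), , drop = FALSE]
  dim(dx) <- c(L, Cin, B)
  list(dx = dx, dW = dW, db = db)
}

layer_norm_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + 1e-5)
  xhat <- xc * istd
  y <- sweep(xhat, 2, g, "*")
  y <- sweep(y, 2, b, "+")
  list(y = y, xhat = xhat, istd = istd)
}

layer_norm_backward <- function(dy, g, cache) {
  xhat <- cache$xhat; istd <- cache$istd
  D <- ncol(dy)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, "*")
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * istd
  list(dx = dx, dg = dg, db = db)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full forward pass.
# x: array (L, Cin, B).  Returns logits (B x 3) and, if keep = TRUE, all
# intermediate activations needed for the backward pass.
nn_forward <- function(model, x, keep = FALSE, dropout_seed = NULL,
                       keep_attention = FALSE) {
  cfg <- model$cfg; p <- model$params
  B <- dim(x)[3]
  caches <- list()
  h <- x
  relu_masks <- list()
  for (l in seq_along(cfg$conv_strides)) {
    cf <- conv_forward(h, p[[paste0("conv", l, "_W")]],
                       p[[paste0("conv", l, "_b")]],
                       cfg$conv_kernels[l], cfg$conv_strides[l])
    m <- cf$y > 0
    h <- cf$y * m
    if (keep) { caches[[paste0("conv", l)]] <- cf; relu_masks[[l]] <- m }
  }
  Tn <- dim(h)[1]; D <- dim(h)[2]
  X <- aperm(h, c(1, 3, 2))                       # (T, B, D)
  dim(X) <- c(Tn * B, D)                          # rows: t fastest, then b
  bm <- bucket_matrix(Tn, cfg)
  dh <- D %/% cfg$n_heads
  drop_p <- if (!is.null(dropout_seed)) cfg$dropout else 0
  if (drop_p > 0) set.seed(dropout_seed)
  attn_store <- if (keep_attention)
    array(NA_real_, c(cfg$n_layers, cfg$n_heads, Tn, Tn)) else NULL

  blk <- function(b) ((b - 1) * Tn + 1):(b * Tn)
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("t", l, "_")
    ln1 <- layer_norm_forward(X, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    Q <- ln1$y %*% p[[paste0(pre, "Wq")]]
    Km <- ln1$y %*% p[[paste0(pre, "Wk")]]
    V <- ln1$y %*% p[[paste0(pre, "Wv")]]
    O <- matrix(0, Tn * B, D)
    A_list <- if (keep) vector("list", B * cfg$n_heads) else NULL
    for (b in seq_len(B)) {
      rb <- blk(b)
      for (hh in seq_len(cfg$n_heads)) {
        cs <- ((hh - 1) * dh + 1):(hh * dh)
        bias <- matrix(p[[paste0(pre, "relb")]][, hh][bm], Tn, Tn)
        S <- tcrossprod(Q[rb, cs, drop = FALSE], Km[rb, cs, drop = FALSE]) /
          sqrt(dh) + bias
        A <- softmax_rows(S)
        if (keep_attention) attn_store[l, hh, , ] <- A
        if (keep) A_list[[(b - 1) * cfg$n_heads + hh]] <- A
        O[rb, cs] <- A %*% V[rb, cs, drop = FALSE]
      }
    }
    AO <- O %*% p[[paste0(pre, "Wo")]]
    AO <- sweep(AO, 2, p[[paste0(pre, "bo")]], "+")
    dm1 <- NULL
    if (drop_p > 0) {
      dm1 <- matrix(stats::runif(length(AO)) >= drop_p, nrow(AO)) / (1 - drop_p)
      AO <- AO * dm1
    }
    X1 <- X + AO
    ln2 <- layer_norm_forward(X1, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    Hpre <- sweep(ln2$y %*% p[[paste0(pre, "W1")]], 2, p[[paste0(pre, "b1")]], "+")
    Hm <- Hpre > 0
    Hh <- Hpre * Hm
    dm2 <- NULL
    if (drop_p > 0) {
      dm2 <- matrix(stats::runif(length(Hh)) >= drop_p, nrow(Hh)) / (1 - drop_p)
      Hh <- Hh * dm2
    }
    M <- sweep(Hh %*% p[[paste0(pre, "W2")]], 2, p[[paste0(pre, "b2")]], "+")
    X2 <- X1 + M
    if (keep)
      caches[[pre]] <- list(ln1 = ln1, Q = Q, K = Km, V = V, A_list = A_list,
                            O = O, X = X, X1 = X1, ln2 = ln2, Hm = Hm, Hh = Hh,
                            dm1 = dm1, dm2 = dm2)
    X <- X2
  }
  lnf <- layer_norm_forward(X, p[["lnf_g"]], p[["lnf_b"]])
  # global average pooling over tokens within each sample block
  G <- matrix(0, B, D)
  for (b in seq_len(B)) G[b, ] <- colMeans(lnf$y[blk(b), , drop = FALSE])
  H1pre <- sweep(G %*% p[["head_W1"]], 2, p[["head_b1"]], "+")
  H1m <- H1pre > 0
  H1 <- H1pre * H1m
  logits <- sweep(H1 %*% p[["head_W2"]], 2, p[["head_b2"]], "+")
  out <- list(logits = logits, Tn = Tn, B = B)
  if (keep) {
    out$caches <- caches; out$relu_masks <- relu_masks
    out$lnf <- lnf; out$G <- G; out$H1 <- H1; out$H1m <- H1m; out$Xfinal <- X
    out$bm <- bm
  }
  if (keep_attention) out$attention <- attn_store
  out
}

# Backward pass from dlogits (B x 3); returns gradient list parallel to params.
nn_backward <- function(model, fw, dlogits) {
  cfg <- model$cfg; p <- model$params
  Tn <- fw$Tn; B <- fw$B; D <- cfg$embed_dim
  dh <- D %/% cfg$n_heads
  g <- list()
  blk <- function(b) ((b - 1) * Tn + 1):(b * Tn)

  g[["head_W2"]] <- crossprod(fw$H1, dlogits)
  g[["head_b2"]] <- colSums(dlogits)
  dH1 <- tcrossprod(dlogits, p[["head_W2"]]) * fw$H1m
  g[["head_W1"]] <- crossprod(fw$G, dH1)
  g[["head_b1"]] <- colSums(dH1)
  dG <- tcrossprod(dH1, p[["head_W1"]])
  dlnf <- matrix(0, Tn * B, D)
  for (b in seq_len(B))
    dlnf[blk(b), ] <- matrix(dG[b, ] / Tn, Tn, D, byrow = TRUE)
  lb <- layer_norm_backward(dlnf, p[["lnf_g"]], fw$lnf)
  g[["lnf_g"]] <- lb$dg; g[["lnf_b"]] <- lb$db
  dX <- lb$dx

  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- paste0("t", l, "_")
    cc <- fw$caches[[pre]]
    # MLP branch
    dM <- dX
    g[[paste0(pre, "W2")]] <- crossprod(cc$Hh, dM)
    g[[paste0(pre, "b2")]] <- colSums(dM)
    dHh <- tcrossprod(dM, p[[paste0(pre, "W2")]])
    if (!is.null(cc$dm2)) dHh <- dHh * cc$dm2
    dHpre <- dHh * cc$Hm
    g[[paste0(pre, "W1")]] <- crossprod(cc$ln2$y, dHpre)
    g[[paste0(pre, "b1")]] <- colSums(dHpre)
    dln2y <- tcrossprod(dHpre, p[[paste0(pre, "W1")]])
    lb2 <- layer_norm_backward(dln2y, p[[paste0(pre, "ln2_g")]], cc$ln2)
    g[[paste0(pre, "ln2_g")]] <- lb2$dg; g[[paste0(pre, "ln2_b")]] <- lb2$db
    dX1 <- dX + lb2$dx
    # attention branch
    dAO <- dX1
    if (!is.null(cc$dm1)) dAO <- dAO * cc$dm1
    g[[paste0(pre, "Wo")]] <- crossprod(cc$O, dAO)
    g[[paste0(pre, "bo")]] <- colSums(dAO)
    dO <- tcrossprod(dAO, p[[paste0(pre, "Wo")]])
    dQ <- matrix(0, Tn * B, D); dK <- matrix(0, Tn * B, D)
    dV <- matrix(0, Tn * B, D)
    drelb <- matrix(0, nrow(p[[paste0(pre, "relb")]]), cfg$n_heads)
    for (b in seq_len(B)) {
      rb <- blk(b)
      for (hh in seq_len(cfg$n_heads)) {
        cs <- ((hh - 1) * dh + 1):(hh * dh)
        A <- cc$A_list[[(b - 1) * cfg$n_heads + hh]]
        dOb <- dO[rb, cs, drop = FALSE]
        dA <- tcrossprod(dOb, cc$V[rb, cs, drop = FALSE])
        dV[rb, cs] <- dV[rb, cs] + crossprod(A, dOb)
        dS <- A * (dA - rowSums(dA * A))
        acc <- rowsum(as.vector(dS), group = as.vector(fw$bm))
        drelb[as.integer(rownames(acc)), hh] <-
          drelb[as.integer(rownames(acc)), hh] + acc[, 1]
        dQ[rb, cs] <- dQ[rb, cs] +
          (dS %*% cc$K[rb, cs, drop = FALSE]) / sqrt(dh)
        dK[rb, cs] <- dK[rb, cs] +
          (crossprod(dS, cc$Q[rb, cs, drop = FALSE])) / sqrt(dh)
      }
    }
    g[[paste0(pre, "relb")]] <- drelb
    g[[paste0(pre, "Wq")]] <- crossprod(cc$ln1$y, dQ)
    g[[paste0(pre, "Wk")]] <- crossprod(cc$ln1$y, dK)
    g[[paste0(pre, "Wv")]] <- crossprod(cc$ln1$y, dV)
    dln1y <- tcrossprod(dQ, p[[paste0(pre, "Wq")]]) +
      tcrossprod(dK, p[[paste0(pre, "Wk")]]) +
      tcrossprod(dV, p[[paste0(pre, "Wv")]])
    lb1 <- layer_norm_backward(dln1y, p[[paste0(pre, "ln1_g")]], cc$ln1)
    g[[paste0(pre, "ln1_g")]] <- lb1$dg; g[[paste0(pre, "ln1_b")]] <- lb1$db
    dX <- dX1 + lb1$dx
  }

  dH3 <- dX; dim(dH3) <- c(Tn, B, D)
  dh3 <- aperm(dH3, c(1, 3, 2))                  # (T, D, B)
  for (l in rev(seq_along(cfg$conv_strides))) {
    dh3 <- dh3 * fw$relu_masks[[l]]
    cb <- conv_backward(dh3, model$params[[paste0("conv", l, "_W")]],
                        fw$caches[[paste0("conv", l)]])
    g[[paste0("conv", l, "_W")]] <- cb$dW
    g[[paste0("conv", l, "_b")]] <- cb$db
    dh3 <- cb$dx
  }
  g
}
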
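# SAC network: parameter containers, initialization, forward pass (with
# caches for training), backward pass, and introspection.

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

#' Build a Spatial-Attention ConvMixer model
#'
#' Allocates and initializes all trainable parameters of the network
#' described by `config`: a patch-embedding stem (strided convolution +
#' GELU + BatchNorm), an optional single-channel sigmoid spatial-attention
#' gate, `depth` ConvMixer blocks (depthwise spatial mixing with a residual
#' connection, pointwise channel mixing, GELU + BatchNorm), global average
#' pooling and a dense softmax head. Weights use scaled-uniform (Glorot)
#' initialization; biases start at zero, BatchNorm at scale 1 / shift 0.
#'
#' @param config A [model_config()].
#' @param seed Optional integer; when given, initialization is drawn from a
#'   private RNG stream so the surrounding RNG state is untouched.
#' @return An object of class `sac_model`.
#' @seealso [count_trainable_params()], [n_trainable_params()], [train_sac()]
#' @export
build_sac <- function(config, seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(seed)
  }
  p <- config$patch_size
  h <- config$hidden_dim
  k <- config$kernel_size
  C <- config$num_classes

  params <- list(
    stem_W = glorot_uniform(p * p * 3, h, c(p * p * 3, h)),
    stem_b = numeric(h),
    stem_gamma = rep(1, h),
    stem_beta = numeric(h)
  )
  if (config$use_spatial_attention) {
    params$attn_w <- drop(glorot_uniform(h, 1, c(h, 1)))
    params$attn_b <- 0
  }
  for (i in seq_len(config$depth)) {
    params[[sprintf("blk%d_dwK", i)]] <- glorot_uniform(k * k, k * k, c(k, k, h))
    params[[sprintf("blk%d_dwb", i)]] <- numeric(h)
    params[[sprintf("blk%d_bn1_gamma", i)]] <- rep(1, h)
    params[[sprintf("blk%d_bn1_beta", i)]] <- numeric(h)
    params[[sprintf("blk%d_pwW", i)]] <- glorot_uniform(h, h, c(h, h))
    params[[sprintf("blk%d_pwb", i)]] <- numeric(h)
    params[[sprintf("blk%d_bn2_gamma", i)]] <- rep(1, h)
    params[[sprintf("blk%d_bn2_beta", i)]] <- numeric(h)
  }
  params$head_W <- glorot_uniform(h, C, c(h, C))
  params$head_b <- numeric(C)

  bn_states <- list(stem = bn_state_init(h))
  for (i in seq_len(config$depth)) {
    bn_states[[sprintf("blk%d_bn1", i)]] <- bn_state_init(h)
    bn_states[[sprintf("blk%d_bn2", i)]] <- bn_state_init(h)
  }

  structure(list(config = config, params = params, bn_states = bn_states),
            class = "sac_model")
}

#' Framework-reported trainable parameter count
#'
#' Counts trainable parameters by summing the lengths of the model's
#' allocated parameter arrays — the introspective counterpart of the
#' analytic [count_trainable_params()]. BatchNorm running statistics are
#' stored separately and never enter this count.
#'
#' @param model A [build_sac()] model.
#' @return Integer parameter count.
#' @export
n_trainable_params <- function(model) {
  stopifnot(inherits(model, "sac_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.sac_model <- function(x, ...) {
  bd <- count_trainable_params(x$config)
  cat(sprintf("<sac_model> %s, %d trainable parameters\n",
              if (x$config$use_spatial_attention) "SAC" else "ConvMixer",
              n_trainable_params(x)))
  print(x$config)
  print(bd)
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

# x: array (n, n, B, 3) in [0,1]. Returns probs plus (optionally) every
# intermediate needed for the backward pass. In inference mode BatchNorm
# uses running statistics and no caches are kept.
sac_forward <- function(model, x, training = FALSE, keep_cache = training) {
  cfg <- model$config
  P <- model$params
  n <- dim(x)[1]
  B <- dim(x)[3]
  if (n != cfg$image_size || dim(x)[2] != cfg$image_size || dim(x)[4] != 3L) {
    stop(sprintf("expected input of shape (%d, %d, B, 3), got (%s)",
                 cfg$image_size, cfg$image_size,
                 paste(dim(x), collapse = ", ")))
  }
  H <- n %/% cfg$patch_size
  W <- H
  cache <- list(H = H, W = W, B = B)

  st <- stem_forward(x, P$stem_W, P$stem_b, cfg$patch_size)
  cache$stem <- st$cache
  z <- st$out
  cache$stem_pre <- z
  a <- gelu(z)
  bn <- bn_forward(a, P$stem_gamma, P$stem_beta, model$bn_states$stem, training)
  model$bn_states$stem <- bn$state
  cache$stem_bn <- bn$cache
  f <- bn$out

  if (cfg$use_spatial_attention) {
    at <- attn_forward(f, P$attn_w, P$attn_b)
    cache$attn <- at$cache
    f <- at$out
  }

  cache$blocks <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    bc <- list(input = f)
    dw <- dw_forward(f, P[[sprintf("blk%d_dwK", i)]],
                     P[[sprintf("blk%d_dwb", i)]], H, W, B)
    bc$dw <- dw$cache
    bc$dw_pre <- dw$out
    u <- gelu(dw$out)
    b1 <- bn_forward(u, P[[sprintf("blk%d_bn1_gamma", i)]],
                     P[[sprintf("blk%d_bn1_beta", i)]],
                     model$bn_states[[sprintf("blk%d_bn1", i)]], training)
    model$bn_states[[sprintf("blk%d_bn1", i)]] <- b1$state
    bc$bn1 <- b1$cache
    r <- f + b1$out                                    # residual add
    if (cfg$block_order == "table1") {
      bc$add_out <- r
      g2 <- gelu(r)
      b2 <- bn_forward(g2, P[[sprintf("blk%d_bn2_gamma", i)]],
                       P[[sprintf("blk%d_bn2_beta", i)]],
                       model$bn_states[[sprintf("blk%d_bn2", i)]], training)
      model$bn_states[[sprintf("blk%d_bn2", i)]] <- b2$state
      bc$bn2 <- b2$cache
      bc$pw_in <- b2$out
      f <- pw_forward(b2$out, P[[sprintf("blk%d_pwW", i)]],
                      P[[sprintf("blk%d_pwb", i)]])
    } else {                                           # original_convmixer
      bc$pw_in <- r
      pw <- pw_forward(r, P[[sprintf("blk%d_pwW", i)]],
                       P[[sprintf("blk%d_pwb", i)]])
      bc$pw_pre <- pw
      g2 <- gelu(pw)
      b2 <- bn_forward(g2, P[[sprintf("blk%d_bn2_gamma", i)]],
                       P[[sprintf("blk%d_bn2_beta", i)]],
                       model$bn_states[[sprintf("blk%d_bn2", i)]], training)
      model$bn_states[[sprintf("blk%d_bn2", i)]] <- b2$state
      bc$bn2 <- b2$cache
      f <- b2$out
    }
    cache$blocks[[i]] <- bc
  }

  cache$final_fm <- f                                  # (H*W*B, h), feeds GAP
  gap <- gap_forward(f, H, W, B)
  cache$gap <- gap
  logits <- sweep(gap %*% P$head_W, 2, P$head_b, `+`)
  probs <- softmax_rows(logits)

  list(probs = probs, logits = logits,
       cache = if (keep_cache) cache else NULL,
       bn_states = model$bn_states)
}

# dlogits: gradient of the loss w.r.t. logits, shape (B, C).
# Returns a named list of gradients matching model$params.
sac_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  P <- model$params
  H <- cache$H; W <- cache$W; B <- cache$B
  g <- list()

  g$head_W <- crossprod(cache$gap, dlogits)
  g$head_b <- colSums(dlogits)
  dgap <- dlogits %*% t(P$head_W)
  df <- gap_backward(dgap, H, W, B)

  for (i in rev(seq_len(cfg$depth))) {
    bc <- cache$blocks[[i]]
    if (cfg$block_order == "table1") {
      pb <- pw_backward(df, bc$pw_in, P[[sprintf("blk%d_pwW", i)]])
      g[[sprintf("blk%d_pwW", i)]] <- pb$dW
      g[[sprintf("blk%d_pwb", i)]] <- pb$dbias
      b2 <- bn_backward(pb$dx, bc$bn2)
      g[[sprintf("blk%d_bn2_gamma", i)]] <- b2$dgamma
      g[[sprintf("blk%d_bn2_beta", i)]] <- b2$dbeta
      dr <- b2$dx * gelu_grad(bc$add_out)
    } else {
      b2 <- bn_backward(df, bc$bn2)
      g[[sprintf("blk%d_bn2_gamma", i)]] <- b2$dgamma
      g[[sprintf("blk%d_bn2_beta", i)]] <- b2$dbeta
      dpw <- b2$dx * gelu_grad(bc$pw_pre)
      pb <- pw_backward(dpw, bc$pw_in, P[[sprintf("blk%d_pwW", i)]])
      g[[sprintf("blk%d_pwW", i)]] <- pb$dW
      g[[sprintf("blk%d_pwb", i)]] <- pb$dbias
      dr <- pb$dx
    }
    # residual: r = input + bn1(gelu(dw(input)))
    b1 <- bn_backward(dr, bc$bn1)
    g[[sprintf("blk%d_bn1_gamma", i)]] <- b1$dgamma
    g[[sprintf("blk%d_bn1_beta", i)]] <- b1$dbeta
    ddw <- b1$dx * gelu_grad(bc$dw_pre)
    db <- dw_backward(ddw, bc$dw)
    g[[sprintf("blk%d_dwK", i)]] <- db$dK
    g[[sprintf("blk%d_dwb", i)]] <- db$dbias
    df <- dr + db$dx
  }

  if (cfg$use_spatial_attention) {
    ab <- attn_backward(df, cache$attn)
    g$attn_w <- ab$dw
    g$attn_b <- ab$db
    df <- ab$dx
  }

  sb <- bn_backward(df, cache$stem_bn)
  g$stem_gamma <- sb$dgamma
  g$stem_beta <- sb$dbeta
  dz <- sb$dx * gelu_grad(cache$stem_pre)
  st <- stem_backward(dz, cache$stem)
  g$stem_W <- st$dW
  g$stem_b <- st$dbias
  g
}

#' Class probabilities for a batch of images
#'
#' Runs the network in inference mode (BatchNorm running statistics) over
#' the input in mini-batches.
#'
#' @param object A `sac_model`.
#' @param x Array `(image_size, image_size, N, 3)` with values in `[0, 1]`.
#' @param batch_size Mini-batch size used internally.
#' @param ... Unused.
#' @return Matrix `(N, num_classes)` of softmax probabilities; rows sum to 1.
#' @export
predict.sac_model <- function(object, x, batch_size = 32L, ...) {
  N <- dim(x)[3]
  C <- object$config$num_classes
  out <- matrix(NA_real_, N, C)
  i <- 1L
  while (i <= N) {
    j <- min(i + batch_size - 1L, N)
    out[i:j, ] <- sac_forward(object, x[, , i:j, , drop = FALSE],
                              training = FALSE)$probs
    i <- j + 1L
  }
  out
}

# ---- public single-stage operations ---------------------------------------

#' Apply the spatial-attention gate to a feature map
#'
#' Computes the single-channel gate `sigmoid(<features, w> + b)` at every
#' spatial location and multiplies every channel by it. With `w = 0, b = 0`
#' the gate is exactly 1/2 everywhere, halving the feature map.
#'
#' @param features Array `(H, W, C)` or `(H, W, B, C)`.
#' @param w Numeric vector of length `C` (the 1x1 projection).
#' @param b Scalar bias.
#' @return List with `output` (same shape as `features`) and `attention`
#'   (array with the channel axis reduced to the gate value, entries
#'   strictly in (0, 1)).
#' @export
apply_spatial_attention <- function(features, w, b = 0) {
  d <- dim(features)
  squeeze <- length(d) == 3L
  if (squeeze) features <- array(features, c(d[1], d[2], 1L, d[3]))
  d4 <- dim(features)
  if (length(w) != d4[4]) {
    stop(sprintf("gate weight length %d does not match feature depth %d",
                 length(w), d4[4]))
  }
  mat <- fm_as_matrix(features)
  at <- attn_forward(mat, as.numeric(w), as.numeric(b))
  out <- array(at$out, dim = d4)
  attn <- array(at$cache$a, dim = d4[1:3])
  if (squeeze) {
    out <- array(out, c(d4[1], d4[2], d4[4]))
    attn <- matrix(attn, d4[1], d4[2])
  }
  list(output = out, attention = attn)
}

#' Apply one ConvMixer block to a feature map
#'
#' Runs a single mixer block (depthwise spatial mixing with residual add,
#' pointwise channel mixing, GELU + BatchNorm in the order set by
#' `config$block_order`) with the given parameter set, in training mode
#' (batch statistics). Spatial extent is preserved.
#'
#' @param features Array `(H, W, C)` or `(H, W, B, C)` with `C` equal to
#'   `config$hidden_dim`.
#' @param params Named list: `dwK (k,k,h)`, `dwb`, `bn1_gamma`, `bn1_beta`,
#'   `pwW (h,h)`, `pwb`, `bn2_gamma`, `bn2_beta`.
#' @param config A [model_config()].
#' @return Array of the same shape as `features`.
#' @export
apply_convmixer_block <- function(features, params, config) {
  d <- dim(features)
  squeeze <- length(d) == 3L
  if (squeeze) features <- array(features, c(d[1], d[2], 1L, d[3]))
  d4 <- dim(features)
  if (d4[4] != config$hidden_dim) {
    stop(sprintf("feature depth %d does not match hidden_dim %d",
                 d4[4], config$hidden_dim))
  }
  mat <- fm_as_matrix(features)
  H <- d4[1]; W <- d4[2]; B <- d4[3]
  dw <- dw_forward(mat, params$dwK, params$dwb, H, W, B)
  b1 <- bn_forward(gelu(dw$out), params$bn1_gamma, params$bn1_beta,
                   bn_state_init(ncol(mat)), training = TRUE)
  r <- mat + b1$out
  if (config$block_order == "table1") {
    b2 <- bn_forward(gelu(r), params$bn2_gamma, params$bn2_beta,
                     bn_state_init(ncol(mat)), training = TRUE)
    out <- pw_forward(b2$out, params$pwW, params$pwb)
  } else {
    pw <- pw_forward(r, params$pwW, params$pwb)
    b2 <- bn_forward(gelu(pw), params$bn2_gamma, params$bn2_beta,
                     bn_state_init(ncol(mat)), training = TRUE)
    out <- b2$out
  }
  out <- array(out, dim = d4)
  if (squeeze) out <- array(out, c(d4[1], d4[2], d4[4]))
  out
}

# parameters of block i as the flat list apply_convmixer_block() expects
block_params <- function(model, i) {
  P <- model$params
  list(dwK = P[[sprintf("blk%d_dwK", i)]],
       dwb = P[[sprintf("blk%d_dwb", i)]],
       bn1_gamma = P[[sprintf("blk%d_bn1_gamma", i)]],
       bn1_beta = P[[sprintf("blk%d_bn1_beta", i)]],
       pwW = P[[sprintf("blk%d_pwW", i)]],
       pwb = P[[sprintf("blk%d_pwb", i)]],
       bn2_gamma = P[[sprintf("blk%d_bn2_gamma", i)]],
       bn2_beta = P[[sprintf("blk%d_bn2_beta", i)]])
}

#' Save / load model weights
#'
#' Serializes the model (configuration, parameters and BatchNorm running
#' statistics) with R's native serialization.
#'
#' @param model A `sac_model`.
#' @param path File path.
#' @return `save_sac` returns `path` invisibly; `load_sac` returns the model.
#' @export
save_sac <- function(model, path) {
  stopifnot(inherits(model, "sac_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_sac
#' @export
load_sac <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "sac_model")) stop("not a serialized sac_model: ", path)
  m
}

# ---- RNG bookkeeping -------------------------------------------------------

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  expr
}
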
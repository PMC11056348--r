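# Layer primitives with hand-written forward/backward passes.
#
# Feature maps are stored as a matrix of H*W*B rows by C columns, rows
# ordered height-fastest, then width, then batch -- i.e. the flattening of
# an array with dim c(H, W, B, C). That layout makes the pointwise
# convolution a single matrix multiply, BatchNorm a column operation, the
# spatial gate a row operation, and keeps each image's rows contiguous for
# global average pooling.

fm_as_array <- function(mat, H, W, B) {
  array(mat, dim = c(H, W, B, ncol(mat)))
}

fm_as_matrix <- function(arr) {
  d <- dim(arr)
  matrix(arr, nrow = d[1] * d[2] * d[3], ncol = d[4])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Exact (erf-based) GELU: x * Phi(x).
gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- batch normalization (per channel over all rows) -----------------------

bn_forward <- function(mat, gamma, beta, state, training, eps = 1e-5,
                       momentum = 0.9) {
  if (training) {
    mu <- colMeans(mat)
    xc <- sweep(mat, 2, mu)
    va <- colMeans(xc * xc)           # population variance, as batch stats
    inv <- 1 / sqrt(va + eps)
    xhat <- sweep(xc, 2, inv, `*`)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * va
    cache <- list(xhat = xhat, inv = inv, gamma = gamma)
  } else {
    inv <- 1 / sqrt(state$var + eps)
    xhat <- sweep(sweep(mat, 2, state$mean), 2, inv, `*`)
    cache <- NULL
  }
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = out, state = state, cache = cache)
}

bn_backward <- function(dout, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  m <- nrow(dout)
  t1 <- sweep(dout, 2, colSums(dout) / m)
  t2 <- sweep(xhat, 2, dgamma / m, `*`)
  dx <- sweep(t1 - t2, 2, cache$gamma * cache$inv, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

bn_state_init <- function(h) list(mean = numeric(h), var = rep(1, h))

# ---- depthwise convolution (same padding, stride 1) ------------------------

dw_pad <- function(k) {
  # asymmetric "same" padding for even kernels, symmetric for odd
  k <- as.integer(unname(k))
  c(lo = (k - 1L) %/% 2L, hi = k %/% 2L)
}

dw_forward <- function(mat, K, bias, H, W, B) {
  k <- dim(K)[1]
  h <- ncol(mat)
  p <- dw_pad(k)
  X <- fm_as_array(mat, H, W, B)
  Xpad <- array(0, dim = c(H + p["lo"] + p["hi"], W + p["lo"] + p["hi"], B, h))
  Xpad[p["lo"] + seq_len(H), p["lo"] + seq_len(W), , ] <- X
  nr <- H * W * B
  out <- matrix(rep(bias, each = nr), nrow = nr, ncol = h)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      slab <- Xpad[i:(i + H - 1L), j:(j + W - 1L), , , drop = FALSE]
      out <- out + matrix(slab, nr, h) * rep(K[i, j, ], each = nr)
    }
  }
  list(out = out, cache = list(Xpad = Xpad, K = K, H = H, W = W, B = B))
}

dw_backward <- function(dout, cache) {
  K <- cache$K
  H <- cache$H; W <- cache$W; B <- cache$B
  k <- dim(K)[1]
  h <- ncol(dout)
  p <- dw_pad(k)
  nr <- H * W * B
  dY <- fm_as_array(dout, H, W, B)
  dXpad <- array(0, dim = dim(cache$Xpad))
  dK <- array(0, dim = dim(K))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      slab <- cache$Xpad[i:(i + H - 1L), j:(j + W - 1L), , , drop = FALSE]
      dK[i, j, ] <- colSums(matrix(slab, nr, h) * dout)
      dXpad[i:(i + H - 1L), j:(j + W - 1L), , ] <-
        dXpad[i:(i + H - 1L), j:(j + W - 1L), , , drop = FALSE] +
        dY * rep(K[i, j, ], each = nr)
    }
  }
  dX <- dXpad[p["lo"] + seq_len(H), p["lo"] + seq_len(W), , , drop = FALSE]
  list(dx = fm_as_matrix(dX), dK = dK, dbias = colSums(dout))
}

# ---- pointwise (1x1) convolution = matrix multiply -------------------------

pw_forward <- function(mat, Wt, bias) {
  sweep(mat %*% Wt, 2, bias, `+`)
}

pw_backward <- function(dout, mat, Wt) {
  list(dx = dout %*% t(Wt),
       dW = crossprod(mat, dout),
       dbias = colSums(dout))
}

# ---- spatial attention gate ------------------------------------------------

attn_forward <- function(mat, w, b) {
  w <- as.numeric(w)
  s <- drop(mat %*% w) + as.numeric(b)
  a <- sigmoid(s)
  list(out = mat * a, cache = list(a = a, mat = mat, w = w))
}

attn_backward <- function(dout, cache) {
  a <- cache$a
  mat <- cache$mat
  dda <- rowSums(dout * mat)            # dL/da per location
  dds <- dda * a * (1 - a)              # dL/ds
  list(dx = dout * a + outer(dds, cache$w),
       dw = drop(crossprod(mat, dds)),
       db = sum(dds))
}

# ---- patch-embedding stem (non-overlapping strided conv via im2col) --------

stem_im2col <- function(X, p) {
  # X: array (n, n, B, 3) -> matrix (H*W*B, 3*p^2), rows ordered (H, W, B);
  # column q indexes (i, j, c) as i + (j-1)*p + (c-1)*p^2.
  n <- dim(X)[1]
  B <- dim(X)[3]
  H <- n %/% p
  cols <- vector("list", 3L * p * p)
  q <- 0L
  for (cc in 1:3) {
    for (j in seq_len(p)) {
      for (i in seq_len(p)) {
        q <- q + 1L
        cols[[q]] <- as.vector(X[seq(i, n, by = p), seq(j, n, by = p), , cc])
      }
    }
  }
  # note column order within the list is i-fastest; reorder to the (i, j, c)
  # indexing documented above (identical because we filled i innermost)
  do.call(cbind, cols)
}

stem_forward <- function(X, Wt, bias, p) {
  P <- stem_im2col(X, p)
  list(out = sweep(P %*% Wt, 2, bias, `+`), cache = list(P = P))
}

stem_backward <- function(dout, cache) {
  list(dW = crossprod(cache$P, dout), dbias = colSums(dout))
}

# ---- global average pooling ------------------------------------------------

gap_forward <- function(mat, H, W, B) {
  grp <- rep(seq_len(B), each = H * W)
  out <- rowsum(mat, grp) / (H * W)
  dimnames(out) <- NULL
  out
}

gap_backward <- function(dgap, H, W, B) {
  dgap[rep(seq_len(B), each = H * W), , drop = FALSE] / (H * W)
}

# ---- brute-force oracles ---------------------------------------------------

#' Brute-force depthwise convolution (reference oracle)
#'
#' A deliberately naive nested-loop per-channel convolution with
#' zero "same" padding and stride 1, used as an independent reference for
#' the vectorized depthwise layer inside the network. Intended for small
#' inputs only.
#'
#' @param features Array `(H, W, C)` or `(H, W, B, C)`.
#' @param kernel Array `(k, k, C)` of per-channel kernels.
#' @param bias Numeric vector of length `C` (default zeros).
#' @return Array of the same shape as `features`.
#' @export
depthwise_conv_oracle <- function(features, kernel, bias = NULL) {
  d <- dim(features)
  squeeze <- length(d) == 3L
  if (squeeze) {
    features <- array(features, c(d[1], d[2], 1L, d[3]))
    d <- dim(features)
  }
  H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  k <- dim(kernel)[1]
  if (dim(kernel)[3] != C) stop("kernel channel count does not match features")
  if (k > H || k > W) {
    stop("kernel size exceeds the feature-map extent")
  }
  p <- dw_pad(k)
  if (is.null(bias)) bias <- numeric(C)
  out <- array(0, d)
  for (b in seq_len(B)) {
    for (cc in seq_len(C)) {
      for (y in seq_len(H)) {
        for (x in seq_len(W)) {
          acc <- bias[cc]
          for (i in seq_len(k)) {
            for (j in seq_len(k)) {
              yy <- y + i - 1L - p["lo"]
              xx <- x + j - 1L - p["lo"]
              if (yy >= 1L && yy <= H && xx >= 1L && xx <= W) {
                acc <- acc + features[yy, xx, b, cc] * kernel[i, j, cc]
              }
            }
          }
          out[y, x, b, cc] <- acc
        }
      }
    }
  }
  if (squeeze) out <- array(out, c(H, W, C))
  out
}

#' Brute-force pointwise (1x1) convolution (reference oracle)
#'
#' Per-location loop over the channel mixing `out[x,y,] = t(W) %*% in[x,y,] + b`,
#' used as an independent reference for the matrix-multiply pointwise layer.
#'
#' @param features Array `(H, W, C_in)`.
#' @param weights Matrix `(C_in, C_out)`.
#' @param bias Numeric vector of length `C_out` (default zeros).
#' @return Array `(H, W, C_out)`.
#' @export
pointwise_conv_oracle <- function(features, weights, bias = NULL) {
  d <- dim(features)
  if (is.null(bias)) bias <- numeric(ncol(weights))
  out <- array(0, c(d[1], d[2], ncol(weights)))
  for (y in seq_len(d[1])) {
    for (x in seq_len(d[2])) {
      out[y, x, ] <- drop(features[y, x, ] %*% weights) + bias
    }
  }
  out
}
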
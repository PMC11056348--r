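#' Model architecture configuration
#'
#' Collects every architectural hyperparameter of the Spatial-Attention
#' ConvMixer (SAC). The defaults reproduce the published configuration:
#' 128 px inputs cut into 2 px patches, 256 channels, 8 mixer blocks with a
#' 5x5 depthwise kernel, a 6-class softmax head, and the spatial-attention
#' gate enabled.
#'
#' @param image_size Input edge length in pixels (square images).
#' @param patch_size Patch edge length in pixels; must divide `image_size`.
#' @param hidden_dim Channel width of every feature map after the stem.
#' @param depth Number of ConvMixer blocks.
#' @param kernel_size Depthwise convolution kernel edge length.
#' @param num_classes Number of output classes.
#' @param use_spatial_attention Gate the stem output with the sigmoid
#'   spatial-attention map?
#' @param block_order `"table1"` (depthwise -> GELU -> BN -> residual add ->
#'   GELU -> BN -> pointwise, the published layer summary) or
#'   `"original_convmixer"` (residual depthwise sub-block then pointwise,
#'   each followed by GELU + BN). Both orderings have identical trainable
#'   parameter counts.
#'
#' @return An object of class `sac_config`.
#' @examples
#' cfg <- model_config()
#' cfg$hidden_dim
#' small <- model_config(image_size = 32, patch_size = 4, hidden_dim = 16,
#'                       depth = 2, kernel_size = 3, num_classes = 3)
#' @export
model_config <- function(image_size = 128L,
                         patch_size = 2L,
                         hidden_dim = 256L,
                         depth = 8L,
                         kernel_size = 5L,
                         num_classes = 6L,
                         use_spatial_attention = TRUE,
                         block_order = c("table1", "original_convmixer")) {
  block_order <- match.arg(block_order)
  cfg <- list(
    image_size = as.integer(image_size),
    patch_size = as.integer(patch_size),
    hidden_dim = as.integer(hidden_dim),
    depth = as.integer(depth),
    kernel_size = as.integer(kernel_size),
    num_classes = as.integer(num_classes),
    use_spatial_attention = isTRUE(use_spatial_attention),
    block_order = block_order
  )
  class(cfg) <- "sac_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  counts <- c("image_size", "patch_size", "hidden_dim", "depth",
              "kernel_size", "num_classes")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 1L) {
      stop(sprintf("invalid model configuration: '%s' must be a single positive integer", f),
           call. = FALSE)
    }
  }
  if (cfg$image_size %% cfg$patch_size != 0L) {
    stop("invalid model configuration: 'image_size' must be divisible by 'patch_size'",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sac_config <- function(x, ...) {
  cat("SAC model configuration\n")
  cat(sprintf("  input          : %d x %d x 3\n", x$image_size, x$image_size))
  cat(sprintf("  patch size     : %d  (grid %d x %d)\n",
              x$patch_size, x$image_size %/% x$patch_size,
              x$image_size %/% x$patch_size))
  cat(sprintf("  hidden width   : %d\n", x$hidden_dim))
  cat(sprintf("  depth          : %d blocks (kernel %d x %d, order %s)\n",
              x$depth, x$kernel_size, x$kernel_size, x$block_order))
  cat(sprintf("  classes        : %d\n", x$num_classes))
  cat(sprintf("  spatial gate   : %s\n",
              if (x$use_spatial_attention) "enabled" else "disabled"))
  invisible(x)
}

#' Closed-form trainable-parameter accounting
#'
#' Computes the number of trainable parameters of a SAC (or plain
#' ConvMixer) configuration analytically, stage by stage. Convolution and
#' dense biases and BatchNorm scale/shift pairs are counted; BatchNorm
#' running statistics are not trainable and are excluded. With the default
#' configuration the total is 593,415 with the attention gate and 593,158
#' without it; the gate itself always contributes `hidden_dim + 1`
#' parameters (a 1x1 projection to one channel plus its bias).
#'
#' @param config A [model_config()].
#' @return An object of class `sac_param_breakdown` with fields `stem`,
#'   `spatial_attention`, `per_block`, `blocks_total`, `head`,
#'   `total_trainable`.
#' @examples
#' count_trainable_params(model_config())$total_trainable            # 593415
#' count_trainable_params(model_config(use_spatial_attention = FALSE))$total_trainable
#' @export
count_trainable_params <- function(config) {
  validate_config(config)
  p <- config$patch_size
  h <- config$hidden_dim
  k <- config$kernel_size
  C <- config$num_classes
  d <- config$depth
  stem <- p * p * 3L * h + h + 2L * h          # conv w + b, BN gamma + beta
  attn <- if (config$use_spatial_attention) h + 1L else 0L
  per_block <- (k * k * h + h) +               # depthwise w + b
    2L * h +                                   # BN after depthwise
    (h * h + h) +                              # pointwise w + b
    2L * h                                     # second BN
  out <- list(
    stem = stem,
    spatial_attention = attn,
    per_block = per_block,
    blocks_total = d * per_block,
    head = h * C + C,
    total_trainable = stem + attn + d * per_block + h * C + C
  )
  class(out) <- "sac_param_breakdown"
  out
}

#' @export
print.sac_param_breakdown <- function(x, ...) {
  cat("Trainable parameters\n")
  cat(sprintf("  stem (patch embedding + BN) : %10d\n", x$stem))
  cat(sprintf("  spatial attention gate      : %10d\n", x$spatial_attention))
  cat(sprintf("  per ConvMixer block         : %10d\n", x$per_block))
  cat(sprintf("  all blocks                  : %10d\n", x$blocks_total))
  cat(sprintf("  classification head         : %10d\n", x$head))
  cat(sprintf("  total                       : %10d\n", x$total_trainable))
  invisible(x)
}

#' Per-stage output shapes
#'
#' Tabulates the output shape of every stage of the network, mirroring the
#' published layer summary: with defaults the stem and every mixer block
#' emit a 64 x 64 x 256 feature map, global average pooling collapses it to
#' 256, and the dense head emits 6 logits.
#'
#' @param config A [model_config()].
#' @return A data.frame with columns `stage`, `layer`, `output`.
#' @export
sac_shapes <- function(config) {
  validate_config(config)
  g <- config$image_size %/% config$patch_size
  h <- config$hidden_dim
  fm <- sprintf("%d, %d, %d", g, g, h)
  rows <- list(
    c("input", "Input", sprintf("%d, %d, 3", config$image_size, config$image_size)),
    c("patch embedding", sprintf("Conv2D (stride %d, kernel %d)",
                                 config$patch_size, config$patch_size), fm)
  )
  if (config$use_spatial_attention) {
    rows <- c(rows, list(
      c("spatial attention", "PointwiseConv2D + sigmoid", sprintf("%d, %d, 1", g, g)),
      c("spatial attention", "Multiply", fm)
    ))
  }
  block_layers <- if (config$block_order == "table1") {
    c("DepthwiseConv2D", "GELU", "BatchNorm", "Add", "GELU", "BatchNorm",
      "PointwiseConv2D")
  } else {
    c("DepthwiseConv2D", "GELU", "BatchNorm", "Add", "PointwiseConv2D",
      "GELU", "BatchNorm")
  }
  for (b in seq_len(config$depth)) {
    for (l in block_layers) {
      rows <- c(rows, list(c(sprintf("block %d", b), l, fm)))
    }
  }
  rows <- c(rows, list(
    c("classification", "GlobalAvgPool2D", sprintf("%d", h)),
    c("classification", "Dense + softmax", sprintf("%d", config$num_classes))
  ))
  out <- do.call(rbind, rows)
  data.frame(stage = out[, 1], layer = out[, 2], output = out[, 3])
}
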
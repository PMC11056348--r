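# Grad-CAM: gradient-weighted class activation maps from the final
# convolutional feature map (the map feeding global average pooling).

#' Core Grad-CAM combination
#'
#' Given a feature map and the gradient of a class score with respect to
#' it, computes the channel-importance weights as the spatial mean of the
#' gradient, the ReLU-rectified weighted channel sum, and the max-normalized
#' heatmap (an identically zero raw map stays zero).
#'
#' @param features Array `(H, W, C)`.
#' @param gradients Array `(H, W, C)`, `d score / d features`.
#' @return List with `map` (`(H, W)` in `[0, 1]`) and `raw` (pre-normalization).
#' @export
grad_cam_map <- function(features, gradients) {
  stopifnot(identical(dim(features), dim(gradients)))
  d <- dim(features)
  weights <- apply(gradients, 3, mean)
  raw <- matrix(0, d[1], d[2])
  for (cc in seq_len(d[3])) {
    raw <- raw + weights[cc] * features[, , cc]
  }
  raw <- pmax(raw, 0)
  mx <- max(raw)
  map <- if (mx > 0) raw / mx else raw
  list(map = map, raw = raw)
}

bilinear_upsample <- function(m, size) {
  EBImage::imageData(EBImage::resize(EBImage::Image(m), w = size, h = size))
}

#' Grad-CAM heatmap for one image
#'
#' Runs the model in inference mode, takes the gradient of the pre-softmax
#' score of `class_index` with respect to the final convolutional feature
#' map (the pointwise-convolution output feeding global average pooling),
#' and combines it with [grad_cam_map()]. For this head the gradient is
#' `head_W[, class] / (H * W)` at every location, so the channel weights
#' are exactly the head weights of the target class scaled by the grid
#' size.
#'
#' @param model A `sac_model`.
#' @param image Array `(n, n, 3)` in `[0, 1]`.
#' @param class_index Target class, 1-based.
#' @return An object of class `sac_cam`: list with `map` (grid-resolution
#'   heatmap in `[0, 1]`), `upsampled` (`n x n`, bilinear), `raw`, and
#'   `class_index`.
#' @export
compute_cam <- function(model, image, class_index) {
  cfg <- model$config
  if (class_index < 1L || class_index > cfg$num_classes) {
    stop(sprintf("class_index must be in 1..%d", cfg$num_classes))
  }
  x <- array(image, c(cfg$image_size, cfg$image_size, 1L, 3L))
  fw <- sac_forward(model, x, training = FALSE, keep_cache = TRUE)
  H <- fw$cache$H; W <- fw$cache$W
  fm <- array(fw$cache$final_fm, c(H, W, cfg$hidden_dim))
  # d score_k / d fm[x, y, c] through GAP: constant head_W[c, k] / (H * W)
  gvec <- model$params$head_W[, class_index] / (H * W)
  grads <- array(rep(gvec, each = H * W), c(H, W, cfg$hidden_dim))
  cam <- grad_cam_map(fm, grads)
  structure(list(map = cam$map,
                 upsampled = bilinear_upsample(cam$map, cfg$image_size),
                 raw = cam$raw,
                 class_index = class_index),
            class = "sac_cam")
}

default_cam_palette <- function(n = 256L) {
  grDevices::colorRamp(c("#000080", "#0000FF", "#00FFFF",
                         "#FFFF00", "#FF0000"))(seq(0, 1, length.out = n)) / 255
}

#' Overlay a Grad-CAM heatmap on its input image
#'
#' Renders the upsampled heatmap through a blue-to-red colormap and
#' alpha-blends it onto the image with per-pixel opacity `alpha * heat`,
#' so regions of zero activation show the unmodified image. Output is
#' 8-bit RGB.
#'
#' @param cam An `sac_cam` (or a bare `n x n` matrix in `[0, 1]`).
#' @param image Array `(n, n, 3)` in `[0, 1]`, same extent as the
#'   upsampled heatmap.
#' @param alpha Maximum blend opacity.
#' @return Integer array `(n, n, 3)` with values in `0..255`.
#' @export
overlay_cam <- function(cam, image, alpha = 0.4) {
  heat <- if (inherits(cam, "sac_cam")) cam$upsampled else cam
  d <- dim(image)
  if (!identical(dim(heat), d[1:2])) {
    stop(sprintf("heatmap extent (%s) does not match image extent (%s)",
                 paste(dim(heat), collapse = "x"),
                 paste(d[1:2], collapse = "x")))
  }
  pal <- default_cam_palette()
  idx <- pmin(pmax(round(heat * 255) + 1L, 1L), 256L)
  w <- alpha * heat
  out <- array(0, d)
  for (ch in 1:3) {
    col_ch <- matrix(pal[idx, ch], d[1], d[2])
    out[, , ch] <- (1 - w) * image[, , ch] + w * col_ch
  }
  array(as.integer(round(pmin(pmax(out, 0), 1) * 255)), d)
}

#' Write an overlay (or any 8-bit RGB array) as PNG
#'
#' @param rgb Integer array `(H, W, 3)` in `0..255`, or numeric in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(rgb, path) {
  if (is.integer(rgb) || max(rgb) > 1) rgb <- rgb / 255
  png::writePNG(array(pmin(pmax(rgb, 0), 1), dim(rgb)), path)
  invisible(path)
}
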
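# Image loading and the elementary augmentations.

#' Kvasir-style class label sets
#'
#' `kvasir_classes()` returns the eight folder names of the raw layout
#' (three anatomical "normal" landmark classes plus five findings);
#' `merged_classes()` returns the six labels after the normal classes are
#' collapsed, in the fixed alphabetical order used throughout the package.
#'
#' @return Character vector of class labels.
#' @export
kvasir_classes <- function() {
  c("dyed-lifted-polyps", "dyed-resection-margins", "esophagitis",
    "normal-cecum", "normal-pylorus", "normal-z-line",
    "polyps", "ulcerative-colitis")
}

#' @rdname kvasir_classes
#' @export
merged_classes <- function() {
  c("dyed-lifted-polyps", "dyed-resection-margins", "esophagitis",
    "normal", "polyps", "ulcerative-colitis")
}

normal_source_classes <- function() {
  c("normal-cecum", "normal-pylorus", "normal-z-line")
}

#' Load an image and resize it to the network input size
#'
#' Reads a PNG or JPEG, converts to an RGB array in `[0, 1]` (grayscale
#' inputs are replicated across the three channels, an alpha channel is
#' dropped) and resizes with bilinear resampling.
#'
#' @param path Image file path.
#' @param size Target edge length in pixels (square output).
#' @return Array `(size, size, 3)` with values in `[0, 1]`.
#' @export
load_and_resize <- function(path, size = 128L) {
  img <- tryCatch(suppressWarnings(EBImage::readImage(path)),
                  error = function(e) stop("cannot read image '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  x <- EBImage::imageData(img)
  if (length(dim(x)) == 2L) {
    x <- array(rep(x, 3L), c(dim(x), 3L))
  } else if (dim(x)[3] > 3L) {
    x <- x[, , 1:3, drop = FALSE]
  } else if (dim(x)[3] == 1L) {
    x <- array(rep(x, 3L), c(dim(x)[1:2], 3L))
  }
  if (dim(x)[1] != size || dim(x)[2] != size) {
    x <- EBImage::imageData(EBImage::resize(
      EBImage::Image(x, colormode = "Color"), w = size, h = size))
  }
  x <- array(pmin(pmax(as.numeric(x), 0), 1), c(size, size, 3L))
  x
}

#' Geometric augmentations
#'
#' `mirror_image()` flips horizontally (first spatial axis reversed);
#' `rotate_image_180()` reverses both spatial axes. Both are pixel-exact
#' involutions: applying either twice returns the input unchanged.
#'
#' @param img Array `(H, W, C)`.
#' @return Array of the same shape.
#' @export
mirror_image <- function(img) {
  img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
}

#' @rdname mirror_image
#' @export
rotate_image_180 <- function(img) {
  img[rev(seq_len(dim(img)[1])), rev(seq_len(dim(img)[2])), , drop = FALSE]
}

#' Random brightness shift
#'
#' Adds one scalar delta, drawn uniformly from `delta_range`, to every
#' pixel and clips to `[0, 1]`. Uses the current RNG stream.
#'
#' @param img Array with values in `[0, 1]`.
#' @param delta_range Length-2 numeric range for the shift.
#' @return Shifted, clipped array of the same shape.
#' @export
random_brightness <- function(img, delta_range = c(-0.2, 0.2)) {
  delta <- stats::runif(1, delta_range[1], delta_range[2])
  array(pmin(pmax(img + delta, 0), 1), dim = dim(img))
}

# apply the provenance transform recorded in a manifest row
apply_provenance <- function(img, provenance) {
  switch(provenance,
         original = img,
         mirrored = mirror_image(img),
         rotated180 = rotate_image_180(img),
         stop("unknown provenance: ", provenance))
}

#' Load every image referenced by a manifest into one tensor
#'
#' Reads, resizes and applies each record's provenance transform
#' (mirroring / 180-degree rotation for augmented records), preserving
#' manifest row order.
#'
#' @param manifest A dataset manifest (see [manifest_from_directory()]).
#' @param size Target edge length in pixels.
#' @return Array `(size, size, N, 3)`.
#' @export
load_manifest_images <- function(manifest, size = 128L) {
  N <- nrow(manifest)
  out <- array(0, c(size, size, N, 3L))
  for (i in seq_len(N)) {
    out[, , i, ] <- apply_provenance(load_and_resize(manifest$path[i], size),
                                     manifest$provenance[i])
  }
  out
}
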
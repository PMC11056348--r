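# Deterministic synthetic endoscopy-like fixtures. Eight Kvasir-shaped
# class folders with class-distinct procedural motifs over correlated
# noise; optionally burned-in text glyphs and a dark frame border, the two
# artifacts real endoscopy frames carry. Not photorealistic by design --
# the fixtures exist to exercise the pipeline end to end.

#' Fixture generation settings
#'
#' @param n_per_class Images per class folder.
#' @param image_size Edge length in pixels.
#' @param seed Integer seed; generation is a pure function of this spec,
#'   so the same spec yields byte-identical image trees.
#' @param with_text_artifacts Burn white text-like glyph blocks into a
#'   corner of every image.
#' @param with_border Draw a dark frame border.
#' @return An object of class `sac_fixture_spec`.
#' @export
fixture_spec <- function(n_per_class = 10L, image_size = 128L, seed = 42L,
                         with_text_artifacts = FALSE, with_border = FALSE) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  structure(list(n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 seed = as.integer(seed),
                 with_text_artifacts = isTRUE(with_text_artifacts),
                 with_border = isTRUE(with_border)),
            class = "sac_fixture_spec")
}

# smooth correlated noise field in [-1, 1], one channel
correlated_noise <- function(size, grid = 8L) {
  lo <- matrix(stats::runif(grid * grid, -1, 1), grid, grid)
  up <- EBImage::imageData(EBImage::resize(EBImage::Image(lo),
                                           w = size, h = size))
  matrix(up, size, size)
}

coord_grid <- function(size) {
  u <- (seq_len(size) - 0.5) / size
  list(x = matrix(u, size, size), y = matrix(u, size, size, byrow = TRUE))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# one synthetic frame for a class; consumes the current RNG stream
synth_image <- function(class, size) {
  g <- coord_grid(size)
  base <- switch(class,
    "dyed-lifted-polyps" = c(0.25, 0.45, 0.60),
    "dyed-resection-margins" = c(0.20, 0.50, 0.55),
    "esophagitis" = c(0.80, 0.55, 0.50),
    "normal-cecum" = c(0.75, 0.45, 0.40),
    "normal-pylorus" = c(0.78, 0.50, 0.45),
    "normal-z-line" = c(0.72, 0.42, 0.48),
    "polyps" = c(0.72, 0.40, 0.35),
    "ulcerative-colitis" = c(0.65, 0.25, 0.22))
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    img[, , ch] <- base[ch] + 0.08 * correlated_noise(size)
  }
  cx <- stats::runif(1, 0.3, 0.7)
  cy <- stats::runif(1, 0.3, 0.7)
  r2 <- (g$x - cx)^2 + 1.6 * (g$y - cy)^2
  if (class %in% c("polyps", "dyed-lifted-polyps")) {
    blob <- exp(-r2 / (2 * 0.012))
    lift <- if (class == "polyps") c(0.25, 0.30, 0.30) else c(0.35, 0.30, 0.10)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + lift[ch] * blob
  } else if (class == "dyed-resection-margins") {
    ring <- exp(-((sqrt(r2) - 0.22)^2) / (2 * 0.002))
    for (ch in 1:3) img[, , ch] <- img[, , ch] - 0.35 * ring
  } else if (class == "esophagitis") {
    phase <- stats::runif(1, 0, 2 * pi)
    streaks <- pmax(sin(2 * pi * 7 * g$x + phase), 0)^3
    img[, , 1] <- img[, , 1] + 0.18 * streaks
    img[, , 2] <- img[, , 2] + 0.14 * streaks
    img[, , 3] <- img[, , 3] + 0.14 * streaks
  } else if (class == "ulcerative-colitis") {
    n_spots <- 25L
    sx <- stats::runif(n_spots); sy <- stats::runif(n_spots)
    spots <- matrix(0, size, size)
    for (s in seq_len(n_spots)) {
      spots <- spots + exp(-(((g$x - sx[s])^2 + (g$y - sy[s])^2)) / (2 * 0.0004))
    }
    spots <- pmin(spots, 1)
    img[, , 1] <- img[, , 1] + 0.25 * spots
    img[, , 2] <- img[, , 2] + 0.22 * spots
  } else if (class == "normal-pylorus") {
    hole <- exp(-r2 / (2 * 0.008))
    for (ch in 1:3) img[, , ch] <- img[, , ch] - 0.30 * hole
  } else if (class == "normal-z-line") {
    boundary <- 1 / (1 + exp(-(g$y - stats::runif(1, 0.4, 0.6)) * 30))
    img[, , 1] <- img[, , 1] + 0.10 * boundary
    img[, , 3] <- img[, , 3] - 0.08 * boundary
  }
  # normal-cecum: smooth mucosa, no motif beyond the correlated noise
  clip01(img)
}

add_text_glyphs <- function(img) {
  size <- dim(img)[1]
  row0 <- 6L
  col <- 6L
  for (gl in seq_len(6L)) {
    w <- sample(3:6, 1)
    img[row0:(row0 + 7L), col:(col + w), ] <- 1
    col <- col + w + 3L
    if (col + 7L > size) break
  }
  img
}

add_border <- function(img, width = 6L) {
  size <- dim(img)[1]
  img[c(seq_len(width), (size - width + 1L):size), , ] <- 0
  img[, c(seq_len(width), (size - width + 1L):size), ] <- 0
  img
}

write_fixture_image <- function(img, path) {
  ok <- tryCatch({png::writePNG(img, path); TRUE},
                 error = function(e) stop("cannot write image '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  invisible(ok)
}

#' Generate a Kvasir-shaped synthetic dataset
#'
#' Writes `n_per_class` PNG frames into each of the eight class folders
#' (five findings/procedure classes plus three `normal-*` landmark
#' classes). Each class carries a distinct procedural motif — bright
#' ellipse blob (polyp-like), green-blue tint (dye-like), periodic bright
#' streaks (esophagitis-like), bright speckles on a red base
#' (colitis-like), smooth mucosa fields (normal-like) — over correlated
#' noise, so simple pixel statistics already separate the classes.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if absent).
#' @return Manifest of the generated images (all provenance `original`,
#'   no split assigned).
#' @export
generate_fixture_dataset <- function(spec, out_dir) {
  counts <- stats::setNames(rep(spec$n_per_class, 8L), kvasir_classes())
  generate_fixture_counts(counts, spec, out_dir)
}

generate_fixture_counts <- function(counts, spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  with_seed(spec$seed, {
    rows <- list()
    for (cl in names(counts)) {
      cl_dir <- file.path(out_dir, cl)
      dir.create(cl_dir, showWarnings = FALSE)
      for (i in seq_len(counts[[cl]])) {
        img <- synth_image(cl, spec$image_size)
        if (spec$with_text_artifacts) img <- add_text_glyphs(img)
        if (spec$with_border) img <- add_border(img)
        path <- file.path(cl_dir, sprintf("%s_%03d.png", cl, i))
        write_fixture_image(img, path)
        rows[[length(rows) + 1L]] <- data.frame(path = path, label = cl,
                                                stringsAsFactors = FALSE)
      }
    }
    as_manifest(do.call(rbind, rows))
  })
}

#' Fixed 60-image benchmark set
#'
#' A small fixed post-merge benchmark: 10 images for each of the six
#' merged classes (the 10 `normal` images are drawn 4/3/3 from the three
#' normal source folders), every record assigned to the training split.
#' Used by the overfit-sanity check: a small SAC must be able to reach
#' 100% training accuracy on it.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param image_size Edge length in pixels.
#' @return Merged six-class manifest of 60 training records.
#' @export
tiny_benchmark <- function(out_dir, seed = 7L, image_size = 128L) {
  counts <- c("dyed-lifted-polyps" = 10L, "dyed-resection-margins" = 10L,
              "esophagitis" = 10L, "normal-cecum" = 4L,
              "normal-pylorus" = 3L, "normal-z-line" = 3L,
              "polyps" = 10L, "ulcerative-colitis" = 10L)
  spec <- fixture_spec(n_per_class = 1L, image_size = image_size, seed = seed)
  man <- generate_fixture_counts(counts, spec, out_dir)
  man <- merge_normal_classes(man)
  man$split <- "train"
  man
}
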
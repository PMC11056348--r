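# Dataset manifests: directory scanning, normal-class merging, geometric
# class balancing, and stratified splitting.

new_manifest <- function(path = character(), label = character(),
                         split = character(), provenance = character(),
                         parent = character()) {
  df <- data.frame(path = path, label = label, split = split,
                   provenance = provenance, parent = parent,
                   stringsAsFactors = FALSE)
  class(df) <- c("sac_manifest", class(df))
  df
}

as_manifest <- function(df) {
  for (col in c("split", "provenance", "parent")) {
    if (is.null(df[[col]])) {
      df[[col]] <- rep(if (col == "provenance") "original" else NA_character_,
                       nrow(df))
    }
  }
  if (!nrow(df)) return(new_manifest())
  new_manifest(df$path, df$label, df$split, df$provenance, df$parent)
}

#' Build a manifest from a directory-per-class image tree
#'
#' Scans `root` for one sub-directory per class and lists the PNG/JPEG
#' files inside each, producing one `original` record per image with no
#' split assignment yet.
#'
#' @param root Directory containing one folder per class.
#' @param classes Expected folder names; defaults to the eight-folder
#'   Kvasir layout.
#' @return A manifest data.frame with columns `path`, `label`, `split`,
#'   `provenance`, `parent`.
#' @export
manifest_from_directory <- function(root, classes = kvasir_classes()) {
  missing <- classes[!dir.exists(file.path(root, classes))]
  if (length(missing)) {
    stop("missing class folder(s) under '", root, "': ",
         paste(missing, collapse = ", "),
         "; expected: ", paste(classes, collapse = ", "))
  }
  parts <- lapply(classes, function(cl) {
    files <- sort(list.files(file.path(root, cl),
                             pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) return(NULL)
    data.frame(path = files, label = cl, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  if (is.null(df)) df <- data.frame(path = character(), label = character())
  as_manifest(df)
}

#' Merge the three normal classes into one
#'
#' Maps `normal-cecum`, `normal-pylorus` and `normal-z-line` to the single
#' label `normal`, leaving the five disease/procedure classes unchanged.
#' Record count is conserved; after merging the label set is the fixed
#' six-class ordering of [merged_classes()].
#'
#' @param manifest An eight-class manifest.
#' @return The merged six-class manifest.
#' @export
merge_normal_classes <- function(manifest) {
  expected <- kvasir_classes()
  present <- unique(manifest$label)
  unknown <- setdiff(present, expected)
  if (length(unknown)) {
    stop("unexpected class label(s): ", paste(unknown, collapse = ", "),
         "; expected labels: ", paste(expected, collapse = ", "))
  }
  manifest$label[manifest$label %in% normal_source_classes()] <- "normal"
  attr(manifest, "classes") <- merged_classes()
  manifest
}

#' Augmentation plan
#'
#' Declares which classes receive the static geometric balancing
#' (mirroring and 180-degree rotation) and the on-the-fly random
#' brightness range. The published recipe mirrors/rotates only the five
#' non-normal classes — the merged normal class already holds three times
#' the images — and applies random brightness to all six.
#'
#' @param mirror_classes,rotate_classes Classes receiving each geometric
#'   augmentation.
#' @param random_brightness Apply a random brightness shift during
#'   training (all classes)?
#' @param brightness_delta Half-width of the uniform brightness shift, on
#'   the `[0, 1]` intensity scale.
#' @return An object of class `sac_aug_plan`.
#' @export
augmentation_plan <- function(mirror_classes = setdiff(merged_classes(), "normal"),
                              rotate_classes = setdiff(merged_classes(), "normal"),
                              random_brightness = TRUE,
                              brightness_delta = 0.2) {
  structure(list(mirror_classes = mirror_classes,
                 rotate_classes = rotate_classes,
                 random_brightness = isTRUE(random_brightness),
                 brightness_delta = brightness_delta),
            class = "sac_aug_plan")
}

#' Balance classes with mirrored and rotated copies
#'
#' Adds, for every record of a class listed in the plan, a `mirrored` and
#' a `rotated180` derived record (the transform itself is applied lazily at
#' load time). Classes not listed — the merged `normal` class under the
#' default plan — are left untouched. In paper-faithful mode a plan that
#' geometrically augments `normal` is refused with a warning, since the
#' whole point of the balancing is that `normal` is already three-fold
#' over-represented.
#'
#' @param manifest A merged six-class manifest.
#' @param plan An [augmentation_plan()].
#' @param paper_faithful Refuse geometric augmentation of `normal`?
#' @return Manifest with derived records appended (provenance and parent
#'   recorded).
#' @export
balance_with_augmentation <- function(manifest, plan = augmentation_plan(),
                                      paper_faithful = TRUE) {
  mirror_cl <- plan$mirror_classes
  rotate_cl <- plan$rotate_classes
  if (paper_faithful && "normal" %in% c(mirror_cl, rotate_cl)) {
    warning("refusing geometric augmentation of the 'normal' class; ",
            "it is already three-fold over-represented after merging")
    mirror_cl <- setdiff(mirror_cl, "normal")
    rotate_cl <- setdiff(rotate_cl, "normal")
  }
  orig <- manifest[manifest$provenance == "original", , drop = FALSE]
  pieces <- list(manifest)
  mi <- orig[orig$label %in% mirror_cl, , drop = FALSE]
  if (nrow(mi)) {
    mi$provenance <- "mirrored"
    mi$parent <- mi$path
    pieces <- c(pieces, list(mi))
  }
  ro <- orig[orig$label %in% rotate_cl, , drop = FALSE]
  if (nrow(ro)) {
    ro$provenance <- "rotated180"
    ro$parent <- ro$path
    pieces <- c(pieces, list(ro))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  as_manifest(out)
}

#' Stratified train/validation/test split
#'
#' Assigns every record to exactly one split, stratified per class, with
#' two orderings of the split-vs-augment question:
#'
#' * `paper_faithful`: splits the manifest as given (typically after
#'   geometric balancing). With 3,000 records per class and the default
#'   70/15/15 fractions this yields 2,100 / 450 / 450 per class — the
#'   published per-class test support of 450.
#' * `leakage_safe`: splits the `original` records first and lets derived
#'   records inherit their parent's assignment, keeping augmented copies
#'   only in the training partition. No mirrored/rotated copy of a
#'   validation or test image can then reach the training set.
#'
#' Deterministic for a fixed `seed`.
#'
#' @param manifest A manifest.
#' @param fractions Named or positional numeric vector `(train, val, test)`
#'   summing to 1, each fraction in (0, 1).
#' @param seed Integer seed for the split permutation.
#' @param mode `"paper_faithful"` or `"leakage_safe"`.
#' @return Manifest with the `split` column filled.
#' @export
split_manifest <- function(manifest, fractions = c(train = 0.70, val = 0.15,
                                                   test = 0.15),
                           seed = 42L,
                           mode = c("paper_faithful", "leakage_safe")) {
  mode <- match.arg(mode)
  if (length(fractions) != 3L || any(fractions <= 0) || any(fractions >= 1)) {
    stop("fractions must be three values in (0, 1)")
  }
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  names(fractions) <- c("train", "val", "test")

  assign_rows <- function(idx) {
    n <- length(idx)
    n_test <- round(fractions["test"] * n)
    n_val <- round(fractions["val"] * n)
    perm <- sample(idx)
    out <- rep("train", n)
    if (n_test > 0) out[seq_len(n_test)] <- "test"
    if (n_val > 0) out[n_test + seq_len(n_val)] <- "val"
    list(idx = perm, split = out)
  }

  with_seed(seed, {
    if (mode == "paper_faithful") {
      for (cl in unique(manifest$label)) {
        idx <- which(manifest$label == cl)
        a <- assign_rows(idx)
        manifest$split[a$idx] <- a$split
      }
    } else {
      orig <- which(manifest$provenance == "original")
      for (cl in unique(manifest$label)) {
        idx <- intersect(which(manifest$label == cl), orig)
        a <- assign_rows(idx)
        manifest$split[a$idx] <- a$split
      }
      derived <- which(manifest$provenance != "original")
      if (length(derived)) {
        parent_split <- manifest$split[orig][match(manifest$parent[derived],
                                                   manifest$path[orig])]
        manifest$split[derived] <- parent_split
        drop <- derived[parent_split != "train"]
        if (length(drop)) manifest <- manifest[-drop, , drop = FALSE]
      }
    }
    rownames(manifest) <- NULL
    manifest
  })
}

#' Read / write a manifest as CSV
#'
#' @param manifest A manifest.
#' @param path CSV file path.
#' @return `write_manifest_csv` returns `path` invisibly;
#'   `read_manifest_csv` returns the manifest.
#' @export
write_manifest_csv <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest_csv
#' @export
read_manifest_csv <- function(path) {
  as_manifest(utils::read.csv(path, stringsAsFactors = FALSE,
                              colClasses = "character"))
}

#' Audit a manifest for augmentation leakage
#'
#' Checks that no derived (mirrored / rotated) copy of a validation or
#' test image sits in the training partition, and vice versa.
#'
#' @param manifest A split manifest.
#' @return `TRUE` if clean; otherwise a character vector describing the
#'   offending records.
#' @export
audit_leakage <- function(manifest) {
  derived <- manifest[manifest$provenance != "original", , drop = FALSE]
  if (!nrow(derived)) return(TRUE)
  parent_split <- manifest$split[manifest$provenance == "original"][
    match(derived$parent,
          manifest$path[manifest$provenance == "original"])]
  bad <- which(derived$split != parent_split |
                 (derived$split %in% c("val", "test")))
  if (!length(bad)) return(TRUE)
  sprintf("derived record '%s' (%s) in split '%s' (parent split '%s')",
          derived$path[bad], derived$provenance[bad], derived$split[bad],
          parent_split[bad])
}
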
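# Preprocessing pipeline: merging, balancing, splitting, image ops.

test_that("normal-class merging conserves records and fixes the label set", {
  man <- fake_kvasir_manifest(10L)
  merged <- merge_normal_classes(man)
  expect_equal(nrow(merged), nrow(man))
  tab <- table(merged$label)
  expect_equal(sort(names(tab)), merged_classes())
  expect_equal(unname(tab["normal"]), 30L)
  expect_true(all(tab[setdiff(names(tab), "normal")] == 10L))
  # empty manifest: still declares the six merged classes
  empty <- merge_normal_classes(sacmix:::as_manifest(
    data.frame(path = character(), label = character())))
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "classes"), merged_classes())
  bad <- sacmix:::as_manifest(data.frame(path = "x.png", label = "mystery"))
  expect_error(merge_normal_classes(bad), "mystery")
})

test_that("missing class folders are reported by name", {
  root <- file.path(tempdir(), "incomplete-tree")
  dir.create(file.path(root, "polyps"), recursive = TRUE, showWarnings = FALSE)
  expect_error(manifest_from_directory(root), "esophagitis")
})

test_that("geometric balancing triples disease classes and spares normal", {
  man <- merge_normal_classes(fake_kvasir_manifest(10L))
  bal <- balance_with_augmentation(man)
  tab <- table(bal$label)
  expect_true(all(tab[setdiff(merged_classes(), "normal")] == 30L))
  expect_equal(unname(tab["normal"]), 30L)   # untouched: 3 x 10 originals
  expect_equal(sort(unique(bal$provenance[bal$label == "normal"])), "original")
  expect_setequal(unique(bal$provenance[bal$label == "polyps"]),
                  c("original", "mirrored", "rotated180"))
  # a plan that would augment normal is refused with a warning
  plan <- augmentation_plan(mirror_classes = merged_classes())
  expect_warning(bal2 <- balance_with_augmentation(man, plan), "normal")
  expect_equal(sum(bal2$label == "normal" & bal2$provenance != "original"), 0L)
})

test_that("mirror and rotate-180 are pixel-exact involutions", {
  set.seed(17)
  img <- array(runif(7 * 5 * 3), c(7, 5, 3))
  expect_identical(mirror_image(mirror_image(img)), img)
  expect_identical(rotate_image_180(rotate_image_180(img)), img)
  expect_false(identical(mirror_image(img), img))
  # and they commute into each other: rot180 = mirror in both axes
  expect_identical(rotate_image_180(img),
                   mirror_image(img)[, rev(seq_len(5)), , drop = FALSE])
})

test_that("paper-faithful splitting is stratified, deterministic, and seeded", {
  man <- balance_with_augmentation(merge_normal_classes(fake_kvasir_manifest(20L)))
  sp1 <- split_manifest(man, seed = 1)
  sp2 <- split_manifest(man, seed = 1)
  sp3 <- split_manifest(man, seed = 2)
  expect_identical(sp1$split, sp2$split)
  expect_false(identical(sp1$split, sp3$split))
  for (cl in merged_classes()) {
    n <- sum(sp1$label == cl)
    tab <- table(factor(sp1$split[sp1$label == cl],
                        c("train", "val", "test")))
    expect_lte(abs(tab[["test"]] - 0.15 * n), 1)
    expect_lte(abs(tab[["val"]] - 0.15 * n), 1)
    expect_lte(abs(tab[["train"]] - 0.70 * n), 2)
  }
  expect_error(split_manifest(man, fractions = c(0.5, 0.5, 0)), "fractions")
  expect_error(split_manifest(man, fractions = c(0.6, 0.3, 0.3)), "sum to 1")
})

test_that("leakage-safe splitting keeps derived copies out of val/test", {
  man <- balance_with_augmentation(merge_normal_classes(fake_kvasir_manifest(20L)))
  sp <- split_manifest(man, seed = 3, mode = "leakage_safe")
  expect_true(isTRUE(audit_leakage(sp)))
  derived <- sp[sp$provenance != "original", ]
  expect_true(all(derived$split == "train"))
  orig <- sp[sp$provenance == "original", ]
  parent_split <- orig$split[match(derived$parent, orig$path)]
  expect_true(all(parent_split == "train"))
  # originals of every class still stratify
  for (cl in merged_classes()) {
    n <- sum(orig$label == cl)
    expect_lte(abs(sum(orig$label == cl & orig$split == "test") - 0.15 * n), 1)
  }
  # a corrupted assignment is caught by the audit
  bad <- sp
  i <- which(bad$provenance == "mirrored")[1]
  bad$split[i] <- "test"
  expect_type(audit_leakage(bad), "character")
})

test_that("random brightness adds one clipped scalar shift", {
  set.seed(18)
  img <- array(runif(6 * 6 * 3), c(6, 6, 3))
  expect_equal(random_brightness(img, c(0, 0)), img, tolerance = 1e-15)
  half <- array(0.5, c(4, 4, 3))
  expect_equal(unique(as.numeric(random_brightness(half, c(0.2, 0.2)))), 0.7,
               tolerance = 1e-12)
  for (rep in 1:5) {
    out <- random_brightness(img, c(-0.9, 0.9))
    expect_gte(min(out), 0)
    expect_lte(max(out), 1)
    # unclipped pixels all move by the same delta
    interior <- out > 0 & out < 1 & img > 0 & img < 1
    if (sum(interior) > 1) {
      deltas <- (out - img)[interior]
      expect_lt(diff(range(deltas)), 1e-12)
    }
  }
})

test_that("load_and_resize yields a 3-channel unit-range tensor of the target size", {
  # non-square source resized down
  src <- tempfile(fileext = ".png")
  set.seed(19)
  png::writePNG(array(runif(90 * 72 * 3), c(90, 72, 3)), src)
  x <- load_and_resize(src, size = 32)
  expect_equal(dim(x), c(32L, 32L, 3L))
  expect_gte(min(x), 0); expect_lte(max(x), 1)
  # already at target size: values preserved exactly (8-bit quantized source)
  src2 <- tempfile(fileext = ".png")
  q <- round(array(runif(32 * 32 * 3), c(32, 32, 3)) * 255) / 255
  png::writePNG(q, src2)
  x2 <- load_and_resize(src2, size = 32)
  expect_equal(max(abs(x2 - aperm(q, c(2, 1, 3)))), 0, tolerance = 1e-7)
  # grayscale replicated across channels
  src3 <- tempfile(fileext = ".png")
  png::writePNG(matrix(runif(40 * 40), 40, 40), src3)
  x3 <- load_and_resize(src3, size = 32)
  expect_equal(x3[, , 1], x3[, , 2])
  expect_equal(x3[, , 2], x3[, , 3])
  expect_error(load_and_resize(tempfile(fileext = ".png")), "cannot read")
})

test_that("manifests round-trip through CSV with provenance intact", {
  man <- balance_with_augmentation(merge_normal_classes(fake_kvasir_manifest(3L)))
  man <- split_manifest(man, seed = 4)
  p <- tempfile(fileext = ".csv")
  write_manifest_csv(man, p)
  back <- read_manifest_csv(p)
  expect_equal(back$path, man$path)
  expect_equal(back$split, man$split)
  expect_equal(back$provenance, man$provenance)
})
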
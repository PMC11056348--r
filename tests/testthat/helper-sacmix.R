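# Shared helpers: small configurations, random feature maps, in-memory
# manifests shaped like the Kvasir layout.

tiny_config <- function(...) {
  args <- list(image_size = 8L, patch_size = 2L, hidden_dim = 4L,
               depth = 1L, kernel_size = 3L, num_classes = 2L)
  args[names(list(...))] <- list(...)
  do.call(model_config, args)
}

rand_batch <- function(cfg, B = 2L) {
  array(runif(cfg$image_size^2 * B * 3), c(cfg$image_size, cfg$image_size, B, 3))
}

rand_fm <- function(H, W, C, B = NULL) {
  if (is.null(B)) array(rnorm(H * W * C), c(H, W, C))
  else array(rnorm(H * W * B * C), c(H, W, B, C))
}

# manifest with n records per raw Kvasir class, fake paths, no files
fake_kvasir_manifest <- function(n_per_class = 10L) {
  rows <- lapply(kvasir_classes(), function(cl) {
    data.frame(path = sprintf("%s/img_%04d.png", cl, seq_len(n_per_class)),
               label = cl, stringsAsFactors = FALSE)
  })
  sacmix:::as_manifest(do.call(rbind, rows))
}

# small real fixture tree, cached per session
fixture_dir_small <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "sacmix-fixture-small")
      if (!dir.exists(dir)) {
        generate_fixture_dataset(
          fixture_spec(n_per_class = 3L, image_size = 32L, seed = 101L), dir)
      }
    }
    dir
  }
})
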
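# Core network: configuration validation, shapes, the attention gate,
# mixer blocks, parameter accounting, and gradient correctness.

test_that("configuration invariants are enforced with the field named", {
  expect_error(model_config(depth = 0), "depth")
  expect_error(model_config(hidden_dim = -1), "hidden_dim")
  expect_error(model_config(image_size = 127), "divisible")
  expect_s3_class(model_config(), "sac_config")
})

test_that("default architecture mirrors the published layer summary", {
  sh <- sac_shapes(model_config())
  expect_equal(sh$output[sh$stage == "patch embedding"], "64, 64, 256")
  blk <- sh[sh$stage == "block 8", ]
  expect_true(all(blk$output == "64, 64, 256"))
  expect_equal(tail(sh$output, 2), c("256", "6"))
  # spatial attention emits a one-channel gate then restores full depth
  sa <- sh[sh$stage == "spatial attention", ]
  expect_equal(sa$output, c("64, 64, 1", "64, 64, 256"))
})

test_that("forward pass emits softmax rows over the class count", {
  cfg <- tiny_config()
  m <- build_sac(cfg, seed = 1)
  set.seed(4)
  x <- rand_batch(cfg, B = 3L)
  for (training in c(TRUE, FALSE)) {
    fw <- sacmix:::sac_forward(m, x, training = training)
    expect_equal(dim(fw$probs), c(3L, 2L))
    expect_true(all(fw$probs >= 0))
    expect_equal(rowSums(fw$probs), rep(1, 3), tolerance = 1e-6)
  }
  expect_error(sacmix:::sac_forward(m, array(0, c(4, 4, 1, 3))), "shape")
})

test_that("spatial attention gates every channel by a (0,1) sigmoid map", {
  set.seed(5)
  f <- rand_fm(4, 4, 6)
  # zero parameters: sigmoid(0) = 1/2 exactly halves the features
  res <- apply_spatial_attention(f, w = numeric(6), b = 0)
  expect_identical(res$output, f * 0.5)
  expect_true(all(res$attention == 0.5))
  # random parameters: gate strictly inside (0, 1), output shape preserved
  res2 <- apply_spatial_attention(f, w = rnorm(6), b = 0.3)
  expect_true(all(res2$attention > 0 & res2$attention < 1))
  expect_equal(dim(res2$output), dim(f))
  expect_error(apply_spatial_attention(f, w = numeric(5)), "does not match")
})

test_that("hand-evaluated gate: x=(1,-1), w=(2,0), b=0", {
  f <- array(c(1, -1), c(1, 1, 2))
  res <- apply_spatial_attention(f, w = c(2, 0), b = 0)
  gate <- 1 / (1 + exp(-2))
  expect_equal(res$attention[1, 1], gate, tolerance = 1e-12)
  expect_equal(as.numeric(res$output), c(gate, -gate), tolerance = 1e-12)
  expect_equal(gate, 0.8808, tolerance = 1e-4)
})

test_that("mixer blocks preserve spatial extent and reduce to the input when the branch is zero", {
  set.seed(6)
  for (order in c("table1", "original_convmixer")) {
    cfg <- model_config(image_size = 12, patch_size = 2, hidden_dim = 5,
                        depth = 1, kernel_size = 3, block_order = order)
    m <- build_sac(cfg, seed = 2)
    f <- rand_fm(6, 6, 5, B = 2)
    out <- apply_convmixer_block(f, sacmix:::block_params(m, 1), cfg)
    expect_equal(dim(out), dim(f))
  }
  # zero depthwise branch (weights, bias, BN shift all zero) => Add is identity;
  # probe it with an identity-like pointwise stage in the original ordering
  cfg <- model_config(image_size = 12, patch_size = 2, hidden_dim = 5,
                      depth = 1, kernel_size = 3,
                      block_order = "original_convmixer")
  f <- rand_fm(6, 6, 5, B = 2)
  pars <- list(dwK = array(0, c(3, 3, 5)), dwb = numeric(5),
               bn1_gamma = rep(1, 5), bn1_beta = numeric(5),
               pwW = diag(5), pwb = numeric(5),
               bn2_gamma = rep(1, 5), bn2_beta = numeric(5))
  # the residual add passes f through unchanged, so with an identity pointwise
  # stage both orderings collapse to BN(GELU(f))
  mat <- matrix(f, 6 * 6 * 2, 5)
  manual <- sacmix:::bn_forward(sacmix:::gelu(mat), rep(1, 5), numeric(5),
                                sacmix:::bn_state_init(5), TRUE)$out
  out_oc <- apply_convmixer_block(f, pars, cfg)
  expect_equal(matrix(out_oc, 6 * 6 * 2, 5), manual, tolerance = 1e-12)
  cfg_t1 <- model_config(image_size = 12, patch_size = 2, hidden_dim = 5,
                         depth = 1, kernel_size = 3, block_order = "table1")
  out_t1 <- apply_convmixer_block(f, pars, cfg_t1)
  expect_equal(matrix(out_t1, 6 * 6 * 2, 5), manual, tolerance = 1e-12)
})

test_that("analytic parameter accounting matches allocation for random configurations", {
  set.seed(7)
  for (rep in 1:20) {
    cfg <- model_config(
      image_size = 4 * sample(1:4, 1),
      patch_size = sample(c(1, 2, 4), 1),
      hidden_dim = sample(2:12, 1),
      depth = sample(1:3, 1),
      kernel_size = sample(1:5, 1),
      num_classes = sample(2:8, 1),
      use_spatial_attention = sample(c(TRUE, FALSE), 1),
      block_order = sample(c("table1", "original_convmixer"), 1))
    bd <- count_trainable_params(cfg)
    expect_identical(bd$total_trainable,
                     bd$stem + bd$spatial_attention + bd$blocks_total + bd$head)
    expect_identical(bd$blocks_total, cfg$depth * bd$per_block)
    expect_identical(n_trainable_params(build_sac(cfg)), bd$total_trainable)
  }
})

test_that("block ordering never changes the parameter breakdown", {
  set.seed(8)
  for (rep in 1:5) {
    h <- sample(2:16, 1); k <- sample(1:5, 1); d <- sample(1:4, 1)
    a <- count_trainable_params(model_config(
      image_size = 16, patch_size = 2, hidden_dim = h, depth = d,
      kernel_size = k, block_order = "table1"))
    b <- count_trainable_params(model_config(
      image_size = 16, patch_size = 2, hidden_dim = h, depth = d,
      kernel_size = k, block_order = "original_convmixer"))
    expect_identical(unclass(a), unclass(b))
  }
})

test_that("per-block parameter arithmetic at h=256, k=5", {
  bd <- count_trainable_params(model_config())
  expect_identical(bd$per_block,
                   (25L * 256L + 256L) + 512L + (256L * 256L + 256L) + 512L)
  expect_identical(bd$per_block, 73472L)
})

test_that("backpropagation matches central finite differences", {
  set.seed(9)
  for (order in c("table1", "original_convmixer")) {
    cfg <- model_config(image_size = 8, patch_size = 2, hidden_dim = 3,
                        depth = 2, kernel_size = 3, num_classes = 2,
                        block_order = order)
    m <- build_sac(cfg, seed = 2)
    x <- rand_batch(cfg, B = 2L)
    y <- c(1L, 2L)
    loss_of <- function(model) {
      fw <- sacmix:::sac_forward(model, x, training = TRUE)
      -mean(log(fw$probs[cbind(1:2, y)]))
    }
    fw <- sacmix:::sac_forward(m, x, training = TRUE)
    onehot <- matrix(0, 2, 2); onehot[cbind(1:2, y)] <- 1
    g <- sacmix:::sac_backward(m, fw$cache, (fw$probs - onehot) / 2)
    for (nm in names(m$params)) {
      p <- m$params[[nm]]
      for (ii in sample(length(p), min(length(p), 3))) {
        eps <- 1e-5
        up <- m; up$params[[nm]][ii] <- p[ii] + eps
        dn <- m; dn$params[[nm]][ii] <- p[ii] - eps
        num <- (loss_of(up) - loss_of(dn)) / (2 * eps)
        expect_equal(g[[nm]][ii], num, tolerance = 1e-4,
                     label = sprintf("grad %s[%d] (%s)", nm, ii, order))
      }
    }
  }
})

test_that("weights survive a serialization round trip", {
  cfg <- tiny_config()
  m <- build_sac(cfg, seed = 3)
  path <- tempfile(fileext = ".rds")
  save_sac(m, path)
  m2 <- load_sac(path)
  expect_identical(m2$params, m$params)
  set.seed(10)
  x <- rand_batch(cfg, B = 2L)
  expect_identical(predict(m, x), predict(m2, x))
})
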
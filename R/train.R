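# Training engine: AdamW on categorical cross-entropy, plateau learning
# rate decay, best-checkpoint tracking on validation accuracy.

#' Training configuration
#'
#' Defaults reproduce the published recipe: AdamW with learning rate
#' 0.001 and decoupled weight decay 0.0001, batch size 32, 25 epochs,
#' learning rate halved after 3 epochs without validation-loss improvement
#' (floor 1e-6), and the best weights kept by validation accuracy.
#'
#' @param learning_rate Initial AdamW step size.
#' @param weight_decay Decoupled weight-decay coefficient (not applied to
#'   BatchNorm scale/shift).
#' @param batch_size Mini-batch size.
#' @param epochs Number of epochs.
#' @param seed Integer seed controlling shuffling, brightness draws and
#'   (via [build_sac()]) initialization.
#' @param plateau_factor,plateau_patience,min_lr Plateau schedule:
#'   multiply the learning rate by `plateau_factor` after
#'   `plateau_patience` consecutive epochs without validation-loss
#'   improvement, never below `min_lr`.
#' @param brightness Apply the random brightness augmentation to training
#'   batches? (`NULL` = take it from the augmentation plan; default on.)
#' @param brightness_delta Half-width of the uniform brightness shift.
#' @return An object of class `sac_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 0.0001,
                         batch_size = 32L, epochs = 25L, seed = 42L,
                         plateau_factor = 0.5, plateau_patience = 3L,
                         min_lr = 1e-6, brightness = TRUE,
                         brightness_delta = 0.2) {
  if (learning_rate <= 0 || weight_decay < 0) {
    stop("learning_rate must be positive and weight_decay non-negative")
  }
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch_size must be >= 1")
  if (plateau_factor <= 0 || plateau_factor > 1) {
    stop("plateau_factor must be in (0, 1]")
  }
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 min_lr = min_lr, brightness = isTRUE(brightness),
                 brightness_delta = brightness_delta),
            class = "sac_train_config")
}

#' Plateau learning-rate rule
#'
#' Returns `current_lr * factor` (not below `min_lr`) iff the monitored
#' loss has failed to improve for `patience` consecutive epochs at the
#' tail of `losses`; otherwise `current_lr` unchanged. Improvement means
#' strictly beating the best loss seen so far, and the waiting counter
#' restarts after each reduction, so during a long plateau the rate is
#' reduced every `patience` epochs rather than every epoch.
#'
#' @param losses Numeric vector of the monitored per-epoch losses so far.
#' @param current_lr Current learning rate.
#' @param factor Multiplicative decay factor in (0, 1].
#' @param patience Epochs without improvement that trigger the decay.
#' @param min_lr Lower bound for the learning rate.
#' @return The (possibly decayed) learning rate.
#' @export
plateau_step <- function(losses, current_lr, factor = 0.5, patience = 3L,
                         min_lr = 1e-6) {
  if (factor <= 0 || factor > 1) stop("factor must be in (0, 1]")
  n <- length(losses)
  if (n <= patience) return(current_lr)
  # epochs since the last strict improvement over the running best
  best <- cummin(losses)
  improved <- (losses == best) & !duplicated(best)
  improved[1] <- TRUE
  wait <- n - max(which(improved))
  if (wait >= patience && (wait - patience) %% patience == 0L) {
    max(current_lr * factor, min_lr)
  } else {
    current_lr
  }
}

cross_entropy <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), y_idx)], 1e-12)))
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
       v = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
       t = 0L)
}

is_bn_param <- function(name) grepl("gamma$|beta$", name)

adamw_step <- function(params, grads, opt, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gr
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gr * gr
    upd <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    wd <- if (is_bn_param(nm)) 0 else weight_decay
    params[[nm]] <- params[[nm]] - lr * upd - lr * wd * params[[nm]]
  }
  list(params = params, opt = opt)
}

#' Train a SAC model
#'
#' Minimizes categorical cross-entropy with AdamW over the manifest's
#' training split, evaluating on the validation split after every epoch.
#' The best weights by validation accuracy are retained (strict
#' improvement), and the learning rate follows the plateau rule on
#' validation loss. Fully seeded: two runs with the same data, model and
#' configuration produce identical histories.
#'
#' @param model A [build_sac()] model (its `num_classes` must match the
#'   manifest's label set).
#' @param manifest A split manifest with non-empty `train` and `val`
#'   partitions.
#' @param config A [train_config()].
#' @param classes Ordered class labels; defaults to the sorted labels
#'   present.
#' @param images Optional preloaded tensor `(n, n, N, 3)` aligned with
#'   `manifest` rows, to skip disk reads.
#' @param verbose Print one line per epoch?
#' @return List with `model` (best weights), `final_model` (last-epoch
#'   weights), and `history` (class `sac_history`): per-epoch
#'   train/validation loss and accuracy and the learning rate.
#' @export
train_sac <- function(model, manifest, config = train_config(),
                      classes = NULL, images = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "sac_model"), inherits(config, "sac_train_config"))
  if (is.null(classes)) classes <- sort(unique(manifest$label))
  if (length(classes) != model$config$num_classes) {
    stop(sprintf("model head has %d classes but manifest has %d",
                 model$config$num_classes, length(classes)))
  }
  tr_idx <- which(manifest$split == "train")
  va_idx <- which(manifest$split == "val")
  if (!length(tr_idx)) stop("training split is empty")
  if (!length(va_idx)) stop("validation split is empty")

  n <- model$config$image_size
  if (is.null(images)) images <- load_manifest_images(manifest, n)
  y_all <- match(manifest$label, classes)

  x_tr <- images[, , tr_idx, , drop = FALSE]
  y_tr <- y_all[tr_idx]
  x_va <- images[, , va_idx, , drop = FALSE]
  y_va <- y_all[va_idx]
  N <- length(tr_idx)
  C <- length(classes)

  opt <- adamw_init(model$params)
  lr <- config$learning_rate
  best <- list(acc = -Inf, params = NULL, bn_states = NULL, epoch = NA_integer_)
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), train_acc = numeric(),
                     val_loss = numeric(), val_acc = numeric(),
                     checkpointed = logical())
  val_losses <- numeric()

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(N)
      ep_loss <- 0
      ep_hits <- 0L
      i <- 1L
      while (i <= N) {
        j <- min(i + config$batch_size - 1L, N)
        idx <- perm[i:j]
        xb <- x_tr[, , idx, , drop = FALSE]
        if (config$brightness) {
          dr <- config$brightness_delta
          for (bi in seq_along(idx)) {
            xb[, , bi, ] <- random_brightness(xb[, , bi, , drop = FALSE],
                                              c(-dr, dr))
          }
        }
        yb <- y_tr[idx]
        fw <- sac_forward(model, xb, training = TRUE)
        model$bn_states <- fw$bn_states
        loss <- cross_entropy(fw$probs, yb)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training loss at epoch %d; ", epoch),
               "try a lower learning rate")
        }
        onehot <- matrix(0, length(idx), C)
        onehot[cbind(seq_along(idx), yb)] <- 1
        dlogits <- (fw$probs - onehot) / length(idx)
        grads <- sac_backward(model, fw$cache, dlogits)
        st <- adamw_step(model$params, grads, opt, lr, config$weight_decay)
        model$params <- st$params
        opt <- st$opt
        ep_loss <- ep_loss + loss * length(idx)
        ep_hits <- ep_hits + sum(max.col(fw$probs, ties.method = "first") == yb)
        i <- j + 1L
      }
      va <- eval_tensor(model, x_va, y_va, config$batch_size)
      val_losses <- c(val_losses, va$loss)
      ck <- va$acc > best$acc
      if (ck) {
        best <- list(acc = va$acc, params = model$params,
                     bn_states = model$bn_states, epoch = epoch)
      }
      hist <- rbind(hist, data.frame(
        epoch = epoch, lr = lr,
        train_loss = ep_loss / N, train_acc = 100 * ep_hits / N,
        val_loss = va$loss, val_acc = va$acc, checkpointed = ck))
      if (verbose) {
        message(sprintf(
          "epoch %3d  lr %.2e  train loss %.4f acc %6.2f%%  val loss %.4f acc %6.2f%%%s",
          epoch, lr, ep_loss / N, 100 * ep_hits / N, va$loss, va$acc,
          if (ck) "  *" else ""))
      }
      lr <- plateau_step(val_losses, lr, config$plateau_factor,
                         config$plateau_patience, config$min_lr)
    }
  })

  best_model <- model
  if (!is.null(best$params)) {
    best_model$params <- best$params
    best_model$bn_states <- best$bn_states
  }
  class(hist) <- c("sac_history", class(hist))
  attr(hist, "best_epoch") <- best$epoch
  list(model = best_model, final_model = model, history = hist)
}

eval_tensor <- function(model, x, y_idx, batch_size = 32L) {
  probs <- predict(model, x, batch_size = batch_size)
  list(loss = cross_entropy(probs, y_idx),
       acc = 100 * mean(max.col(probs, ties.method = "first") == y_idx),
       pred = max.col(probs, ties.method = "first"))
}

#' Evaluate a model on one manifest split
#'
#' Runs inference over the records of `split` (in manifest order), takes
#' argmax predictions and produces the full classification report.
#'
#' @param model A trained `sac_model`.
#' @param manifest A split manifest.
#' @param split Which split to evaluate (`"test"` by default).
#' @param classes Ordered class labels; defaults to the sorted labels
#'   present in the manifest.
#' @param images Optional preloaded tensor aligned with `manifest` rows.
#' @return List with `predictions` (character vector in record order),
#'   `truth`, `confusion` and `report`.
#' @export
evaluate_split <- function(model, manifest, split = "test", classes = NULL,
                           images = NULL) {
  if (is.null(classes)) classes <- sort(unique(manifest$label))
  if (length(classes) != model$config$num_classes) {
    stop(sprintf("model head has %d classes but manifest has %d",
                 model$config$num_classes, length(classes)))
  }
  idx <- which(manifest$split == split)
  if (!length(idx)) stop("split '", split, "' is empty")
  if (is.null(images)) {
    images <- load_manifest_images(manifest[idx, , drop = FALSE],
                                   model$config$image_size)
  } else {
    images <- images[, , idx, , drop = FALSE]
  }
  probs <- predict(model, images)
  pred <- classes[max.col(probs, ties.method = "first")]
  truth <- manifest$label[idx]
  cm <- confusion_matrix(truth, pred, classes)
  list(predictions = pred, truth = truth, confusion = cm,
       report = classification_report(cm))
}
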
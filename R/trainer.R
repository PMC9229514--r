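# --- Adam trainer with piecewise learning-rate decay ----------------------

#' Training configuration
#'
#' Defaults follow the reference hyperparameters: Adam, initial learning rate
#' 5e-4, up to 100 epochs, piecewise schedule dropping by a factor 0.95 every
#' 5 epochs, validation every 400 iterations, mini-batches of 8. The moment
#' decay rates and stability constant are the universal Adam defaults
#' (beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8).
#'
#' @param initial_lr Initial learning rate.
#' @param max_epochs Maximum training epochs.
#' @param lr_drop_period Epochs between learning-rate drops.
#' @param lr_drop_factor Multiplicative drop factor in (0, 1].
#' @param validation_frequency Iterations between validation evaluations.
#' @param mini_batch_size Patches per gradient step.
#' @param beta1,beta2 Adam moment decay rates.
#' @param epsilon Adam stability constant.
#' @param seed Master seed for initialization, patch sampling, augmentation.
#' @param bn_momentum Running-statistics update rate for batch normalization.
#' @param verbose Print per-validation progress lines.
#' @return Object of class `train_config`.
#' @export
train_config <- function(initial_lr = 5e-4,
                         max_epochs = 100L,
                         lr_drop_period = 5L,
                         lr_drop_factor = 0.95,
                         validation_frequency = 400L,
                         mini_batch_size = 8L,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         seed = 0L,
                         bn_momentum = 0.1,
                         verbose = FALSE) {
  if (lr_drop_factor <= 0 || lr_drop_factor > 1)
    stop("`lr_drop_factor` must be in (0, 1]")
  if (initial_lr <= 0 || epsilon <= 0) stop("rates must be positive")
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1)
    stop("beta1/beta2 must be in [0, 1)")
  structure(list(initial_lr = initial_lr, max_epochs = as.integer(max_epochs),
                 lr_drop_period = as.integer(lr_drop_period),
                 lr_drop_factor = lr_drop_factor,
                 validation_frequency = as.integer(validation_frequency),
                 mini_batch_size = as.integer(mini_batch_size),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = as.integer(seed), bn_momentum = bn_momentum,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Piecewise learning-rate schedule
#'
#' `lr(e) = initial_lr * drop_factor ^ floor(e / drop_period)` for the
#' 0-based epoch index `e`: the rate is piecewise constant with drops at
#' epochs 5, 10, 15, ... under the defaults.
#'
#' @param epoch 0-based epoch index (0 = first epoch).
#' @param config A [train_config()].
#' @return Learning rate.
#' @export
#' @examples
#' lr_at_epoch(0, train_config())   # 5e-4
#' lr_at_epoch(99, train_config())  # 5e-4 * 0.95^19
lr_at_epoch <- function(epoch, config) {
  stopifnot(epoch >= 0)
  config$initial_lr * config$lr_drop_factor^(epoch %/% config$lr_drop_period)
}

#' Initialize Adam optimizer state
#'
#' @param params Named list of parameter arrays.
#' @return Adam state: zero first/second moments and step counter `t = 0`.
#' @export
adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zeros, v = zeros, t = 0L)
}

#' One Adam update step
#'
#' Updates the exponential moment aggregates
#' `m_t = beta1 * m_{t-1} + (1 - beta1) * g` and
#' `v_t = beta2 * v_{t-1} + (1 - beta2) * g^2`, then applies the
#' bias-corrected parameter update
#' `w <- w - lr * mhat / (sqrt(vhat) + epsilon)` with
#' `mhat = m_t / (1 - beta1^t)`, `vhat = v_t / (1 - beta2^t)`.
#'
#' @param state Optimizer state from [adam_init()] (or a previous step).
#' @param params Named list of parameter arrays.
#' @param grads Matching named list of gradient arrays.
#' @param lr Learning rate for this step.
#' @param config A [train_config()] supplying `beta1`, `beta2`, `epsilon`.
#' @return List with updated `state` and `params`.
#' @export
adam_step <- function(state, params, grads, lr, config = train_config()) {
  if (!identical(names(params), names(state$m)))
    stop("state and params name mismatch")
  if (!identical(names(params), names(grads)))
    stop("params and grads name mismatch")
  b1 <- config$beta1; b2 <- config$beta2; eps <- config$epsilon
  t <- state$t + 1L
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (any(!is.finite(g)))
      stop("non-finite gradient for parameter '", nm, "' at step ", t)
    if (!identical(length(g), length(params[[nm]])))
      stop("gradient shape mismatch for '", nm, "'")
    m <- b1 * state$m[[nm]] + (1 - b1) * g
    v <- b2 * state$v[[nm]] + (1 - b2) * g^2
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / c1) / (sqrt(v / c2) + eps)
  }
  state$t <- t
  list(state = state, params = params)
}

# Mean generalized Dice loss and mean per-patch tumor Dice (of argmax
# predictions) over a fixed patch set, from one inference-mode forward pass.
patch_set_metrics <- function(network, images, labels) {
  B <- dim(images)[5]
  probs <- forward(network, images)
  ls <- numeric(B); d <- numeric(B)
  for (b in seq_len(B)) {
    T1 <- one_hot(labels[, , , b], network$spec$num_classes)
    ls[b] <- generalized_dice_loss(probs[, , , , b], T1)
    pred <- (probs[, , , 2, b] >= probs[, , , 1, b]) * 1
    d[b] <- dsc(confusion_counts(pred, labels[, , , b]))
  }
  c(mean(ls), mean(d))
}

#' Train a 3D U-Net on volume samples
#'
#' Runs mini-batch Adam on the class-weighted generalized Dice loss with the
#' piecewise learning-rate schedule of [lr_at_epoch()]. Each epoch draws a
#' fresh random-patch plan over all training volumes (positions resampled per
#' epoch, reflection/rotation augmentation applied). Validation loss and
#' mean tumor Dice are computed on a fixed set of patches from the
#' validation volumes every `validation_frequency` iterations and at the end
#' of every epoch; the checkpoint with the best validation Dice is returned
#' alongside the final-epoch network. Training aborts with a diagnostic if
#' the loss or any gradient becomes non-finite (the best checkpoint is
#' preserved).
#'
#' @param network A [build_network()] result.
#' @param train_samples Non-empty list of preprocessed [volume_sample()]s.
#' @param val_samples List of validation samples (may be empty; validation is
#'   then skipped and the final network is the checkpoint).
#' @param config A [train_config()].
#' @param pspec A [patch_spec()] (its `batch_size` should equal
#'   `config$mini_batch_size`).
#' @param val_patches_per_volume Patches drawn once per validation volume for
#'   the fixed validation set.
#' @return List with `network` (best-validation checkpoint), `final`
#'   (final-epoch network) and `history` (data.frame: iteration, epoch, lr,
#'   train_loss, val_loss, val_dice; validation columns are `NA` on
#'   iterations where validation did not run).
#' @export
train_network <- function(network, train_samples, val_samples = list(),
                          config = train_config(),
                          pspec = patch_spec(batch_size = config$mini_batch_size),
                          val_patches_per_volume = 2L) {
  if (length(train_samples) == 0L) stop("no training samples")
  state <- adam_init(network$params)
  val <- NULL
  if (length(val_samples) > 0L) {
    vspec <- patch_spec(pspec$patch_size, val_patches_per_volume,
                        pspec$batch_size)
    pairs <- unlist(lapply(seq_along(val_samples), function(i) {
      sample_patches(val_samples[[i]], vspec, derive_seed(config$seed, 5000L + i))
    }), recursive = FALSE)
    ps <- pspec$patch_size
    C <- dim(val_samples[[1]]$image)[4]
    val <- list(images = array(0, dim = c(ps, C, length(pairs))),
                labels = array(0L, dim = c(ps, length(pairs))))
    for (b in seq_along(pairs)) {
      val$images[, , , , b] <- pairs[[b]]$image
      val$labels[, , , b] <- pairs[[b]]$label
    }
  }

  history <- list()
  iteration <- 0L
  best <- list(dice = -Inf, network = network)
  run_validation <- function(net) {
    if (is.null(val)) return(c(NA_real_, NA_real_))
    patch_set_metrics(net, val$images, val$labels)
  }

  for (epoch in seq_len(config$max_epochs)) {
    lr <- lr_at_epoch(epoch - 1L, config)
    plan <- epoch_plan(train_samples, pspec,
                       derive_seed(config$seed, 100L + epoch), augment = TRUE)
    for (chunk in plan) {
      batch <- materialize_batch(train_samples, chunk, pspec)
      res <- unet_loss_and_gradients(network, batch$images, batch$labels,
                                     bn_momentum = config$bn_momentum)
      if (!is.finite(res$loss)) {
        warning("training diverged (non-finite loss) at iteration ",
                iteration + 1L, "; aborting, best checkpoint preserved")
        return(list(network = best$network, final = network,
                    history = do.call(rbind, history)))
      }
      upd <- tryCatch(
        adam_step(state, network$params, res$grads, lr, config),
        error = function(e) e)
      if (inherits(upd, "error")) {
        warning("training diverged (", conditionMessage(upd), ") at iteration ",
                iteration + 1L, "; aborting, best checkpoint preserved")
        return(list(network = best$network, final = network,
                    history = do.call(rbind, history)))
      }
      state <- upd$state
      network$params <- upd$params
      network$bn_state <- res$bn_state
      iteration <- iteration + 1L
      val_metrics <- c(NA_real_, NA_real_)
      if (!is.null(val) &&
          (iteration %% config$validation_frequency == 0L)) {
        val_metrics <- run_validation(network)
        if (config$verbose)
          message(sprintf("iter %d (epoch %d) lr %.2e train %.4f val %.4f dice %.4f",
                          iteration, epoch, lr, res$loss,
                          val_metrics[1], val_metrics[2]))
      }
      history[[length(history) + 1L]] <- data.frame(
        iteration = iteration, epoch = epoch, lr = lr,
        train_loss = res$loss, val_loss = val_metrics[1],
        val_dice = val_metrics[2])
    }
    # end-of-epoch validation drives checkpoint selection
    if (!is.null(val)) {
      vm <- run_validation(network)
      if (vm[2] >= best$dice) best <- list(dice = vm[2], network = network)
      if (config$verbose)
        message(sprintf("epoch %d done: val loss %.4f val dice %.4f", epoch,
                        vm[1], vm[2]))
    } else {
      best <- list(dice = NA_real_, network = network)
    }
  }
  list(network = best$network, final = network,
       history = do.call(rbind, history))
}
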
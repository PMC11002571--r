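## Training (SGD with momentum, cosine-annealed learning rate, on-the-fly
## in-plane augmentation, dice + weighted BCE objective) and single-stage
## full-volume inference with probability thresholding -- no ROI cropping
## and no post-processing.

#' Training configuration
#'
#' Defaults follow the published recipe: SGD for 200 epochs, cosine
#' annealing from 0.001, loss weight lambda = 1, threshold 0.5, 50%
#' in-plane affine augmentation. Momentum and batch size are unstated in
#' the recipe; defaults 0.9 and 2.
#'
#' @param initial_lr Initial learning rate.
#' @param epochs Number of epochs.
#' @param momentum SGD momentum.
#' @param batch_size Minibatch size (gradient averaged over the batch).
#' @param lambda_bce BCE weight in the loss.
#' @param threshold Probability threshold for binarization, in (0, 1).
#' @param seed RNG seed controlling initialization order, shuffling and
#'   augmentation draws.
#' @param augment An [augment_config()]; `NULL` disables augmentation.
#' @param smooth_eps Dice smoothing term.
#' @param init_head_prior Before the first epoch, set the head bias to the
#'   log-odds of the training foreground fraction. With a strongly
#'   imbalanced foreground a zero-initialized head starts the optimization
#'   in a regime where background dominates both loss terms and the
#'   logistic output can saturate toward empty predictions; prior
#'   initialization starts it at the base rate instead.
#' @return A `train_config` list.
#' @export
train_config <- function(initial_lr = 0.001, epochs = 200L, momentum = 0.9,
                         batch_size = 2L, lambda_bce = 1, threshold = 0.5,
                         seed = 42L, augment = augment_config(),
                         smooth_eps = 1e-5, init_head_prior = TRUE) {
  stopifnot(initial_lr > 0, epochs >= 0, momentum >= 0, momentum < 1,
            batch_size >= 1, threshold > 0, threshold < 1)
  structure(list(initial_lr = initial_lr, epochs = as.integer(epochs),
                 momentum = momentum, batch_size = as.integer(batch_size),
                 lambda_bce = lambda_bce, threshold = threshold,
                 seed = as.integer(seed), augment = augment,
                 smooth_eps = smooth_eps,
                 init_head_prior = isTRUE(init_head_prior)),
            class = "train_config")
}

#' Cosine annealing schedule
#'
#' `lr0 * 0.5 * (1 + cos(pi * epoch / total))`: starts at `lr0`, reaches
#' `lr0/2` halfway and 0 at `epoch == total`.
#'
#' @param epoch 0-based epoch index, `0 <= epoch <= total`.
#' @param total Total number of epochs, >= 1.
#' @param lr0 Initial learning rate.
#' @return The learning rate for that epoch.
#' @export
cosine_lr <- function(epoch, total, lr0) {
  stopifnot(total >= 1)
  if (any(epoch < 0) || any(epoch > total)) stop("epoch out of [0, total]")
  lr0 * 0.5 * (1 + cos(pi * epoch / total))
}

get_weights <- function(net) lapply(all_layers(net), function(l) l$params)

set_weights <- function(net, weights) {
  layers <- all_layers(net)
  stopifnot(length(layers) == length(weights))
  for (i in seq_along(layers)) layers[[i]]$params <- weights[[i]]
  invisible(net)
}

zero_grads <- function(net) {
  for (l in all_layers(net)) l$grads <- lapply(l$params, function(p) p * 0)
}

sgd_step <- function(net, lr, momentum, scale = 1) {
  for (l in all_layers(net)) {
    if (is.null(l$vel)) l$vel <- lapply(l$params, function(p) p * 0)
    for (nm in names(l$params)) {
      l$vel[[nm]] <- momentum * l$vel[[nm]] - lr * scale * l$grads[[nm]]
      l$params[[nm]] <- l$params[[nm]] + l$vel[[nm]]
    }
  }
}

## Normalize and pad one volume/mask pair for the network grid.
prep_pair <- function(vol, mask) {
  x <- normalize_volume(vol_data(vol))
  px <- pad_to_multiple(x, 16L)
  out <- list(x = px$vol, record = px$record)
  if (!is.null(mask)) {
    m <- mask_data(mask)
    out$y <- pad_to_multiple(m, 16L, fill = 0)$vol
  }
  out
}

#' Train a network
#'
#' Mini-batch SGD on the combined dice + weighted BCE loss with on-the-fly
#' in-plane affine augmentation and a cosine-annealed learning rate.
#' Deterministic given `(cfg$seed, data, config)` under a fixed thread
#' policy. Aborts with a diagnostic if the loss turns non-finite.
#'
#' @param net A [build_usformer()] network (modified in place).
#' @param train_set List of `list(vol=, mask=)` pairs.
#' @param val_set Optional list of validation pairs; the per-epoch
#'   validation dice is recorded and, when `restore_best`, the weights of
#'   the best-validation-dice epoch are restored at the end.
#' @param cfg A [train_config()].
#' @param restore_best Keep the best-validation checkpoint (requires
#'   `val_set`).
#' @param verbose Print a line per epoch.
#' @return List with `net` and `history` (data frame: epoch, loss, lr,
#'   val_dice).
#' @export
fit <- function(net, train_set, val_set = NULL, cfg = train_config(),
                restore_best = !is.null(val_set), verbose = FALSE) {
  stopifnot(length(train_set) >= 1)
  set.seed(cfg$seed)
  loss_cfg <- loss_config(cfg$lambda_bce, cfg$smooth_eps)
  prepped <- lapply(train_set, function(p) prep_pair(p$vol, p$mask))
  prepped_val <- lapply(val_set %||% list(),
                        function(p) list(pr = prep_pair(p$vol, p$mask)))
  n <- length(prepped)
  history <- data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
                        val_dice = numeric())
  best <- list(dice = -Inf, weights = NULL)

  if (cfg$init_head_prior && cfg$epochs > 0) {
    fg <- mean(vapply(prepped, function(p) mean(p$y), numeric(1)))
    fg <- min(max(fg, 1e-4), 0.5)
    head_l <- net$seg$head[[length(net$seg$head)]]
    if (!is.null(head_l$params$b)) head_l$params$b[] <- stats::qlogis(fg)
  }

  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch - 1, cfg$epochs, cfg$initial_lr)
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (batch in batches) {
      zero_grads(net)
      for (i in batch) {
        x <- prepped[[i]]$x
        y <- prepped[[i]]$y
        if (!is.null(cfg$augment) && cfg$augment$prob > 0) {
          aug <- apply_inplane_affine(x, y, sample_affine(cfg$augment))
          x <- aug$vol
          y <- aug$mask
        }
        dims <- dim(x)
        p <- usformer_forward(net, matrix(as.numeric(x), ncol = 1L), dims,
                              training = TRUE)
        l <- seg_loss(p, as.numeric(y), loss_cfg)
        if (!is.finite(l))
          stop(sprintf("training diverged: non-finite loss at epoch %d (lr %.2g)",
                       epoch, lr))
        ep_loss <- ep_loss + l
        usformer_backward(net, seg_loss_grad_logits(p, as.numeric(y), loss_cfg))
      }
      sgd_step(net, lr, cfg$momentum, scale = 1 / length(batch))
    }
    ep_loss <- ep_loss / n

    val_dice <- NA_real_
    if (length(prepped_val) > 0) {
      dices <- vapply(prepped_val, function(v) {
        pr <- v$pr
        p <- usformer_forward(net, matrix(as.numeric(pr$x), ncol = 1L),
                              dim(pr$x))
        dice3d(array((p > cfg$threshold) * 1L, dim(pr$x)),
               array(pr$y, dim(pr$x)))
      }, numeric(1))
      val_dice <- mean(dices)
      if (restore_best && val_dice > best$dice) {
        best <- list(dice = val_dice, weights = get_weights(net))
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss,
                                         lr = lr, val_dice = val_dice))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  lr %.5f  val dice %s",
                      epoch, ep_loss, lr,
                      ifelse(is.na(val_dice), "-", sprintf("%.4f", val_dice))))
  }
  if (restore_best && !is.null(best$weights)) set_weights(net, best$weights)
  clear_cache(all_layers(net))
  list(net = net, history = history)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-voxel probability map for a volume
#'
#' Normalizes (per-volume z-score), pads to a 16-divisible grid, runs one
#' forward pass and crops back -- single-stage full-volume inference.
#'
#' @param net A trained `usformer_net`.
#' @param vol A [volume3d()] or 3D array.
#' @return 3D array of probabilities, same shape as the input.
#' @export
predict_prob <- function(net, vol) {
  pr <- prep_pair(vol, NULL)
  dims <- dim(pr$x)
  p <- usformer_forward(net, matrix(as.numeric(pr$x), ncol = 1L), dims)
  crop_by_record(array(p, dims), pr$record)
}

#' Segment a volume
#'
#' Thresholds the probability map: voxels strictly exceeding `threshold`
#' are foreground. No post-processing is applied.
#'
#' @inheritParams predict_prob
#' @param threshold Probability threshold in (0, 1); 0.5 by default.
#' @return A [label_mask()] on the input grid.
#' @export
predict_mask <- function(net, vol, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  p <- predict_prob(net, vol)
  spacing <- if (inherits(vol, "volume3d")) vol$spacing else c(1, 1, 1)
  label_mask((p > threshold) * 1L, spacing = spacing)
}

#' Training-set-size sweep
#'
#' For each size, draws that many scans from the pool at random, trains a
#' fresh network from scratch and evaluates mean test dice; repeated
#' `replicates` times with distinct derived seeds and averaged.
#'
#' @param pool List of `list(vol=, mask=)` training candidates.
#' @param sizes Integer vector of training-set sizes (each <= pool size).
#' @param replicates Number of repeats per size.
#' @param test_set Fixed list of test pairs.
#' @param net_cfg A [usformer_config()] for the fresh networks.
#' @param cfg A [train_config()]; its seed anchors all derived seeds.
#' @return Data frame with one row per size: `size`, `mean_dice`.
#' @export
learning_curve <- function(pool, sizes, replicates, test_set,
                           net_cfg = usformer_config(), cfg = train_config()) {
  stopifnot(all(sizes <= length(pool)), replicates >= 1)
  rows <- lapply(sizes, function(s) {
    reps <- vapply(seq_len(replicates), function(r) {
      dseed <- cfg$seed + 7919L * r + s
      set.seed(dseed)
      idx <- sample.int(length(pool), s)
      net <- build_usformer(net_cfg)
      cfg_r <- cfg
      cfg_r$seed <- dseed
      fit(net, pool[idx], cfg = cfg_r)
      mean(vapply(test_set, function(p) {
        dice3d(predict_mask(net, p$vol, cfg$threshold), p$mask)
      }, numeric(1)))
    }, numeric(1))
    data.frame(size = s, mean_dice = mean(reps))
  })
  do.call(rbind, rows)
}

#' Save / load a self-describing checkpoint
#'
#' The checkpoint carries the architecture config, all weights, the
#' training config and seed, so the network can be reconstructed exactly.
#'
#' @param net A `usformer_net`.
#' @param path Destination file.
#' @param train_cfg Optional [train_config()] to embed.
#' @export
save_checkpoint <- function(net, path, train_cfg = NULL) {
  saveRDS(list(cfg = net$cfg, weights = get_weights(net),
               train_cfg = train_cfg), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()`: list with `net` and `train_cfg`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_usformer(do.call(usformer_config, unclass(ck$cfg)))
  set_weights(net, ck$weights)
  list(net = net, train_cfg = ck$train_cfg)
}
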
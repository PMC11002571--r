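## Training objective: soft dice loss plus lambda-weighted binary
## cross-entropy. The dice term is area-based and insensitive to the amount
## of background, countering the strong class imbalance of atrial
## segmentation; the BCE term stabilizes optimization when the foreground
## is small. Total loss: L = L_dice + lambda * L_bce.

#' Loss configuration
#'
#' @param lambda_bce Non-negative weight of the BCE term. The published
#'   sweep over c(0, 0.1, 0.5, 0.9, 1, 10, 100) selected 1.
#' @param smooth_eps Small positive smoothing added to the dice numerator
#'   and denominator so empty masks are well defined.
#' @return A `loss_config` list.
#' @export
loss_config <- function(lambda_bce = 1, smooth_eps = 1e-5) {
  stopifnot(lambda_bce >= 0, smooth_eps > 0)
  structure(list(lambda_bce = lambda_bce, smooth_eps = smooth_eps),
            class = "loss_config")
}

check_same_shape <- function(pred, truth) {
  dp <- dim(pred)
  dt <- dim(truth)
  mismatch <- length(pred) != length(truth) ||
    (length(dp) == 3L && length(dt) == 3L && !identical(dp, dt))
  if (mismatch)
    stop("prediction and truth are not aligned: ",
         paste(if (is.null(dp)) length(pred) else dp, collapse = "x"), " vs ",
         paste(if (is.null(dt)) length(truth) else dt, collapse = "x"))
}

#' Soft dice loss
#'
#' `1 - (2*sum(Y*Yhat) + eps) / (sum(Y) + sum(Yhat) + eps)` over all voxels.
#'
#' @param pred Probabilities in \[0, 1\] (array or vector).
#' @param truth Binary ground truth of the same shape.
#' @param smooth_eps Smoothing term.
#' @return Loss in \[0, 1\].
#' @export
soft_dice_loss <- function(pred, truth, smooth_eps = 1e-5) {
  check_same_shape(pred, truth)
  p <- as.numeric(pred)
  y <- as.numeric(truth)
  1 - (2 * sum(p * y) + smooth_eps) / (sum(p) + sum(y) + smooth_eps)
}

#' Binary cross-entropy loss
#'
#' Mean over voxels of `-(Y log Yhat + (1-Y) log(1-Yhat))`, with
#' probabilities clamped away from 0 and 1.
#'
#' @inheritParams soft_dice_loss
#' @param clamp_eps Clamping bound for the probabilities.
#' @return Non-negative mean cross-entropy.
#' @export
bce_loss <- function(pred, truth, clamp_eps = 1e-7) {
  check_same_shape(pred, truth)
  p <- pmin(pmax(as.numeric(pred), clamp_eps), 1 - clamp_eps)
  y <- as.numeric(truth)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Combined segmentation loss
#'
#' @inheritParams soft_dice_loss
#' @param cfg A [loss_config()].
#' @return `soft_dice_loss + lambda_bce * bce_loss`.
#' @export
seg_loss <- function(pred, truth, cfg = loss_config()) {
  soft_dice_loss(pred, truth, cfg$smooth_eps) +
    cfg$lambda_bce * bce_loss(pred, truth)
}

## Gradient of seg_loss w.r.t. the head logits z (pred = plogis(z)),
## composed analytically for numerical stability:
##   dBCE/dz = (p - y) / n
##   dDice/dz = dDice/dp * p(1-p)
seg_loss_grad_logits <- function(pred, truth, cfg = loss_config()) {
  p <- as.numeric(pred)
  y <- as.numeric(truth)
  n <- length(p)
  eps <- cfg$smooth_eps
  num <- 2 * sum(p * y) + eps
  den <- sum(p) + sum(y) + eps
  ddice_dp <- -(2 * y * den - num) / den^2
  g <- ddice_dp * p * (1 - p) + cfg$lambda_bce * (p - y) / n
  matrix(g, ncol = 1L)
}
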
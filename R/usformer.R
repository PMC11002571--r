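## The Usformer architecture: a U-shaped 3D encoder-decoder whose three
## shallow encoder stages are convolutional and whose two deepest stages
## (encoder level 4 and the bottleneck) are transformer stages built on
## transposed (channel-wise) attention. The decoder mirrors the encoder
## with transposed-convolution upsampling and skip connections; a 1x1x1
## head plus logistic squashing yields a per-voxel probability map.

#' Architecture configuration
#'
#' Hyperparameters of the Usformer network. The defaults reproduce the
#' published configuration: channel widths 16/32/64/128/256, 3x3x3
#' convolution kernels, 2x2x2 max pooling, two convolutions per encoder
#' stage and a lightweight single-convolution decoder.
#'
#' @param channels Integer vector of length 5: feature channels C1..C5 at
#'   the five resolution levels.
#' @param conv_kernel Odd integer, cubic convolution kernel size.
#' @param pool_kernel Pooling kernel/stride (only 2 is supported).
#' @param convs_per_stage Convolutions per encoder stage.
#' @param decoder_convs_per_stage Convolutions per decoder stage.
#' @param ffn_expansion Hidden-width multiplier of the transformer
#'   feed-forward network.
#' @param attention_heads Number of attention heads (only 1 is supported).
#' @param in_channels,out_channels Input and output channel counts.
#' @return An object of class `usformer_config`.
#' @export
usformer_config <- function(channels = c(16L, 32L, 64L, 128L, 256L),
                            conv_kernel = 3L, pool_kernel = 2L,
                            convs_per_stage = 2L, decoder_convs_per_stage = 1L,
                            ffn_expansion = 2, attention_heads = 1L,
                            in_channels = 1L, out_channels = 1L) {
  if (length(channels) != 5L || any(channels < 1))
    stop("`channels` must be five positive integers (C1..C5)")
  if (conv_kernel %% 2 != 1) stop("`conv_kernel` must be odd")
  if (pool_kernel != 2L) stop("only 2x2x2 pooling is supported")
  if (attention_heads != 1L) stop("only single-head attention is supported")
  if (ffn_expansion <= 0) stop("`ffn_expansion` must be positive")
  structure(list(
    channels = as.integer(channels), conv_kernel = as.integer(conv_kernel),
    pool_kernel = 2L, convs_per_stage = as.integer(convs_per_stage),
    decoder_convs_per_stage = as.integer(decoder_convs_per_stage),
    ffn_expansion = ffn_expansion, attention_heads = 1L,
    in_channels = as.integer(in_channels), out_channels = as.integer(out_channels)
  ), class = "usformer_config")
}

ffn_hidden <- function(cfg, C) as.integer(ceiling(cfg$ffn_expansion * C))

conv_block <- function(cin, cout, k, n_convs) {
  layers <- list()
  for (i in seq_len(n_convs)) {
    layers <- c(layers, list(
      layer_conv3(if (i == 1) cin else cout, cout, k),
      layer_inorm(cout), layer_relu()
    ))
  }
  layers
}

transformer_block_layers <- function(C, hidden) {
  list(
    ln1 = layer_lnorm(C),
    attn = layer_attn(C),
    ln2 = layer_lnorm(C),
    ffn1 = layer_conv3(C, hidden, k = 1),
    ffn_relu = layer_relu(),
    ffn2 = layer_conv3(hidden, C, k = 1)
  )
}

#' Build a Usformer network
#'
#' Instantiates all trainable layers. Weight initialization draws from the
#' current R random stream, so `set.seed()` beforehand makes the build
#' reproducible.
#'
#' @param cfg A [usformer_config()].
#' @return An object of class `usformer_net`.
#' @export
build_usformer <- function(cfg = usformer_config()) {
  C <- cfg$channels
  k <- cfg$conv_kernel
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$seg <- list(
    enc1 = conv_block(cfg$in_channels, C[1], k, cfg$convs_per_stage),
    enc1_pool = list(layer_maxpool()),
    enc2 = conv_block(C[1], C[2], k, cfg$convs_per_stage),
    enc2_pool = list(layer_maxpool()),
    enc3 = conv_block(C[2], C[3], k, cfg$convs_per_stage),
    enc3_pool = list(layer_maxpool()),
    enc4_lift = conv_block(C[3], C[4], k, 1L),
    enc4_tf = transformer_block_layers(C[4], ffn_hidden(cfg, C[4])),
    enc4_conv = conv_block(C[4], C[4], k, 1L),
    enc4_pool = list(layer_maxpool()),
    bneck_lift = conv_block(C[4], C[5], k, 1L),
    bneck_tf = transformer_block_layers(C[5], ffn_hidden(cfg, C[5])),
    bneck_conv = conv_block(C[5], C[5], k, 1L),
    bneck_up = list(layer_tconv(C[5], C[4])),
    dec4 = conv_block(2L * C[4], C[4], k, cfg$decoder_convs_per_stage),
    dec4_up = list(layer_tconv(C[4], C[3])),
    dec3 = conv_block(2L * C[3], C[3], k, cfg$decoder_convs_per_stage),
    dec3_up = list(layer_tconv(C[3], C[2])),
    dec2 = conv_block(2L * C[2], C[2], k, cfg$decoder_convs_per_stage),
    dec2_up = list(layer_tconv(C[2], C[1])),
    dec1 = conv_block(2L * C[1], C[1], k, cfg$decoder_convs_per_stage),
    head = list(layer_conv3(C[1], cfg$out_channels, k = 1))
  )
  class(net) <- "usformer_net"
  net
}

all_layers <- function(net) unlist(net$seg, recursive = FALSE, use.names = TRUE)

seq_forward <- function(layers, x, dims, training = FALSE) {
  for (l in layers) {
    r <- layer_forward(l, x, dims, training)
    x <- r$x
    dims <- r$dims
  }
  list(x = x, dims = dims)
}

seq_backward <- function(layers, dy) {
  for (l in rev(layers)) dy <- layer_backward(l, dy)
  dy
}

## Transformer block: pre-norm residual wiring
##   y = x + Attn(LN1(x));  z = y + FFN(LN2(y))
tf_forward <- function(b, x, dims, training = FALSE) {
  u <- layer_forward(b$ln1, x, dims, training)$x
  a <- layer_forward(b$attn, u, dims, training)$x
  y <- x + a
  u2 <- layer_forward(b$ln2, y, dims, training)$x
  f <- seq_forward(list(b$ffn1, b$ffn_relu, b$ffn2), u2, dims, training)$x
  list(x = y + f, dims = dims)
}

tf_backward <- function(b, dz) {
  du2 <- seq_backward(list(b$ffn1, b$ffn_relu, b$ffn2), dz)
  dy <- dz + layer_backward(b$ln2, du2)
  du <- layer_backward(b$attn, dy)
  dy + layer_backward(b$ln1, du)
}

#' Forward pass of the network
#'
#' @param net A [build_usformer()] network.
#' @param x Input as an `n x in_channels` matrix (or H x W x Z array for a
#'   single channel); all grid dimensions must be divisible by 16.
#' @param dims Integer grid dims `c(H, W, Z)` (taken from the array if
#'   `x` is one).
#' @param training Keep activation caches for a subsequent backward pass.
#' @return `n x out_channels` matrix of probabilities in \[0, 1\].
#' @export
usformer_forward <- function(net, x, dims = NULL, training = FALSE) {
  if (is.array(x) && length(dim(x)) == 3L) {
    dims <- dim(x)
    x <- matrix(as.vector(x), ncol = 1L)
  }
  dims <- as.integer(dims)
  if (any(dims %% 16L != 0L))
    stop("input dims must be divisible by 16 (four 2x2x2 poolings); got ",
         paste(dims, collapse = "x"))
  s <- net$seg
  e1 <- seq_forward(s$enc1, x, dims, training)
  p1 <- seq_forward(s$enc1_pool, e1$x, e1$dims, training)
  e2 <- seq_forward(s$enc2, p1$x, p1$dims, training)
  p2 <- seq_forward(s$enc2_pool, e2$x, e2$dims, training)
  e3 <- seq_forward(s$enc3, p2$x, p2$dims, training)
  p3 <- seq_forward(s$enc3_pool, e3$x, e3$dims, training)
  l4 <- seq_forward(s$enc4_lift, p3$x, p3$dims, training)
  t4 <- tf_forward(s$enc4_tf, l4$x, l4$dims, training)
  e4 <- seq_forward(s$enc4_conv, t4$x, t4$dims, training)
  p4 <- seq_forward(s$enc4_pool, e4$x, e4$dims, training)
  l5 <- seq_forward(s$bneck_lift, p4$x, p4$dims, training)
  t5 <- tf_forward(s$bneck_tf, l5$x, l5$dims, training)
  b5 <- seq_forward(s$bneck_conv, t5$x, t5$dims, training)
  u4 <- seq_forward(s$bneck_up, b5$x, b5$dims, training)
  d4 <- seq_forward(s$dec4, cbind(u4$x, e4$x), u4$dims, training)
  u3 <- seq_forward(s$dec4_up, d4$x, d4$dims, training)
  d3 <- seq_forward(s$dec3, cbind(u3$x, e3$x), u3$dims, training)
  u2 <- seq_forward(s$dec3_up, d3$x, d3$dims, training)
  d2 <- seq_forward(s$dec2, cbind(u2$x, e2$x), u2$dims, training)
  u1 <- seq_forward(s$dec2_up, d2$x, d2$dims, training)
  d1 <- seq_forward(s$dec1, cbind(u1$x, e1$x), u1$dims, training)
  z <- seq_forward(s$head, d1$x, d1$dims, training)$x
  if (training) net$logits <- z
  stats::plogis(z)
}

## Backward pass from the gradient w.r.t. the head logits. Requires a prior
## training-mode forward. Accumulates into every layer's $grads.
usformer_backward <- function(net, dlogits) {
  s <- net$seg
  split2 <- function(d, C) list(d[, seq_len(C), drop = FALSE],
                                d[, C + seq_len(ncol(d) - C), drop = FALSE])
  C <- net$cfg$channels
  dd1 <- seq_backward(s$head, dlogits)
  dcat1 <- seq_backward(s$dec1, dd1)
  sp1 <- split2(dcat1, C[1])
  dd2 <- seq_backward(s$dec2_up, sp1[[1]])
  dcat2 <- seq_backward(s$dec2, dd2)
  sp2 <- split2(dcat2, C[2])
  dd3 <- seq_backward(s$dec3_up, sp2[[1]])
  dcat3 <- seq_backward(s$dec3, dd3)
  sp3 <- split2(dcat3, C[3])
  dd4 <- seq_backward(s$dec4_up, sp3[[1]])
  dcat4 <- seq_backward(s$dec4, dd4)
  sp4 <- split2(dcat4, C[4])
  db5 <- seq_backward(s$bneck_up, sp4[[1]])
  dt5 <- seq_backward(s$bneck_conv, db5)
  dl5 <- tf_backward(s$bneck_tf, dt5)
  dp4 <- seq_backward(s$bneck_lift, dl5)
  de4 <- seq_backward(s$enc4_pool, dp4) + sp4[[2]]
  dt4 <- seq_backward(s$enc4_conv, de4)
  dl4 <- tf_backward(s$enc4_tf, dt4)
  dp3 <- seq_backward(s$enc4_lift, dl4)
  de3 <- seq_backward(s$enc3_pool, dp3) + sp3[[2]]
  dp2 <- seq_backward(s$enc3, de3)
  de2 <- seq_backward(s$enc2_pool, dp2) + sp2[[2]]
  dp1 <- seq_backward(s$enc2, de2)
  de1 <- seq_backward(s$enc1_pool, dp1) + sp1[[2]]
  invisible(seq_backward(s$enc1, de1))
}

#' Count trainable parameters
#'
#' @param net A `usformer_net`.
#' @return Exact number of trainable scalars.
#' @export
count_parameters <- function(net) {
  sum(vapply(all_layers(net), layer_n_params, numeric(1)))
}

#' Transposed (channel-wise) attention
#'
#' Functional form of the attention operator used in the transformer
#' stages. The input is layer-normalized across channels, projected to
#' Q, K, V by bias-free 1x1x1 convolutions (channel-mixing matrices), and
#' aggregated as `A = V %*% softmax(t(K) %*% Q)` where the softmax is taken
#' column-wise over the C x C score matrix, so each output channel is a
#' convex combination of V's channels. No n x n spatial attention matrix is
#' ever formed. The residual input is added back by default.
#'
#' @param x Feature grid: H x W x Z x C array, or n x C matrix.
#' @param Wq,Wk,Wv C x C projection matrices (bias-free).
#' @param layer_norm Apply channel layer normalization first.
#' @param residual Add `x` to the attention output.
#' @param eps Layer-norm stabilizer.
#' @return Same shape as `x`, with attributes `scores` (the C x C
#'   softmax-normalized score matrix) and `score_dim`.
#' @export
transposed_attention <- function(x, Wq, Wk, Wv, layer_norm = TRUE,
                                 residual = TRUE, eps = 1e-5) {
  arr <- is.array(x) && length(dim(x)) == 4L
  X <- if (arr) matrix(x, ncol = dim(x)[4]) else as.matrix(x)
  C <- ncol(X)
  stopifnot(nrow(X) >= 1, C >= 1,
            all(dim(Wq) == C), all(dim(Wk) == C), all(dim(Wv) == C))
  U <- if (layer_norm) {
    mu <- rowMeans(X)
    xc <- X - mu
    (xc) / sqrt(rowMeans(xc * xc) + eps)
  } else X
  Q <- U %*% Wq
  K <- U %*% Wk
  V <- U %*% Wv
  S <- softmax_cols(crossprod(K, Q))
  A <- V %*% S
  out <- if (residual) X + A else A
  if (arr) out <- array(out, dim(x))
  attr(out, "scores") <- S
  attr(out, "score_dim") <- dim(S)
  out
}

#' Analytic FLOP count of the transposed-attention module
#'
#' Counts multiply-accumulates (x2) of the Q/K/V projections, the C x C
#' score product, the value aggregation, and optionally the output
#' projection: linear in the voxel count `n` and quadratic in the channel
#' count `C` -- the complexity advantage over spatial attention, which is
#' quadratic in `n`.
#'
#' @param n Number of voxels of the feature grid.
#' @param C Number of channels.
#' @param output_proj Include the output projection.
#' @return FLOPs (a real number).
#' @export
attention_flops <- function(n, C, output_proj = TRUE) {
  2 * n * C^2 * (3 + 1 + 1 + as.numeric(output_proj))
}

## Per-layer analytic table of output grids, parameters and FLOPs for the
## default stage layout; the basis of estimate_flops() and the summary.
usformer_layout <- function(cfg, input_shape) {
  C <- cfg$channels
  k <- cfg$conv_kernel
  d <- as.integer(input_shape)
  rows <- list()
  add <- function(stage, what, params, flops, dims) {
    rows[[length(rows) + 1]] <<- data.frame(
      stage = stage, layer = what, params = params, flops = flops,
      out_shape = paste(dims, collapse = "x"), stringsAsFactors = FALSE)
  }
  conv_entry <- function(stage, cin, cout, kk, n, dims, n_convs = 1L) {
    for (i in seq_len(n_convs)) {
      ci <- if (i == 1) cin else cout
      add(stage, sprintf("conv%dx%dx%d %d->%d", kk, kk, kk, ci, cout),
          kk^3 * ci * cout + cout, 2 * kk^3 * ci * cout * n, dims)
      add(stage, "inorm", 2 * cout, 6 * n * cout, dims)
      add(stage, "relu", 0, n * cout, dims)
    }
  }
  tf_entry <- function(stage, Cc, n, dims) {
    h <- ffn_hidden(cfg, Cc)
    add(stage, "lnorm", 2 * Cc, 6 * n * Cc, dims)
    add(stage, sprintf("transposed-attn C=%d", Cc), 4 * Cc^2,
        attention_flops(n, Cc), dims)
    add(stage, "lnorm", 2 * Cc, 6 * n * Cc, dims)
    add(stage, sprintf("ffn %d->%d->%d", Cc, h, Cc),
        Cc * h + h + h * Cc + Cc, 2 * n * Cc * h * 2 + n * h, dims)
  }
  pool_entry <- function(stage, Cc, dims) {
    dims2 <- dims %/% 2L
    add(stage, "maxpool2x2x2", 0, 8 * prod(dims2) * Cc, dims2)
    dims2
  }
  up_entry <- function(stage, cin, cout, n, dims) {
    add(stage, sprintf("tconv2x2x2 %d->%d", cin, cout),
        8 * cin * cout + cout, 2 * 8 * cin * cout * n, dims * 2L)
    dims * 2L
  }

  conv_entry("enc1", cfg$in_channels, C[1], k, prod(d), d, cfg$convs_per_stage)
  d <- pool_entry("enc1", C[1], d)
  conv_entry("enc2", C[1], C[2], k, prod(d), d, cfg$convs_per_stage)
  d <- pool_entry("enc2", C[2], d)
  conv_entry("enc3", C[2], C[3], k, prod(d), d, cfg$convs_per_stage)
  d <- pool_entry("enc3", C[3], d)
  conv_entry("enc4", C[3], C[4], k, prod(d), d)
  tf_entry("enc4", C[4], prod(d), d)
  conv_entry("enc4", C[4], C[4], k, prod(d), d)
  d4 <- d
  d <- pool_entry("enc4", C[4], d)
  conv_entry("bneck", C[4], C[5], k, prod(d), d)
  tf_entry("bneck", C[5], prod(d), d)
  conv_entry("bneck", C[5], C[5], k, prod(d), d)
  d <- up_entry("bneck", C[5], C[4], prod(d), d)
  conv_entry("dec4", 2L * C[4], C[4], k, prod(d), d, cfg$decoder_convs_per_stage)
  d <- up_entry("dec4", C[4], C[3], prod(d), d)
  conv_entry("dec3", 2L * C[3], C[3], k, prod(d), d, cfg$decoder_convs_per_stage)
  d <- up_entry("dec3", C[3], C[2], prod(d), d)
  conv_entry("dec2", 2L * C[2], C[2], k, prod(d), d, cfg$decoder_convs_per_stage)
  d <- up_entry("dec2", C[2], C[1], prod(d), d)
  conv_entry("dec1", 2L * C[1], C[1], k, prod(d), d, cfg$decoder_convs_per_stage)
  add("head", sprintf("conv1x1x1 %d->%d", C[1], cfg$out_channels),
      C[1] * cfg$out_channels + cfg$out_channels,
      2 * C[1] * cfg$out_channels * prod(d), d)
  add("head", "sigmoid", 0, 4 * prod(d), d)
  do.call(rbind, rows)
}

#' Analytic FLOP estimate of a full forward pass
#'
#' @param cfg A [usformer_config()].
#' @param input_shape Grid dims `c(H, W, Z)`, divisible by 16.
#' @return Total FLOPs of one forward pass on that grid.
#' @export
estimate_flops <- function(cfg, input_shape) {
  stopifnot(all(as.integer(input_shape) %% 16L == 0L))
  sum(usformer_layout(cfg, input_shape)$flops)
}

#' Per-layer summary of shapes, parameters and FLOPs
#'
#' @param object A `usformer_net`.
#' @param input_shape Grid dims `c(H, W, Z)`, divisible by 16.
#' @param ... Unused.
#' @return Invisibly, the per-layer data frame.
#' @export
summary.usformer_net <- function(object, input_shape = c(96L, 96L, 48L), ...) {
  tab <- usformer_layout(object$cfg, input_shape)
  total_p <- count_parameters(object)
  stopifnot(sum(tab$params) == total_p)  # analytic table must match the net
  cat(sprintf("Usformer: channels %s, input %s\n",
              paste(object$cfg$channels, collapse = "/"),
              paste(input_shape, collapse = "x")))
  print(tab, row.names = FALSE)
  cat(sprintf("Total parameters: %d (%.3fM)\n", total_p, total_p / 1e6))
  cat(sprintf("Estimated forward FLOPs: %.2f G\n", sum(tab$flops) / 1e9))
  invisible(tab)
}
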
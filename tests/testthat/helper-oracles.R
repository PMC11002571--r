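# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, dense matrices) so they share no code
# with the implementation paths they check.

# Dense evaluation of channel attention: layer norm by explicit per-row
# arithmetic, dense C x C score matrix, column softmax by hand.
dense_attention_oracle <- function(X, Wq, Wk, Wv, layer_norm = TRUE,
                                   residual = TRUE, eps = 1e-5) {
  X <- as.matrix(X)
  C <- ncol(X)
  U <- X
  if (layer_norm) {
    for (r in seq_len(nrow(X))) {
      row <- X[r, ]
      m <- mean(row)
      U[r, ] <- (row - m) / sqrt(mean((row - m)^2) + eps)
    }
  }
  Q <- U %*% Wq
  K <- U %*% Wk
  V <- U %*% Wv
  Sraw <- t(K) %*% Q
  S <- matrix(0, C, C)
  for (j in seq_len(C)) {
    e <- exp(Sraw[, j] - max(Sraw[, j]))
    S[, j] <- e / sum(e)
  }
  A <- V %*% S
  if (residual) X + A else A
}

# Surface voxels by per-voxel neighbour checking.
surface_oracle <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (mask[i, j, k] != 1) next
    nb <- c(
      if (i > 1) mask[i - 1, j, k] else 0, if (i < d[1]) mask[i + 1, j, k] else 0,
      if (j > 1) mask[i, j - 1, k] else 0, if (j < d[2]) mask[i, j + 1, k] else 0,
      if (k > 1) mask[i, j, k - 1] else 0, if (k < d[3]) mask[i, j, k + 1] else 0
    )
    if (any(nb == 0)) out <- rbind(out, c(i, j, k))
  }
  out
}

# All-pairs directed surface distances via a dense distance matrix.
surface_dist_oracle <- function(P, G, spacing) {
  Pm <- sweep(P - 1, 2, spacing, `*`)
  Gm <- sweep(G - 1, 2, spacing, `*`)
  D <- matrix(0, nrow(Pm), nrow(Gm))
  for (a in seq_len(nrow(Pm))) for (b in seq_len(nrow(Gm)))
    D[a, b] <- sqrt(sum((Pm[a, ] - Gm[b, ])^2))
  rp <- apply(D, 1, min)
  rg <- apply(D, 2, min)
  list(hd = max(max(rp), max(rg)),
       assd = (sum(rp) + sum(rg)) / (length(rp) + length(rg)))
}

# Random non-empty blob mask (union of a few balls) on a small grid.
random_blob_mask <- function(d = c(10, 10, 8)) {
  m <- array(0L, d)
  for (b in seq_len(sample(1:3, 1))) {
    ctr <- runif(3, 2, d - 1)
    r <- runif(1, 1.5, min(d) / 2.5)
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1]))
      if (sum((c(i, j, k) - ctr)^2) <= r^2) m[i, j, k] <- 1L
  }
  if (sum(m) == 0) m[ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2)] <- 1L
  m
}

# Closed-form parameter count of the architecture, written as independent
# spreadsheet-style arithmetic (not by walking the built network).
param_count_formula <- function(C, k = 3, convs = 2, dec_convs = 1,
                                ffn_exp = 2, cin = 1, cout = 1) {
  conv_p <- function(ci, co) k^3 * ci * co + co
  block_p <- function(ci, co, n) {
    tot <- 0
    for (i in seq_len(n)) {
      tot <- tot + conv_p(if (i == 1) ci else co, co) + 2 * co  # conv + inorm
    }
    tot
  }
  tf_p <- function(Cc) {
    h <- ceiling(ffn_exp * Cc)
    2 * Cc + 4 * Cc^2 + 2 * Cc + (Cc * h + h) + (h * Cc + Cc)
  }
  tconv_p <- function(ci, co) 8 * ci * co + co
  total <- block_p(cin, C[1], convs) + block_p(C[1], C[2], convs) +
    block_p(C[2], C[3], convs) +
    block_p(C[3], C[4], 1) + tf_p(C[4]) + block_p(C[4], C[4], 1) +
    block_p(C[4], C[5], 1) + tf_p(C[5]) + block_p(C[5], C[5], 1) +
    tconv_p(C[5], C[4]) +
    block_p(2 * C[4], C[4], dec_convs) + tconv_p(C[4], C[3]) +
    block_p(2 * C[3], C[3], dec_convs) + tconv_p(C[3], C[2]) +
    block_p(2 * C[2], C[2], dec_convs) + tconv_p(C[2], C[1]) +
    block_p(2 * C[1], C[1], dec_convs) +
    (C[1] * cout + cout)
  total
}

tiny_net_cfg <- function() usformer_config(channels = c(2L, 4L, 8L, 16L, 32L))

# Small-grid phantom spec used for fast training tests.
small_phantom_spec <- function() {
  phantom_spec(grid_shape = c(32L, 32L, 16L),
               body_a = c(4, 7), body_b = c(4, 6), body_c = c(3, 5),
               tube_radius = c(0.8, 1.4), tube_length = c(5, 9))
}
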
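## Minimal trainable-layer library backing the segmentation network.
##
## A feature map is an n x C numeric matrix (n = H*W*Z voxels, column-major
## over the first array axis) travelling with its grid dims c(H, W, Z).
## Each layer is an environment holding $params, $grads and a forward cache;
## layer_forward()/layer_backward() dispatch on $type. Backward passes
## accumulate into $grads so minibatch gradients can be summed sample by
## sample before an optimizer step.

new_layer <- function(type, params = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- params
  e$grads <- lapply(params, function(p) p * 0)
  e$cache <- NULL
  class(e) <- c(paste0("usf_", type), "usf_layer")
  e
}

rnorm_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

#' @noRd
layer_conv3 <- function(cin, cout, k = 3, bias = TRUE) {
  stopifnot(k %% 2 == 1)
  fan_in <- k^3 * cin
  params <- list(W = rnorm_mat(fan_in, cout, sqrt(2 / fan_in)))
  if (bias) params$b <- numeric(cout)
  l <- new_layer("conv3", params)
  l$k <- k
  l$cin <- cin
  l$cout <- cout
  l
}

layer_tconv <- function(cin, cout) {
  params <- list(W = rnorm_mat(8 * cin, cout, sqrt(2 / cin)), b = numeric(cout))
  l <- new_layer("tconv", params)
  l$cin <- cin
  l$cout <- cout
  l
}

layer_inorm <- function(C, eps = 1e-5) {
  l <- new_layer("inorm", list(gamma = rep(1, C), beta = numeric(C)))
  l$eps <- eps
  l
}

layer_lnorm <- function(C, eps = 1e-5) {
  l <- new_layer("lnorm", list(gamma = rep(1, C), beta = numeric(C)))
  l$eps <- eps
  l
}

layer_relu <- function() new_layer("relu")

layer_maxpool <- function() new_layer("maxpool")

layer_attn <- function(C) {
  sd <- 1 / sqrt(C)
  new_layer("attn", list(
    Wq = rnorm_mat(C, C, sd), Wk = rnorm_mat(C, C, sd),
    Wv = rnorm_mat(C, C, sd), Wo = rnorm_mat(C, C, sd)
  ))
}

add_bias <- function(y, b) y + rep(b, each = nrow(y))

softmax_cols <- function(M) {
  M <- M - rep(apply(M, 2, max), each = nrow(M))
  E <- exp(M)
  E / rep(colSums(E), each = nrow(E))
}

## Output-voxel index (1-based) of each input voxel for the 8 offsets of a
## 2x2x2 stride-2 transposed convolution on a grid of dims d.
upsample_indices <- function(d) {
  H <- d[1]; W <- d[2]; Z <- d[3]
  i <- rep.int(0:(H - 1), W * Z)
  j <- rep.int(rep(0:(W - 1), each = H), Z)
  z <- rep(0:(Z - 1), each = H * W)
  idx <- vector("list", 8)
  o <- 1
  for (dz in 0:1) for (dj in 0:1) for (di in 0:1) {
    idx[[o]] <- 1 + (2 * i + di) + 2 * H * ((2 * j + dj) + 2 * W * (2 * z + dz))
    o <- o + 1
  }
  idx
}

layer_forward <- function(l, x, dims, training = FALSE) {
  n <- nrow(x)
  switch(l$type,
    conv3 = {
      if (l$k == 1) {
        y <- x %*% l$params$W
        if (!is.null(l$params$b)) y <- add_bias(y, l$params$b)
      } else {
        b <- if (is.null(l$params$b)) numeric(l$cout) else l$params$b
        y <- conv3_fwd(x, l$params$W, b, dims[1], dims[2], dims[3], l$k)
      }
      if (training) l$cache <- list(x = x, dims = dims)
      list(x = y, dims = dims)
    },
    tconv = {
      idx <- upsample_indices(dims)
      cout <- l$cout
      y <- matrix(0, 8 * n, cout)
      for (o in 1:8) {
        rows <- ((o - 1) * l$cin + 1):(o * l$cin)
        y[idx[[o]], ] <- x %*% l$params$W[rows, , drop = FALSE]
      }
      y <- add_bias(y, l$params$b)
      if (training) l$cache <- list(x = x, idx = idx)
      list(x = y, dims = dims * 2L)
    },
    inorm = {
      r <- inorm_fwd(x, l$params$gamma, l$params$beta, l$eps)
      if (training) l$cache <- list(x = x, mu = r$mu, inv_sd = r$inv_sd)
      list(x = r$y, dims = dims)
    },
    lnorm = {
      C <- ncol(x)
      mu <- rowMeans(x)
      xc <- x - mu
      v <- rowMeans(xc * xc)
      inv_sd <- 1 / sqrt(v + l$eps)
      xhat <- xc * inv_sd
      y <- xhat * rep(l$params$gamma, each = n) + rep(l$params$beta, each = n)
      if (training) l$cache <- list(xc = xc, xhat = xhat, inv_sd = inv_sd)
      list(x = y, dims = dims)
    },
    relu = {
      y <- relu_fwd(x)
      if (training) l$cache <- list(y = y)
      list(x = y, dims = dims)
    },
    maxpool = {
      stopifnot(all(dims %% 2L == 0L))
      res <- maxpool3_fwd(x, dims[1], dims[2], dims[3])
      if (training) l$cache <- list(idx = res$idx, n_in = n)
      list(x = res$y, dims = dims %/% 2L)
    },
    attn = {
      p <- l$params
      Q <- x %*% p$Wq
      K <- x %*% p$Wk
      V <- x %*% p$Wv
      S <- softmax_cols(crossprod(K, Q))   # C x C score matrix
      A <- V %*% S
      y <- A %*% p$Wo
      if (training) l$cache <- list(x = x, Q = Q, K = K, V = V, S = S, A = A)
      list(x = y, dims = dims)
    },
    stop("unknown layer type: ", l$type)
  )
}

layer_backward <- function(l, dy) {
  cc <- l$cache
  n <- nrow(dy)
  switch(l$type,
    conv3 = {
      d <- cc$dims
      if (!is.null(l$params$b)) l$grads$b <- l$grads$b + colSums(dy)
      if (l$k == 1) {
        l$grads$W <- l$grads$W + crossprod(cc$x, dy)
        dy %*% t(l$params$W)
      } else {
        l$grads$W <- l$grads$W +
          conv3_bwd_weights(cc$x, dy, d[1], d[2], d[3], l$k)
        conv3_bwd_data(dy, l$params$W, d[1], d[2], d[3], l$k, l$cin)
      }
    },
    tconv = {
      x <- cc$x
      dx <- matrix(0, nrow(x), l$cin)
      for (o in 1:8) {
        rows <- ((o - 1) * l$cin + 1):(o * l$cin)
        dyo <- dy[cc$idx[[o]], , drop = FALSE]
        l$grads$W[rows, ] <- l$grads$W[rows, ] + crossprod(x, dyo)
        dx <- dx + dyo %*% t(l$params$W[rows, , drop = FALSE])
      }
      l$grads$b <- l$grads$b + colSums(dy)
      dx
    },
    inorm = {
      r <- inorm_bwd(cc$x, dy, cc$mu, cc$inv_sd, l$params$gamma)
      l$grads$gamma <- l$grads$gamma + as.numeric(r$dgamma)
      l$grads$beta <- l$grads$beta + as.numeric(r$dbeta)
      r$dx
    },
    lnorm = {
      C <- ncol(dy)
      dxhat <- dy * rep(l$params$gamma, each = n)
      l$grads$gamma <- l$grads$gamma + colSums(dy * cc$xhat)
      l$grads$beta <- l$grads$beta + colSums(dy)
      dvar <- rowSums(dxhat * cc$xc) * (-0.5) * cc$inv_sd^3
      dmu <- -rowSums(dxhat) * cc$inv_sd
      dxhat * cc$inv_sd + cc$xc * (2 * dvar / C) + dmu / C
    },
    relu = relu_bwd(dy, cc$y),
    maxpool = maxpool3_bwd(dy, cc$idx, cc$n_in),
    attn = {
      p <- l$params
      dA <- dy %*% t(p$Wo)
      l$grads$Wo <- l$grads$Wo + crossprod(cc$A, dy)
      dV <- dA %*% t(cc$S)
      dS <- crossprod(cc$V, dA)
      # softmax backward, column-wise
      dSraw <- cc$S * (dS - rep(colSums(dS * cc$S), each = nrow(dS)))
      dQ <- cc$K %*% dSraw
      dK <- cc$Q %*% t(dSraw)
      l$grads$Wq <- l$grads$Wq + crossprod(cc$x, dQ)
      l$grads$Wk <- l$grads$Wk + crossprod(cc$x, dK)
      l$grads$Wv <- l$grads$Wv + crossprod(cc$x, dV)
      dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    },
    stop("unknown layer type: ", l$type)
  )
}

layer_n_params <- function(l) sum(vapply(l$params, length, integer(1)))

clear_cache <- function(layers) for (l in layers) l$cache <- NULL
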
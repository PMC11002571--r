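test_that("config validation catches malformed architectures", {
  expect_error(usformer_config(channels = c(16, 32, 64)), "five")
  expect_error(usformer_config(conv_kernel = 4), "odd")
  expect_error(usformer_config(attention_heads = 2), "single-head")
  cfg <- usformer_config()
  expect_equal(cfg$channels, c(16L, 32L, 64L, 128L, 256L))
})

test_that("forward pass keeps shape and yields probabilities", {
  set.seed(20)
  net <- build_usformer(tiny_net_cfg())
  x <- array(rnorm(32 * 32 * 16), c(32, 32, 16))
  p <- usformer_forward(net, x)
  expect_equal(dim(p), c(32 * 32 * 16, 1L))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(usformer_forward(net, array(rnorm(30 * 32 * 16), c(30, 32, 16))),
               "divisible by 16")
  # deterministic in evaluation mode
  expect_identical(p, usformer_forward(net, x))
})

test_that("parameter counts match single-layer closed forms", {
  l1 <- usformer:::layer_conv3(3, 5, k = 1, bias = FALSE)
  expect_equal(usformer:::layer_n_params(l1), 15)          # 1*1*1*3*5
  l2 <- usformer:::layer_conv3(1, 16, k = 3, bias = TRUE)
  expect_equal(usformer:::layer_n_params(l2), 448)         # 27*16 + 16
})

test_that("network parameter total equals an independent hand count", {
  for (ch in list(c(2, 4, 8, 16, 32), c(3, 5, 7, 9, 11), c(16, 32, 64, 128, 256))) {
    set.seed(21)
    net <- build_usformer(usformer_config(channels = ch))
    expect_equal(count_parameters(net), param_count_formula(ch))
  }
})

test_that("attention reduces to closed forms in degenerate settings", {
  set.seed(22)
  # C = 1: the 1x1 score softmax is exactly 1, so A = V
  x1 <- matrix(rnorm(20), ncol = 1)
  w1 <- matrix(1.3, 1, 1)
  a1 <- transposed_attention(x1, w1, w1, w1, layer_norm = FALSE, residual = FALSE)
  expect_equal(as.numeric(a1), as.numeric(x1 %*% w1), tolerance = 1e-12)
  expect_equal(attr(a1, "score_dim"), c(1L, 1L))

  # zero scores: uniform softmax, every output channel = mean of V channels
  x <- matrix(rnorm(24 * 3), 24, 3)
  a0 <- transposed_attention(x, Wq = matrix(0, 3, 3), Wk = diag(3),
                             Wv = diag(3), layer_norm = FALSE, residual = FALSE)
  expect_equal(unname(a0[, 1]), unname(rowMeans(x)), tolerance = 1e-12)
  expect_equal(unname(a0[, 2]), unname(rowMeans(x)), tolerance = 1e-12)
})

test_that("attention matches the dense brute-force oracle", {
  set.seed(23)
  x <- matrix(rnorm(24 * 3), 24, 3)
  Wq <- matrix(rnorm(9), 3); Wk <- matrix(rnorm(9), 3); Wv <- matrix(rnorm(9), 3)
  got <- transposed_attention(x, Wq, Wk, Wv)
  want <- dense_attention_oracle(x, Wq, Wk, Wv)
  expect_equal(unclass(got), want, tolerance = 1e-6, ignore_attr = TRUE)
  S <- attr(got, "scores")
  expect_equal(dim(S), c(3L, 3L))
  expect_equal(colSums(S), rep(1, 3), tolerance = 1e-6, ignore_attr = TRUE)
  # array-in, array-out
  xa <- array(rnorm(4 * 3 * 2 * 3), c(4, 3, 2, 3))
  ga <- transposed_attention(xa, Wq, Wk, Wv)
  expect_equal(dim(ga), dim(xa))
})

test_that("attention never materializes an n x n matrix", {
  # at n = 40960 an n x n score matrix would need ~13 GB; success here plus
  # the C x C score attribute demonstrates the channel-wise formulation
  set.seed(24)
  n <- 40960
  x <- matrix(rnorm(n * 4), n, 4)
  W <- matrix(rnorm(16), 4)
  out <- transposed_attention(x, W, W, W)
  expect_equal(attr(out, "score_dim"), c(4L, 4L))
  expect_equal(dim(out), c(n, 4L))
})

test_that("transformer block is the identity under zeroed branch outputs", {
  set.seed(25)
  b <- usformer:::transformer_block_layers(4, 8)
  b$attn$params$Wo[] <- 0
  b$ffn2$params$W[] <- 0
  b$ffn2$params$b[] <- 0
  x <- matrix(rnorm(32 * 4), 32, 4)
  out <- usformer:::tf_forward(b, x, c(4, 4, 2))
  expect_equal(out$x, x, tolerance = 1e-12)
})

test_that("transformer block preserves shape and trains every parameter", {
  set.seed(26)
  for (rep in 1:10) {
    C <- sample(2:6, 1)
    d <- c(sample(2:5, 1), sample(2:5, 1), sample(2:4, 1))
    b <- usformer:::transformer_block_layers(C, 2 * C)
    x <- matrix(rnorm(prod(d) * C), prod(d), C)
    out <- usformer:::tf_forward(b, x, d, training = TRUE)
    expect_equal(dim(out$x), dim(x))
    usformer:::tf_backward(b, matrix(rnorm(prod(d) * C), prod(d), C))
    for (l in b) {
      for (nm in names(l$grads)) {
        expect_gt(sum(abs(l$grads[[nm]])), 0)
      }
    }
  }
})

test_that("analytic FLOP model has the expected scaling structure", {
  cfg <- tiny_net_cfg()
  # fully convolutional pipeline: doubling each spatial dim scales all
  # per-layer costs linearly in voxel count, i.e. by 8
  f1 <- estimate_flops(cfg, c(32, 32, 16))
  f2 <- estimate_flops(cfg, c(64, 64, 32))
  expect_equal(f2 / f1, 8, tolerance = 1e-12)
  # single-conv closed form: 2 * k^3 * cin * cout * n
  tab <- usformer:::usformer_layout(usformer_config(), c(64, 64, 32))
  first_conv <- tab$flops[1]
  expect_equal(first_conv, 2 * 27 * 1 * 16 * 64 * 64 * 32)
  # attention: linear in n at fixed C, quadratic in C at fixed n
  ns <- c(64, 128, 256, 512)
  sl_n <- coef(lm(log(attention_flops(ns, 8)) ~ log(ns)))[2]
  expect_equal(unname(sl_n), 1, tolerance = 1e-12)
  Cs <- c(4, 8, 16, 32)
  sl_c <- coef(lm(log(attention_flops(256, Cs)) ~ log(Cs)))[2]
  expect_equal(unname(sl_c), 2, tolerance = 1e-12)
})

test_that("gradients of the full network agree with finite differences", {
  set.seed(27)
  net <- build_usformer(usformer_config(channels = c(2, 3, 4, 5, 6)))
  x <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  y <- array(rbinom(16^3, 1, 0.1), c(16, 16, 16))
  lcfg <- loss_config()
  lossfun <- function() {
    seg_loss(usformer_forward(net, matrix(as.numeric(x), ncol = 1), dim(x)),
             as.numeric(y), lcfg)
  }
  usformer:::zero_grads(net)
  p <- usformer_forward(net, matrix(as.numeric(x), ncol = 1), dim(x),
                        training = TRUE)
  usformer:::usformer_backward(
    net, usformer:::seg_loss_grad_logits(p, as.numeric(y), lcfg))
  layers <- usformer:::all_layers(net)
  set.seed(28)
  picks <- sample(seq_along(layers), 10)
  for (li in picks) {
    l <- layers[[li]]
    if (length(l$params) == 0) next
    nm <- sample(names(l$params), 1)
    k <- sample(length(l$params[[nm]]), 1)
    g <- l$grads[[nm]][k]
    h <- 1e-5
    orig <- l$params[[nm]][k]
    l$params[[nm]][k] <- orig + h; f1 <- lossfun()
    l$params[[nm]][k] <- orig - h; f2 <- lossfun()
    l$params[[nm]][k] <- orig
    fd <- (f1 - f2) / (2 * h)
    expect_lt(abs(fd - g) / max(1e-6, abs(fd) + abs(g)), 1e-3)
  }
})

test_that("summary reconciles the analytic table with the built network", {
  set.seed(29)
  net <- build_usformer(tiny_net_cfg())
  tab <- withr::with_output_sink(withr::local_tempfile(), {
    summary(net, input_shape = c(32, 32, 16))
  })
  expect_equal(sum(tab$params), count_parameters(net))
  expect_equal(sum(tab$flops), estimate_flops(tiny_net_cfg(), c(32, 32, 16)))
})
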
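test_that("cosine schedule hits its closed-form landmarks", {
  expect_equal(cosine_lr(0, 200, 0.001), 0.001, tolerance = 1e-15)
  expect_equal(cosine_lr(200, 200, 0.001), 0, tolerance = 1e-15)
  expect_equal(cosine_lr(100, 200, 0.001), 0.0005, tolerance = 1e-15)
  expect_error(cosine_lr(-1, 10, 0.1), "epoch")
  expect_error(cosine_lr(11, 10, 0.1), "epoch")
})

make_small_pairs <- function(n, seed0) {
  lapply(seq_len(n), function(i) {
    ph <- generate_phantom(small_phantom_spec(), seed = seed0 + i)
    list(vol = ph$vol, mask = ph$mask)
  })
}

test_that("zero epochs leave the weights untouched", {
  set.seed(60)
  net <- build_usformer(usformer_config(channels = c(2, 3, 4, 5, 6)))
  w0 <- usformer:::get_weights(net)
  fit(net, make_small_pairs(1, 600), cfg = train_config(epochs = 0L))
  expect_identical(usformer:::get_weights(net), w0)
})

test_that("training reduces the loss and follows the schedule exactly", {
  pairs <- make_small_pairs(2, 610)
  set.seed(61)
  net <- build_usformer(usformer_config(channels = c(2, 4, 8, 16, 32)))
  cfg <- train_config(epochs = 12L, seed = 61L, batch_size = 2L,
                      initial_lr = 0.02, augment = NULL)
  res <- fit(net, pairs, cfg = cfg)
  h <- res$history
  expect_equal(nrow(h), 12)
  expect_lt(h$loss[12], h$loss[1])
  expect_equal(h$lr, cosine_lr(0:11, 12, 0.02), tolerance = 1e-15)
})

test_that("fit is bit-reproducible given seed, data and config", {
  pairs <- make_small_pairs(2, 620)
  run <- function() {
    set.seed(62)
    net <- build_usformer(usformer_config(channels = c(2, 3, 4, 5, 6)))
    fit(net, pairs, cfg = train_config(epochs = 2L, seed = 62L))
    usformer:::get_weights(net)
  }
  expect_identical(run(), run())
})

test_that("training aborts with a diagnostic when the loss turns non-finite", {
  pairs <- make_small_pairs(1, 630)
  set.seed(63)
  net <- build_usformer(usformer_config(channels = c(2, 3, 4, 5, 6)))
  net$seg$enc1[[1]]$params$W[1] <- NaN
  expect_error(fit(net, pairs, cfg = train_config(epochs = 1L, seed = 63L)),
               "non-finite|diverged")
})

test_that("prediction restores arbitrary grids and nests across thresholds", {
  set.seed(64)
  net <- build_usformer(usformer_config(channels = c(2, 3, 4, 5, 6)))
  v <- volume3d(array(rnorm(40 * 36 * 20), c(40, 36, 20)), c(1, 1, 2))
  p <- predict_prob(net, v)
  expect_equal(dim(p), c(40L, 36L, 20L))
  lo <- predict_mask(net, v, threshold = 0.05)
  hi <- predict_mask(net, v, threshold = 0.9)
  expect_true(all(lo$data[hi$data == 1] == 1))   # level sets nest
  expect_equal(lo$spacing, c(1, 1, 2))
})

test_that("a zeroed head makes the 0.5 threshold decision explicit", {
  set.seed(65)
  net <- build_usformer(usformer_config(channels = c(2, 3, 4, 5, 6)))
  head <- net$seg$head[[1]]
  head$params$W[] <- 0
  head$params$b[] <- 0
  v <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  p <- predict_prob(net, v)
  expect_true(all(abs(p - 0.5) < 1e-12))
  # plogis(0) = 0.5 does not strictly exceed 0.5 -> empty mask
  expect_equal(sum(predict_mask(net, v, 0.5)$data), 0)
  expect_equal(sum(predict_mask(net, v, 0.4)$data), 16^3)
})

test_that("checkpoints reconstruct the network exactly", {
  set.seed(66)
  net <- build_usformer(usformer_config(channels = c(2, 3, 4, 5, 6)))
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, f, train_config(epochs = 3L))
  ck <- load_checkpoint(f)
  expect_equal(usformer:::get_weights(ck$net), usformer:::get_weights(net))
  v <- array(rnorm(16^3), c(16, 16, 16))
  expect_identical(usformer_forward(ck$net, v), usformer_forward(net, v))
  expect_equal(ck$train_cfg$epochs, 3L)
})

test_that("learning_curve returns one row per size with valid dice", {
  pool <- make_small_pairs(3, 640)
  test_set <- make_small_pairs(1, 650)
  tab <- learning_curve(pool, sizes = c(1, 2), replicates = 1, test_set,
                        net_cfg = usformer_config(channels = c(2, 3, 4, 5, 6)),
                        cfg = train_config(epochs = 1L, seed = 64L))
  expect_equal(tab$size, c(1, 2))
  expect_true(all(tab$mean_dice >= 0 & tab$mean_dice <= 1))
})
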
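test_that("confusion counts are exact voxel-wise tallies", {
  m <- array(0L, c(4, 4, 4))
  m[1:10] <- 1L  # 10 foreground voxels
  expect_equal(confusion_counts(m, m), list(TP = 10L, TN = 54L, FP = 0L, FN = 0L))

  inv <- 1L - m
  cc <- confusion_counts(inv, m)
  expect_equal(cc$TP, 0L)
  expect_equal(cc$TN, 0L)

  set.seed(10)
  p <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
  t <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
  tp <- tn <- fp <- fn <- 0
  for (v in seq_len(64)) {
    if (p[v] == 1 && t[v] == 1) tp <- tp + 1
    if (p[v] == 0 && t[v] == 0) tn <- tn + 1
    if (p[v] == 1 && t[v] == 0) fp <- fp + 1
    if (p[v] == 0 && t[v] == 1) fn <- fn + 1
  }
  expect_equal(confusion_counts(p, t), list(TP = tp, TN = tn, FP = fp, FN = fn))
})

test_that("dice3d follows 2TP/(2TP+FN+FP)", {
  m <- array(0L, c(3, 3, 3)); m[1:4] <- 1L
  expect_equal(dice3d(m, m), 1)
  n <- array(0L, c(3, 3, 3)); n[10:12] <- 1L
  expect_equal(dice3d(m, n), 0)
  # TP=2, FP=1, FN=1
  a <- array(0L, c(3, 3, 3)); a[1:3] <- 1L
  b <- array(0L, c(3, 3, 3)); b[2:4] <- 1L
  expect_equal(dice3d(a, b), 4 / 6)
  expect_warning(d <- dice3d(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 2))),
                 "empty")
  expect_equal(d, 1)
  # consistency with the soft dice loss at vanishing smoothing
  expect_equal(dice3d(a, b), 1 - soft_dice_loss(a, b, smooth_eps = 1e-14),
               tolerance = 1e-9)
})

test_that("surface extraction matches the neighbour-checking oracle", {
  single <- array(0L, c(4, 4, 4)); single[2, 3, 2] <- 1L
  expect_equal(unname(surface_voxels(single)), matrix(c(2, 3, 2), 1))

  cube <- array(0L, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- 1L
  expect_equal(nrow(surface_voxels(cube)), 26)  # all but the centre

  expect_error(surface_voxels(array(0L, c(3, 3, 3))), "empty")

  set.seed(11)
  for (rep in 1:10) {
    m <- random_blob_mask(c(9, 8, 7))
    got <- surface_voxels(m)
    want <- surface_oracle(m)
    expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                 unname(want[order(want[, 1], want[, 2], want[, 3]), ,
                             drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("surface distances match examples, symmetry and mm scaling", {
  a <- array(0L, c(4, 4, 4)); a[1, 1, 1] <- 1L
  b <- array(0L, c(4, 4, 4)); b[1, 1, 3] <- 1L
  sa <- surface_voxels(a); sb <- surface_voxels(b)
  sp <- c(1, 1, 2.5)
  expect_equal(hausdorff(sa, sb, sp), 5)
  expect_equal(assd(sa, sb, sp), 5)
  expect_equal(hausdorff(sa, sa, sp), 0)
  expect_equal(assd(sb, sb, sp), 0)

  set.seed(12)
  for (rep in 1:10) {
    p <- random_blob_mask(c(8, 8, 6)); g <- random_blob_mask(c(8, 8, 6))
    spc <- runif(3, 0.5, 3)
    P <- surface_voxels(p); G <- surface_voxels(g)
    # symmetry
    expect_equal(hausdorff(P, G, spc), hausdorff(G, P, spc), tolerance = 1e-12)
    expect_equal(assd(P, G, spc), assd(G, P, spc), tolerance = 1e-12)
    # linear scaling of spacing
    expect_equal(hausdorff(P, G, 3 * spc), 3 * hausdorff(P, G, spc),
                 tolerance = 1e-9)
    expect_equal(assd(P, G, 3 * spc), 3 * assd(P, G, spc), tolerance = 1e-9)
    # oracle agreement and ordering
    o <- surface_dist_oracle(P, G, spc)
    expect_equal(hausdorff(P, G, spc), o$hd, tolerance = 1e-9)
    expect_equal(assd(P, G, spc), o$assd, tolerance = 1e-9)
    expect_lte(assd(P, G, spc), hausdorff(P, G, spc) + 1e-12)
  }
})

test_that("evaluate_set aggregates per-scan metrics consistently", {
  m <- array(0L, c(4, 4, 4)); m[2:3, 2:3, 2:3] <- 1L
  rep1 <- evaluate_set(list(list(pred = m, truth = m, spacing = c(1, 1, 1))))
  expect_equal(unname(attr(rep1, "mean")), c(1, 0, 0))
  expect_equal(unname(attr(rep1, "sd")), c(0, 0, 0))

  # second pair engineered to dice 0.5: TP=4, FP=4+FN=0 -> 8/(8+4)=... use
  # pred with 8 fg of which 4 overlap truth's 4 -> 2*4/(8+4) = 2/3; instead
  # make pred 4 fg overlapping 2 of truth's 4: 4/8 = 0.5
  t2 <- array(0L, c(4, 4, 4)); t2[1:2, 1:2, 1] <- 1L
  p2 <- array(0L, c(4, 4, 4)); p2[1:2, 1, 1] <- 1L; p2[1:2, 4, 4] <- 1L
  expect_equal(dice3d(p2, t2), 0.5)
  rep2 <- evaluate_set(list(list(pred = m, truth = m),
                            list(pred = p2, truth = t2)))
  expect_equal(unname(attr(rep2, "mean")["dice"]), 0.75)
  expect_equal(attr(rep2, "mean")[["dice"]], mean(rep2$dice))
  expect_equal(attr(rep2, "sd")[["hd_mm"]],
               sqrt(mean((rep2$hd_mm - mean(rep2$hd_mm))^2)))
  expect_equal(nrow(rep2), 2)
})
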
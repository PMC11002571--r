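test_that("NIfTI and NRRD volumes round-trip bit-exactly with spacing", {
  set.seed(1)
  a <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  vol <- volume3d(a, spacing = c(1.25, 1.25, 2.5))
  for (ext in c(".nii.gz", ".nii", ".nrrd")) {
    f <- withr::local_tempfile(fileext = ext)
    write_volume(vol, f)
    back <- read_volume(f)
    expect_identical(back$data, a)
    expect_equal(back$spacing, c(1.25, 1.25, 2.5))
  }
})

test_that("both NRRD encodings (raw and gzip) read back identically", {
  set.seed(9)
  a <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  for (enc in c("raw", "gzip")) {
    f <- withr::local_tempfile(fileext = ".nrrd")
    usformer:::write_nrrd(a, f, spacing = c(0.75, 0.75, 2), encoding = enc)
    nr <- usformer:::read_nrrd(f)
    expect_identical(nr$data, a)
    expect_equal(nr$spacing, c(0.75, 0.75, 2))
  }
})

test_that("masks round-trip and invalid masks are rejected", {
  set.seed(2)
  a <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  ref <- volume3d(a, spacing = c(1, 1, 2))
  m <- array(rbinom(8 * 8 * 4, 1, 0.3), c(8, 8, 4))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(m, ref, f)
  back <- read_volume(f)
  expect_identical(array(as.integer(back$data), dim(m)), array(as.integer(m), dim(m)))

  zf <- withr::local_tempfile(fileext = ".nrrd")
  write_mask(array(0L, c(8, 8, 4)), ref, zf)
  expect_true(all(read_volume(zf)$data == 0))

  bad <- m
  bad[1, 1, 1] <- 2
  expect_error(write_mask(bad, ref, f), "0 or 1")
  expect_error(write_mask(m[1:4, , ], ref, f), "does not match")
})

test_that("non-finite voxels follow the configured contract", {
  a <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  a[2, 3, 1] <- NaN
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(a)
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "non-finite")
  expect_warning(v <- read_volume(f, nan = "zero"), "non-finite")
  expect_equal(v$data[2, 3, 1], 0)
  expect_true(all(is.finite(v$data)))
})

test_that("degenerate payloads and bad metadata are rejected", {
  expect_error(read_volume("does-not-exist.nii"), "no such file")
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(matrix(rnorm(16), 4, 4)), f)
  expect_error(read_volume(f), "3D")
  expect_error(volume3d(array(1, c(2, 2)), c(1, 1, 1)), "rank-3")
  expect_error(volume3d(array(1, c(2, 2, 2)), c(1, 0, 1)), "positive")
})

test_that("pad_to_multiple reaches the next multiple and inverts exactly", {
  v <- array(rnorm(96 * 96 * 48), c(96, 96, 48))
  p <- pad_to_multiple(v, 16)
  expect_identical(dim(p$vol), dim(v))   # already divisible: unchanged
  expect_identical(p$vol, v)

  v2 <- array(rnorm(88 * 88 * 44), c(88, 88, 44))
  p2 <- pad_to_multiple(v2, 16)
  expect_identical(dim(p2$vol), c(96L, 96L, 48L))
  expect_equal(p2$vol[89, 1, 1], min(v2))  # fill = volume minimum

  set.seed(3)
  for (rep in 1:50) {
    d <- sample(3:40, 3, replace = TRUE)
    x <- array(rnorm(prod(d)), d)
    pp <- pad_to_multiple(x, 16)
    expect_identical(crop_by_record(pp$vol, pp$record), x)
  }
})

test_that("z-score normalization yields mean 0 and SD 1", {
  set.seed(4)
  v <- volume3d(array(rnorm(1000, 50, 7), c(10, 10, 10)), c(1, 1, 1))
  nv <- normalize_volume(v)
  expect_equal(mean(nv$data), 0, tolerance = 1e-12)
  expect_equal(stats::sd(as.numeric(nv$data)), 1, tolerance = 1e-12)
})
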
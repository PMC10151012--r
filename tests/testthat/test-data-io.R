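# File IO, preprocessing, augmentation and splits.

test_that("write-then-load round-trips a dataset with sorted ids", {
  root <- tempfile("ds")
  samples <- generateSynthetic(synthConfig("nuclei", nImages = 4L,
                                           size = c(32L, 32L), seed = 5))
  writeDataset(samples, root)
  expect_length(list.files(file.path(root, "images")), 4L)
  expect_length(list.files(file.path(root, "masks")), 4L)
  loaded <- loadDataset(file.path(root, "images"), file.path(root, "masks"))
  expect_identical(vapply(loaded, `[[`, "", "id"),
                   sort(vapply(samples, `[[`, "", "id")))
  # mask content is lossless through the 8-bit round trip
  for (i in seq_along(samples)) {
    expect_identical(loaded[[i]]$mask, samples[[i]]$mask)
  }
  unlink(root, recursive = TRUE)
})

test_that("colour handling: RGB collapses to luminance, grayscale replicates", {
  root <- tempfile("ds")
  glands <- generateSynthetic(synthConfig("glands", nImages = 2L,
                                          size = c(32L, 32L),
                                          radiusRange = c(5, 8), seed = 6))
  writeDataset(glands, root)
  asRgb <- loadDataset(file.path(root, "images"), file.path(root, "masks"),
                       mode = "rgb")
  expect_identical(dim(asRgb[[1]]$image)[3], 3L)
  asGray <- loadDataset(file.path(root, "images"), file.path(root, "masks"),
                        mode = "grayscale")
  expect_identical(dim(asGray[[1]]$image)[3], 1L)
  lum <- asRgb[[1]]$image[, , 1] * 0.299 + asRgb[[1]]$image[, , 2] * 0.587 +
    asRgb[[1]]$image[, , 3] * 0.114
  expect_equal(asGray[[1]]$image[, , 1], lum, tolerance = 1e-6)
  unlink(root, recursive = TRUE)
})

test_that("resizing keeps masks strictly binary", {
  root <- tempfile("ds")
  samples <- generateSynthetic(synthConfig("nuclei", nImages = 2L,
                                           size = c(48L, 40L), seed = 7))
  writeDataset(samples, root)
  small <- loadDataset(file.path(root, "images"), file.path(root, "masks"),
                       resizeTo = c(16L, 16L))
  expect_identical(dim(small[[1]]$image)[1:2], c(16L, 16L))
  expect_identical(dim(small[[1]]$mask), c(16L, 16L))
  expect_true(all(small[[1]]$mask %in% c(0L, 1L)))
  unlink(root, recursive = TRUE)
})

test_that("orphan image/mask files are reported explicitly", {
  root <- tempfile("ds")
  samples <- generateSynthetic(synthConfig("nuclei", nImages = 2L,
                                           size = c(32L, 32L), seed = 8))
  writeDataset(samples, root)
  file.remove(list.files(file.path(root, "masks"), full.names = TRUE)[1])
  expect_error(loadDataset(file.path(root, "images"),
                           file.path(root, "masks")),
               "unmatched.*nuclei_0001")
  unlink(root, recursive = TRUE)
})

test_that("augmentation is seeded, shape-preserving and mask-binary", {
  s <- generateSynthetic(synthConfig("nuclei", nImages = 1L,
                                     size = c(32L, 32L), seed = 9))[[1]]
  a1 <- withr::with_seed(10, augmentSample(s))
  a2 <- withr::with_seed(10, augmentSample(s))
  expect_identical(a1, a2)
  for (k in 1:20) {
    a <- withr::with_seed(k, augmentSample(s))
    expect_identical(dim(a$image), dim(s$image))
    expect_identical(dim(a$mask), dim(s$mask))
    expect_true(all(a$mask %in% c(0L, 1L)))
    expect_true(all(a$image >= 0 & a$image <= 1))
  }
})

test_that("a pure horizontal flip is an exact involution", {
  s <- smallSample(16, 16, seed = 2)
  flipOnce <- function(x) {
    augmentSample(x, rotationRange = 0, zoomRange = c(1, 1), shiftFrac = 0,
                  flipProb = 1)
  }
  twice <- flipOnce(flipOnce(s))
  expect_equal(twice$image, s$image, tolerance = 1e-12)
  expect_identical(twice$mask, (s$mask > 0.5) * 1L)
})

test_that("augmentation roughly preserves foreground fraction on average", {
  # half-foreground mask: the mean fraction over many draws stays within
  # +-0.1 of the original (reflection fill, moderate zoom/shift)
  s <- list(image = array(0.5, c(32, 32, 1L)),
            mask = rbind(matrix(1L, 16, 32), matrix(0L, 16, 32)),
            id = "half")
  fracs <- withr::with_seed(123, vapply(seq_len(500), function(i) {
    mean(augmentSample(s)$mask)
  }, numeric(1)))
  expect_lt(abs(mean(fracs) - 0.5), 0.1)
})

test_that("splits are deterministic partitions with balanced folds", {
  ids <- sprintf("img%03d", seq_len(670))
  sp <- makeSplits(ids, trainN = 570L, testN = 100L, kfold = TRUE, seed = 4)
  expect_length(sp$train, 570L)
  expect_length(sp$test, 100L)
  expect_length(sp$val, 0L)
  expect_identical(sort(c(sp$train, sp$test)), sort(ids))
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(vapply(sp$folds, length, integer(1), USE.NAMES = FALSE),
                   rep(114L, 5L))
  expect_identical(sort(unname(unlist(sp$folds))), sort(sp$train))
  # reproducible in (ids, seed)
  expect_identical(makeSplits(ids, 570L, 100L, kfold = TRUE, seed = 4), sp)
  expect_false(identical(makeSplits(ids, 570L, 100L, seed = 5)$train,
                         sp$train))
  expect_error(makeSplits(ids[1:10], 8L, 5L), "cannot split")
})

test_that("splits survive the YAML round trip", {
  sp <- makeSplits(sprintf("s%02d", 1:20), 12L, 5L, kfold = FALSE, seed = 2)
  path <- tempfile(fileext = ".yaml")
  writeSplits(sp, path)
  back <- readSplits(path)
  expect_identical(back$train, sp$train)
  expect_identical(back$test, sp$test)
  expect_identical(back$val, sp$val)
  unlink(path)
})
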
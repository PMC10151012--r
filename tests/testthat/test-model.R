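# FRUNet assembly, structural variants, parameter counting, inference.

toyConfig <- function(levels = 1L, ch = 2L) {
  modelConfig(levels = levels, channels = rep(as.integer(ch), levels + 1L))
}

test_that("encoder-decoder restores input resolution on a toy model", {
  m <- buildModel(toyConfig(), seed = 3)
  x <- withr::with_seed(4, array(runif(8 * 8), c(8, 8, 1, 1)))
  prob <- predictProb(m, x)
  expect_identical(dim(prob), c(8L, 8L, 1L, 1L))
  expect_true(all(prob > 0 & prob < 1)) # sigmoid head
  # inference is deterministic: bitwise-identical repeated outputs
  expect_identical(prob, predictProb(m, x))
  # S4 predict dispatches to the probability map
  expect_identical(predict(m, x), prob)
})

test_that("input contract errors are explicit", {
  m <- buildModel(toyConfig(levels = 2L), seed = 1)
  expect_error(predictProb(m, array(0.1, c(6, 6, 1, 1))), "divisible by 4")
  expect_error(predictProb(m, array(0.1, c(8, 8, 3, 1))), "channel")
  expect_error(buildVariant("not_a_variant"), "unknown variant")
})

test_that("default architecture: 3 levels at width 64, deepest map 16x16", {
  m <- buildModel(seed = 1)
  x <- array(0.5, c(128, 128, 1, 1))
  fw <- frunet:::frunetFwd(m, x, training = FALSE, needCache = TRUE)
  expect_identical(dim(fw$prob)[1:2], c(128L, 128L))
  # deepest feature map (bottleneck) is 16x16 after three halvings
  bneckDim <- dim(fw$caches$bottleneck$b1$xhat)
  expect_identical(bneckDim[1:2], c(16L, 16L))
  # every hidden layer runs at 64 channels
  expect_true(all(m@config@channels == 64L))
  widths <- vapply(m@params$enc, function(e) dim(e$unit$fca1$conv1$w)[4],
                   integer(1))
  expect_true(all(widths == 64L))
  expect_identical(dim(m@params$head$w)[3:4], c(64L, 1L))
})

test_that("parameter counting is exact for known layers", {
  conv <- withr::with_seed(1, frunet:::initConvParams(3L, 1L, 64L))
  expect_identical(countParameters(conv), 1L * 64L * 9L + 64L)
  bn <- frunet:::initBnParams(64L)
  expect_identical(countParameters(bn), 128L)
  # resolution- and batch-independent: the count is a function of the
  # configuration only
  expect_identical(countParameters(buildModel(toyConfig(), seed = 1)),
                   countParameters(buildModel(toyConfig(), seed = 99)))
})

test_that("variant parameter counts are ordered as the structure implies", {
  base <- buildVariant("base")
  noFft <- buildVariant("no_fft")
  noAtt <- buildVariant("no_attention")
  wide <- buildVariant("wide_channels")
  deep <- buildVariant("deep_4level")
  deepWide <- buildVariant("deep_and_wide")
  # the transform is parameter-free, so removing it changes nothing
  expect_identical(countParameters(base), countParameters(noFft))
  # removing the attention gate drops the 1x1 convolutions
  expect_lt(countParameters(noAtt), countParameters(base))
  expect_gt(countParameters(wide), countParameters(base))
  expect_gt(countParameters(deep), countParameters(base))
  expect_gt(countParameters(deepWide), countParameters(wide))
  expect_gt(countParameters(deepWide) / countParameters(base), 5)
})

test_that("forward pass replays layer by layer on a frozen toy model", {
  m <- buildModel(toyConfig(ch = 3L), seed = 11)
  x <- withr::with_seed(12, array(runif(8 * 8), c(8, 8, 1, 1)))
  got <- predictProb(m, x)
  p <- m@params
  st <- m@state
  cfg <- fcaConfig(channels = 3L)
  t0 <- frunet:::convFwd(x, p$stem)$out
  e1 <- residualUnitForward(t0, cfg, p$enc[[1]]$unit, st$enc[[1]])
  pl <- frunet:::maxPoolFwd(e1)$out
  bt <- residualUnitForward(pl, cfg, p$bottleneck$unit, st$bottleneck)
  up <- frunet:::upsampleFwd(bt)
  fused <- frunet:::abind4(e1, up)
  fz <- frunet:::convFwd(fused, p$dec[[1]]$fuse)$out
  d1 <- residualUnitForward(fz, cfg, p$dec[[1]]$unit, st$dec[[1]])
  ref <- frunet:::sigmoid(frunet:::convFwd(d1, p$head)$out)
  expect_lt(max(abs(got - ref)), 1e-5)
})

test_that("one optimisation step decreases the training loss", {
  m <- buildModel(toyConfig(ch = 4L), seed = 21)
  s <- generateSynthetic(synthConfig("nuclei", nImages = 1L,
                                     size = c(32L, 32L), seed = 7))[[1]]
  x <- array(s$image, c(32, 32, 1, 1))
  y <- array(s$mask, c(32, 32, 1, 1))
  fw <- frunet:::frunetFwd(m, x, training = TRUE, needCache = TRUE)
  lg <- frunet:::lossAndGrad(y, fw$prob, "combined")
  dlog <- lg$dprob * fw$prob * (1 - fw$prob)
  g <- frunet:::frunetBwd(m, fw$caches, dlog)
  opt <- frunet:::adamInit(m@params)
  r <- frunet:::adamRec(m@params, g, opt$m, opt$v, lr = 1e-3, t = 1)
  m2 <- m
  m2@params <- r$p
  fw2 <- frunet:::frunetFwd(m2, x, training = TRUE)
  expect_lt(frunet:::lossAndGrad(y, fw2$prob, "combined")$loss, lg$loss)
})

test_that("checkpoints round-trip the model bitwise", {
  m <- buildModel(toyConfig(levels = 2L, ch = 3L), seed = 31)
  x <- withr::with_seed(32, array(runif(16 * 16), c(16, 16, 1, 1)))
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(m, path)
  m2 <- loadCheckpoint(path)
  expect_identical(predictProb(m2, x), predictProb(m, x))
  expect_identical(m2@config@channels, m@config@channels)
  expect_error(suppressWarnings(loadCheckpoint(tempfile())), ".")
  unlink(path)
})

test_that("transposed-convolution and additive-fusion decoders run", {
  cfgT <- modelConfig(levels = 1L, channels = c(2L, 2L),
                      upsampleMode = "transposed")
  mT <- buildModel(cfgT, seed = 41)
  x <- withr::with_seed(42, array(runif(8 * 8), c(8, 8, 1, 1)))
  expect_identical(dim(predictProb(mT, x)), c(8L, 8L, 1L, 1L))
  cfgA <- modelConfig(levels = 1L, channels = c(2L, 2L), skipFusion = "add")
  mA <- buildModel(cfgA, seed = 43)
  expect_identical(dim(predictProb(mA, x)), c(8L, 8L, 1L, 1L))
})
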
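# The Fourier channel attention block and its residual unit.

test_that("spatial branch preserves shape and maps zero to zero", {
  p <- withr::with_seed(3, initFcaParams(4L))
  x <- withr::with_seed(4, array(rnorm(32 * 32 * 4 * 2), c(32, 32, 4, 2)))
  out <- spatialBranch(x, p)
  expect_identical(dim(out), dim(x))

  # zero input with zero biases stays zero: GELU(0) = 0
  pz <- zeroFcaParams(4L)
  z <- array(0, c(8, 8, 4, 1))
  expect_equal(spatialBranch(z, pz), z)

  # channel mismatch is a configuration error
  expect_error(spatialBranch(array(0, c(8, 8, 3, 1)), p), "channel")
})

test_that("spatial branch matches a sliding-window convolution oracle", {
  p <- withr::with_seed(7, initFcaParams(2L))
  x <- withr::with_seed(8, array(rnorm(5 * 5 * 2), c(5, 5, 2, 1)))
  got <- spatialBranch(x, p)
  h1 <- naiveGelu(naiveConvSame(x[, , , 1], p$conv1$w, p$conv1$b))
  ref <- naiveGelu(naiveConvSame(h1, p$conv2$w, p$conv2$b))
  expect_lt(max(abs(got[, , , 1] - ref)), 1e-5)
})

test_that("amplitude spectrum: zero map, DC-only constant, naive DFT", {
  z <- array(0, c(8, 8, 2, 1))
  expect_equal(amplitudeSpectrum(z), z)

  # a constant image has all its energy in the zero-frequency bin;
  # with the orthonormal transform the DC modulus is c * sqrt(H * W)
  cst <- array(0.7, c(6, 4, 1, 1))
  sp <- amplitudeSpectrum(cst, gamma = 0.8)
  expect_equal(sp[1, 1, 1, 1], (0.7 * sqrt(24))^0.8, tolerance = 1e-6)
  expect_equal(sum(sp > 1e-9), 1L)
  # fftshift recenters that bin
  sps <- amplitudeSpectrum(cst, gamma = 0.8, applyFftshift = TRUE)
  expect_equal(sps[4, 3, 1, 1], (0.7 * sqrt(24))^0.8, tolerance = 1e-6)

  x <- withr::with_seed(11, matrix(rnorm(64), 8, 8))
  got <- amplitudeSpectrum(array(x, c(8, 8, 1, 1)), gamma = 1)
  expect_lt(max(abs(got[, , 1, 1] - naiveDftMod(x))), 1e-6)

  # spectrum is non-negative and shape-preserving for any input
  x4 <- withr::with_seed(12, array(rnorm(6 * 10 * 3 * 2), c(6, 10, 3, 2)))
  sp4 <- amplitudeSpectrum(x4, gamma = 0.8)
  expect_identical(dim(sp4), dim(x4))
  expect_true(all(sp4 >= 0))
})

test_that("channel attention weights: range, zero input, arithmetic oracle", {
  p1 <- withr::with_seed(5, initConvParams(1L, 4L, 4L))

  # zero input and zero bias gives sigmoid(0) = 0.5 exactly
  pz <- list(w = p1$w * 0, b = p1$b * 0)
  wz <- channelAttentionWeights(array(0, c(6, 6, 4, 2)), pz)
  expect_equal(as.vector(wz), rep(0.5, 8))

  # direct mean-then-sigmoid oracle on a random spectrum
  freq <- withr::with_seed(6, array(abs(rnorm(6 * 6 * 4)), c(6, 6, 4, 1)))
  got <- channelAttentionWeights(freq, p1)
  ref <- sapply(1:4, function(co) {
    z <- p1$b[co]
    z <- z + Reduce(`+`, lapply(1:4, function(ci) {
      freq[, , ci, 1] * p1$w[1, 1, ci, co]
    }))
    1 / (1 + exp(-mean(pmax(z, 0))))
  })
  expect_lt(max(abs(as.vector(got) - ref)), 1e-6)

  # strictly inside (0,1) for arbitrary finite inputs
  for (s in 1:5) {
    f <- withr::with_seed(s, array(rnorm(8 * 8 * 4, sd = 10), c(8, 8, 4, 1)))
    w <- channelAttentionWeights(f, p1)
    expect_true(all(w > 0 & w < 1))
    expect_length(w, 4L)
  }
})

test_that("attention weights are invariant to circular translation", {
  p <- withr::with_seed(21, initFcaParams(3L))
  x <- withr::with_seed(22, array(rnorm(12 * 12 * 3), c(12, 12, 3, 1)))
  wts <- function(xx) {
    s <- spatialBranch(xx, p) # translation-equivariant (caution: padding)
    channelAttentionWeights(amplitudeSpectrum(xx, gamma = 0.8), p$att)
  }
  base <- channelAttentionWeights(amplitudeSpectrum(x, 0.8), p$att)
  for (shift in list(c(3, 0), c(0, 5), c(7, 2))) {
    xs <- x[c((shift[1] + 1):12, seq_len(shift[1])),
            c((shift[2] + 1):12, seq_len(shift[2])), , , drop = FALSE]
    shifted <- channelAttentionWeights(amplitudeSpectrum(xs, 0.8), p$att)
    expect_lt(max(abs(base - shifted)), 1e-6)
  }
})

test_that("FCA block composes its stages and respects the skip", {
  cfg <- fcaConfig(channels = 2L, gamma = 0.8)
  p <- withr::with_seed(31, initFcaParams(2L))
  x <- withr::with_seed(32, array(rnorm(8 * 8 * 2), c(8, 8, 2, 1)))

  out <- fcaBlockForward(x, cfg, p)
  expect_identical(dim(out), dim(x))

  # staged composition: spatial branch -> spectrum -> weights -> gate -> skip
  s <- spatialBranch(x, p)
  w <- channelAttentionWeights(amplitudeSpectrum(s, cfg@gamma), p$att)
  ref <- x + s * array(rep(as.vector(w), each = 64), dim(s))
  expect_lt(max(abs(out - ref)), 1e-5)

  # forcing unit weights bypasses the gate: out = x + spatialBranch(x)
  outF <- fcaBlockForward(x, cfg, p, forceUnitWeights = TRUE)
  expect_equal(outF, x + s, tolerance = 1e-12)

  expect_error(fcaBlockForward(array(0, c(8, 8, 3, 1)), cfg, p), "channels")
})

test_that("ablation twins: no-FFT keeps the graph, no-attention drops the gate", {
  p <- withr::with_seed(41, initFcaParams(2L))
  x <- withr::with_seed(42, array(rnorm(8 * 8 * 2), c(8, 8, 2, 1)))

  # use_fft off: same computation with the spectrum replaced by identity
  cfgNoF <- fcaConfig(channels = 2L, useFft = FALSE)
  s <- spatialBranch(x, p)
  w <- channelAttentionWeights(s, p$att)
  ref <- x + s * array(rep(as.vector(w), each = 64), dim(s))
  expect_lt(max(abs(fcaBlockForward(x, cfgNoF, p) - ref)), 1e-5)

  # attention off: a plain two-convolution residual block, fewer parameters
  cfgNoA <- fcaConfig(channels = 2L, useAttention = FALSE)
  pNoA <- withr::with_seed(41, initFcaParams(2L, useAttention = FALSE))
  expect_equal(fcaBlockForward(x, cfgNoA, pNoA), x + s, tolerance = 1e-12)
  expect_lt(countParameters(pNoA), countParameters(p))
  expect_identical(countParameters(p),
                   countParameters(withr::with_seed(9, initFcaParams(2L))))
})

test_that("residual unit: shape, identity skip, staged oracle", {
  cfg <- fcaConfig(channels = 4L)
  p <- withr::with_seed(51, initResidualUnitParams(4L))
  st <- frunet:::initResidualUnitState(4L)
  x <- withr::with_seed(52, array(rnorm(16 * 16 * 4), c(16, 16, 4, 1)))

  out <- residualUnitForward(x, cfg, p, st)
  expect_identical(dim(out), dim(x))

  # when the residual branch vanishes the skip path is exactly x: with
  # zero kernels/biases and attention disabled the inner FCA maps are the
  # identity on zero, and zeroed batch-norm scale/shift annihilate the
  # branch, so out = x + 0
  pz <- withr::with_seed(1, initResidualUnitParams(4L, useAttention = FALSE))
  pz <- frunet:::mapLeaves(pz, function(a) a * 0)
  cfgNoA <- fcaConfig(channels = 4L, useAttention = FALSE)
  expect_equal(residualUnitForward(x, cfgNoA, pz), x, tolerance = 1e-12)

  # staged four-layer + skip oracle in inference mode
  f1 <- fcaBlockForward(x, cfg, p$fca1)
  bn1 <- frunet:::bnFwd(f1, p$bn1, st$bn1, training = FALSE)$out
  f2 <- fcaBlockForward(bn1, cfg, p$fca2)
  bn2 <- frunet:::bnFwd(f2, p$bn2, st$bn2, training = FALSE)$out
  expect_lt(max(abs(out - (x + bn2))), 1e-5)
})

test_that("training-mode gradients agree with finite differences", {
  # validates the hand-derived backward passes through conv, GELU, the
  # DFT modulus, ReLU-GAP-sigmoid attention and batch normalisation
  cfg <- fcaConfig(channels = 2L)
  p <- withr::with_seed(61, initFcaParams(2L))
  x <- withr::with_seed(62, array(rnorm(6 * 6 * 2), c(6, 6, 2, 1)))
  proj <- withr::with_seed(63, array(rnorm(length(x)), dim(x)))
  fw <- frunet:::fcaBlockFwd(x, p, cfg, needCache = TRUE)
  bk <- frunet:::fcaBlockBwd(proj, fw$cache, p, cfg)
  f <- function(xx) sum(proj * frunet:::fcaBlockFwd(xx, p, cfg)$out)
  idx <- withr::with_seed(64, sample(length(x), 6))
  for (i in idx) {
    eps <- 2e-3 # sized for the single-precision convolution core
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal(bk$dx[i], (f(xp) - f(xm)) / (2 * eps), tolerance = 5e-3)
  }
})
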
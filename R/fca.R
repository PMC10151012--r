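# Fourier channel attention (FCA) block and the residual unit built from it.
#
# Block: x -> conv3x3 -> GELU -> conv3x3 -> GELU  (spatial branch, output s)
#        s -> |DFT2|^gamma -> 1x1 conv -> ReLU -> GAP -> sigmoid  (weights w)
#        out = x + w (.) s          (per-channel broadcast, internal skip)
# Residual unit: out = x + BN2(FCA2(BN1(FCA1(x)))).

#' Initialise the parameters of one FCA block
#'
#' @param channels number of feature channels (input and output).
#' @param useAttention include the 1x1 attention convolution (dropped in the
#'   attention-disabled ablation, which therefore has fewer parameters).
#' @return named list with `conv1`, `conv2` (3x3 kernels + biases) and
#'   `att` (1x1 kernel + bias, or NULL).
#' @export
initFcaParams <- function(channels, useAttention = TRUE) {
  list(
    conv1 = initConvParams(3L, channels, channels),
    conv2 = initConvParams(3L, channels, channels),
    att = if (useAttention) initConvParams(1L, channels, channels) else NULL
  )
}

#' Initialise the parameters of one residual unit (two FCA blocks + BN)
#'
#' @inheritParams initFcaParams
#' @return named list with `fca1`, `bn1`, `fca2`, `bn2`.
#' @export
initResidualUnitParams <- function(channels, useAttention = TRUE) {
  list(
    fca1 = initFcaParams(channels, useAttention),
    bn1 = initBnParams(channels),
    fca2 = initFcaParams(channels, useAttention),
    bn2 = initBnParams(channels)
  )
}

initResidualUnitState <- function(channels) {
  list(bn1 = initBnState(channels), bn2 = initBnState(channels))
}

# ---- spatial branch ----

spatialBranchFwd <- function(x, p, needCache = FALSE) {
  c1 <- convFwd(x, p$conv1, needCache)
  g1 <- gelu(c1$out)
  c2 <- convFwd(g1, p$conv2, needCache)
  s <- gelu(c2$out)
  cache <- if (needCache) {
    list(a1 = c1$out, a2 = c2$out, c1 = c1$cache, c2 = c2$cache)
  }
  list(out = s, cache = cache)
}

spatialBranchBwd <- function(ds, cache, p) {
  da2 <- gelu_grad_cpp(cache$a2, ds)
  g2 <- convBwd(da2, cache$c2, p$conv2)
  da1 <- gelu_grad_cpp(cache$a1, g2$dx)
  g1 <- convBwd(da1, cache$c1, p$conv1)
  list(dx = g1$dx, grads = list(conv1 = g1$grads, conv2 = g2$grads))
}

#' Spatial branch of an FCA block
#'
#' Two 3x3 convolutions (stride 1, zero same-padding, biases), each followed
#' by a GELU activation. Preserves spatial size and channel count.
#'
#' @param x feature map array `(row, col, channel, batch)` (trailing
#'   singleton dimensions may be omitted).
#' @param params list with `conv1` and `conv2`, as from [initFcaParams].
#' @return feature map of the same shape as `x`.
#' @export
spatialBranch <- function(x, params) {
  x <- checkFeatureMap(x)
  spatialBranchFwd(x, params)$out
}

# ---- amplitude spectrum ----

ampSpectrumFwd <- function(s, gamma, needCache = FALSE) {
  r <- amp_fwd_cpp(s, gamma)
  cache <- if (needCache) list(f = r$f, a = r$a, gamma = gamma)
  list(out = r$out, cache = cache)
}

ampSpectrumBwd <- function(dout, cache) {
  amp_bwd_cpp(dout, cache$f, cache$a, cache$gamma)
}

#' Amplitude spectrum of a feature map
#'
#' Per channel, takes the orthonormal 2-D discrete Fourier transform over
#' (row, col), the elementwise modulus, and raises it to the power `gamma`.
#' `gamma < 1` compresses the dominant low-frequency magnitudes, which
#' raises the relative contribution of the high-frequency content. The
#' output is real, non-negative and has the shape of the input.
#'
#' @param x feature map array.
#' @param gamma positive exponent (default 0.8).
#' @param applyFftshift recenter the zero-frequency bin to the grid centre.
#' @return real array of the same shape as `x`.
#' @export
amplitudeSpectrum <- function(x, gamma = 0.8, applyFftshift = FALSE) {
  x <- checkFeatureMap(x)
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0)
  out <- ampSpectrumFwd(x, gamma)$out
  if (applyFftshift) out <- fftshift4(out)
  out
}

# ---- channel attention weights ----

attWeightsFwd <- function(freq, p, needCache = FALSE) {
  cz <- convFwd(freq, p, needCache)
  gap <- relu_gap_fwd_cpp(cz$out)
  w <- sigmoid(gap)
  cache <- if (needCache) list(z = cz$out, conv = cz$cache, w = w)
  list(w = w, cache = cache)
}

attWeightsBwd <- function(dw, cache, p) {
  dgap <- dw * cache$w * (1 - cache$w)
  dz <- relu_gap_bwd_cpp(cache$z, dgap)
  g <- convBwd(dz, cache$conv, p)
  list(dfreq = g$dx, grads = g$grads)
}

#' Per-channel attention weights from a (frequency) feature map
#'
#' Applies a 1x1 convolution with ReLU, global average pooling over
#' (row, col), and a sigmoid, producing one weight strictly in (0,1) per
#' channel (and per batch element). Because pooling averages all spatial
#' positions, the weights are invariant to any spatial permutation of the
#' input — in particular to the circular translations under which the DFT
#' modulus is itself invariant.
#'
#' @param freq real feature map (typically an amplitude spectrum).
#' @param params a 1x1 convolution parameter list (`w`, `b`).
#' @return matrix `(channel, batch)` of weights in (0,1).
#' @export
channelAttentionWeights <- function(freq, params) {
  freq <- checkFeatureMap(freq)
  attWeightsFwd(freq, params)$w
}

# ---- full FCA block ----

fcaBlockFwd <- function(x, p, cfg, needCache = FALSE, forceUnitWeights = FALSE) {
  sb <- spatialBranchFwd(x, p, needCache)
  s <- sb$out
  if (!cfg@useAttention) {
    out <- x + s
    return(list(out = out,
                cache = if (needCache) list(sb = sb$cache, mode = "none")))
  }
  if (cfg@useFft) {
    # the GAP-based weights are exactly invariant to the fftshift
    # permutation, so the spectrum is consumed unshifted here
    amp <- ampSpectrumFwd(s, cfg@gamma, needCache)
    specIn <- amp$out
  } else {
    amp <- NULL
    specIn <- s
  }
  att <- attWeightsFwd(specIn, p$att, needCache)
  w <- if (forceUnitWeights) matrix(1, nrow(att$w), ncol(att$w)) else att$w
  out <- x + mul_channels_cpp(s, w)
  cache <- if (needCache) {
    list(sb = sb$cache, amp = amp$cache, att = att$cache, s = s, w = w,
         mode = "att")
  }
  list(out = out, cache = cache, weights = w)
}

fcaBlockBwd <- function(dout, cache, p, cfg) {
  if (identical(cache$mode, "none")) {
    sb <- spatialBranchBwd(dout, cache$sb, p)
    return(list(dx = dout + sb$dx,
                grads = c(sb$grads, list(att = NULL))))
  }
  s <- cache$s
  ds <- mul_channels_cpp(dout, cache$w)
  dw <- dot_channels_cpp(dout, s)
  att <- attWeightsBwd(dw, cache$att, p$att)
  dspecIn <- att$dfreq
  if (cfg@useFft) {
    ds <- ds + ampSpectrumBwd(dspecIn, cache$amp)
  } else {
    ds <- ds + dspecIn
  }
  sb <- spatialBranchBwd(ds, cache$sb, p)
  list(dx = dout + sb$dx, grads = c(sb$grads, list(att = att$grads)))
}

#' Forward pass of one FCA block
#'
#' Computes the spatial branch, derives per-channel attention weights from
#' the amplitude spectrum of the spatial features (or from the features
#' themselves when `useFft` is off), gates the spatial features with the
#' weights, and adds the block input back (internal skip connection). With
#' `useAttention` off the block is a plain two-convolution residual block.
#'
#' @param x feature map array; its channel count must equal `cfg@channels`.
#' @param cfg an [FcaConfig-class].
#' @param params parameter list from [initFcaParams].
#' @param forceUnitWeights test hook: bypass the sigmoid gate and use
#'   weight 1 for every channel.
#' @return feature map of the same shape as `x`.
#' @export
fcaBlockForward <- function(x, cfg, params, forceUnitWeights = FALSE) {
  x <- checkFeatureMap(x)
  if (!is.na(cfg@channels) && dim(x)[3] != cfg@channels) {
    stop(sprintf("FCA block configured for %d channels, input has %d",
                 cfg@channels, dim(x)[3]), call. = FALSE)
  }
  fcaBlockFwd(x, params, cfg, forceUnitWeights = forceUnitWeights)$out
}

# ---- residual unit ----

residualUnitFwd <- function(x, p, state, cfg, training = FALSE,
                            needCache = FALSE) {
  f1 <- fcaBlockFwd(x, p$fca1, cfg, needCache)
  b1 <- bnFwd(f1$out, p$bn1, state$bn1, training, needCache = needCache)
  f2 <- fcaBlockFwd(b1$out, p$fca2, cfg, needCache)
  b2 <- bnFwd(f2$out, p$bn2, state$bn2, training, needCache = needCache)
  out <- x + b2$out
  state$bn1 <- b1$state
  state$bn2 <- b2$state
  cache <- if (needCache) {
    list(f1 = f1$cache, b1 = b1$cache, f2 = f2$cache, b2 = b2$cache)
  }
  list(out = out, state = state, cache = cache)
}

residualUnitBwd <- function(dout, cache, p, cfg) {
  g2 <- bnBwd(dout, cache$b2, p$bn2)
  f2 <- fcaBlockBwd(g2$dx, cache$f2, p$fca2, cfg)
  g1 <- bnBwd(f2$dx, cache$b1, p$bn1)
  f1 <- fcaBlockBwd(g1$dx, cache$f1, p$fca1, cfg)
  list(
    dx = dout + f1$dx,
    grads = list(fca1 = f1$grads, bn1 = g1$grads,
                 fca2 = f2$grads, bn2 = g2$grads)
  )
}

#' Forward pass of one residual unit
#'
#' `out = x + BN2(FCA2(BN1(FCA1(x))))`: two FCA blocks, each followed by
#' batch normalisation, wrapped in an additive identity skip. Uses the
#' supplied running statistics (inference mode).
#'
#' @param x feature map array.
#' @param cfg an [FcaConfig-class].
#' @param params parameters from [initResidualUnitParams].
#' @param state batch-normalisation running statistics, as from
#'   `initResidualUnitState`; identity statistics (mean 0, variance 1)
#'   are used when omitted.
#' @return feature map of the same shape as `x`.
#' @export
residualUnitForward <- function(x, cfg, params, state = NULL) {
  x <- checkFeatureMap(x)
  if (is.null(state)) state <- initResidualUnitState(dim(x)[3])
  residualUnitFwd(x, params, state, cfg, training = FALSE)$out
}
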
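# Low-level layer primitives on (row, col, channel, batch) arrays.
# Each *Fwd returns list(out, cache); each *Bwd consumes the cache and the
# upstream gradient and returns dx plus parameter gradients.

as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature maps must be arrays", call. = FALSE)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) stop("expected a (row, col, channel, batch) array",
                                 call. = FALSE)
  x
}

checkFeatureMap <- function(x) {
  x <- as4d(x)
  if (!all(is.finite(x))) stop("feature map contains non-finite values",
                               call. = FALSE)
  if (dim(x)[1] < 2L || dim(x)[2] < 2L) {
    stop("feature maps need at least 2 rows and 2 columns", call. = FALSE)
  }
  x
}

gelu <- function(x) gelu_cpp(x)
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- convolution (stride 1, zero "same" padding, odd kernel) ----

#' @noRd
initConvParams <- function(k, cin, cout) {
  fanIn <- k * k * cin
  fanOut <- k * k * cout
  lim <- sqrt(6 / (fanIn + fanOut)) # Glorot uniform
  list(
    w = array(runif(k * k * cin * cout, -lim, lim), c(k, k, cin, cout)),
    b = numeric(cout)
  )
}

convFwd <- function(x, p, needCache = FALSE) {
  d <- dim(x)
  k <- dim(p$w)[1]
  cin <- dim(p$w)[3]
  cout <- dim(p$w)[4]
  if (d[3] != cin) {
    stop(sprintf("channel mismatch: input has %d channels, kernel expects %d",
                 d[3], cin), call. = FALSE)
  }
  wmat <- p$w
  dim(wmat) <- c(k * k * cin, cout)
  r <- conv2d_fwd_cpp(x, wmat, p$b, k, needCache)
  if (needCache) {
    list(out = r$out, cache = list(x = x, cols = r$cols))
  } else {
    list(out = r$out)
  }
}

convBwd <- function(dout, cache, p) {
  k <- dim(p$w)[1]
  cin <- dim(p$w)[3]
  cout <- dim(p$w)[4]
  wmat <- p$w
  dim(wmat) <- c(k * k * cin, cout)
  g <- conv2d_bwd_cpp(cache$x, wmat, dout, k, cache$cols)
  dw <- g$dw
  dim(dw) <- c(k, k, cin, cout)
  list(dx = g$dx, grads = list(w = dw, b = g$db))
}

# ---- batch normalisation (per channel over rows, cols, batch) ----

initBnParams <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels))
}

initBnState <- function(channels) {
  list(mean = rep(0, channels), var = rep(1, channels))
}

bnFwd <- function(x, p, state, training, momentum = 0.9, eps = 1e-3,
                  needCache = FALSE) {
  r <- bn_fwd_cpp(x, p$gamma, p$beta, state$mean, state$var, training,
                  momentum, eps, needCache)
  if (training) {
    state$mean <- as.numeric(r$newMean)
    state$var <- as.numeric(r$newVar)
  }
  cache <- if (needCache) list(xhat = r$xhat, invstd = as.numeric(r$invstd))
  list(out = r$out, state = state, cache = cache)
}

bnBwd <- function(dout, cache, p) {
  r <- bn_bwd_cpp(dout, cache$xhat, cache$invstd, p$gamma)
  list(dx = r$dx,
       grads = list(gamma = as.numeric(r$dgamma),
                    beta = as.numeric(r$dbeta)))
}

# ---- pooling / upsampling ----

maxPoolFwd <- function(x, needCache = FALSE) {
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L) {
    stop("2x2 max pooling requires even spatial dimensions", call. = FALSE)
  }
  r <- maxpool2_fwd_cpp(x)
  list(out = r$out,
       cache = if (needCache) list(arg = r$argmax, d = d) else NULL)
}

maxPoolBwd <- function(dout, cache) {
  maxpool2_bwd_cpp(dout, cache$arg, cache$d[1], cache$d[2])
}

upsampleFwd <- function(x) upsample2_fwd_cpp(x)

upsampleBwd <- function(dout) upsample2_bwd_cpp(dout)

# ---- discrete Fourier transform helpers (orthonormal scaling) ----

fftshiftIdx <- function(n) c((floor(n / 2) + 1L):n, 1L:floor(n / 2))

fftshift4 <- function(x) {
  d <- dim(x)
  x[fftshiftIdx(d[1]), fftshiftIdx(d[2]), , , drop = FALSE]
}

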
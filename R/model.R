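# FRUNet assembly: stem conv -> [residual unit -> 2x2 max pool] x levels ->
# bottleneck residual unit -> [x2 upsample -> skip fusion -> 3x3 adjust conv
# -> residual unit] x levels -> 1x1 conv + sigmoid head.

fcaAt <- function(cfg, channels) {
  f <- cfg@fca
  f@channels <- as.integer(channels)
  f
}

# ---- transposed 2x2 stride-2 convolution (optional upsampling operator) ----

initTconvParams <- function(cin, cout) {
  lim <- sqrt(6 / (4 * cin + 4 * cout))
  list(w = array(runif(4 * cin * cout, -lim, lim), c(2, 2, cin, cout)),
       b = numeric(cout))
}

tconvFwd <- function(x, p, needCache = FALSE) {
  d <- dim(x)
  cin <- dim(p$w)[3]
  cout <- dim(p$w)[4]
  out <- array(0, c(2 * d[1], 2 * d[2], cout, d[4]))
  for (n in seq_len(d[4])) {
    xm <- matrix(x[, , , n], d[1] * d[2], cin)
    for (dj in 0:1) for (di in 0:1) {
      y <- xm %*% matrix(p$w[di + 1, dj + 1, , ], cin, cout)
      y <- sweep(y, 2, p$b, "+")
      out[seq(1, 2 * d[1], 2) + di, seq(1, 2 * d[2], 2) + dj, , n] <-
        array(y, c(d[1], d[2], cout))
    }
  }
  list(out = out, cache = if (needCache) list(x = x))
}

tconvBwd <- function(dout, cache, p) {
  x <- cache$x
  d <- dim(x)
  cin <- dim(p$w)[3]
  cout <- dim(p$w)[4]
  dw <- array(0, dim(p$w))
  db <- numeric(cout)
  dx <- array(0, d)
  for (n in seq_len(d[4])) {
    xm <- matrix(x[, , , n], d[1] * d[2], cin)
    dxm <- matrix(0, d[1] * d[2], cin)
    for (dj in 0:1) for (di in 0:1) {
      dy <- matrix(dout[seq(1, 2 * d[1], 2) + di,
                        seq(1, 2 * d[2], 2) + dj, , n],
                   d[1] * d[2], cout)
      dw[di + 1, dj + 1, , ] <- dw[di + 1, dj + 1, , ] + crossprod(xm, dy)
      db <- db + colSums(dy)
      dxm <- dxm + dy %*% t(matrix(p$w[di + 1, dj + 1, , ], cin, cout))
    }
    dx[, , , n] <- array(dxm, d[1:3])
  }
  list(dx = dx, grads = list(w = dw, b = db))
}

# ---- parameter / state initialisation ----

initModelParams <- function(cfg) {
  L <- cfg@levels
  ch <- cfg@channels
  att <- cfg@fca@useAttention
  p <- list(stem = initConvParams(3L, cfg@inChannels, ch[1]))
  p$enc <- lapply(seq_len(L), function(l) {
    list(unit = initResidualUnitParams(ch[l], att))
  })
  p$down <- lapply(seq_len(L), function(l) {
    if (ch[l + 1] != ch[l]) {
      list(adjust = initConvParams(3L, ch[l], ch[l + 1]))
    } else {
      list(adjust = NULL)
    }
  })
  p$bottleneck <- list(unit = initResidualUnitParams(ch[L + 1], att))
  p$dec <- lapply(seq_len(L), function(l) {
    cur <- ch[l + 1] # width arriving from below
    up <- if (cfg@upsampleMode == "transposed") initTconvParams(cur, cur)
    fuseIn <- if (cfg@skipFusion == "concat") ch[l] + cur else cur
    list(up = up,
         fuse = initConvParams(3L, fuseIn, ch[l]),
         unit = initResidualUnitParams(ch[l], att))
  })
  p$head <- initConvParams(1L, ch[1], 1L)
  p
}

initModelState <- function(cfg) {
  L <- cfg@levels
  ch <- cfg@channels
  list(
    enc = lapply(seq_len(L), function(l) initResidualUnitState(ch[l])),
    bottleneck = initResidualUnitState(ch[L + 1]),
    dec = lapply(seq_len(L), function(l) initResidualUnitState(ch[l]))
  )
}

#' Build a FRUNet model
#'
#' Constructs the encoder--decoder with randomly initialised weights
#' (Glorot-uniform kernels, zero biases, batch-normalisation scale 1 /
#' shift 0).
#'
#' @param cfg a [ModelConfig-class] (default: 3 levels, 64 channels,
#'   grayscale input).
#' @param seed integer seed for the weight initialisation.
#' @return a [FRUNet-class] model.
#' @export
buildModel <- function(cfg = modelConfig(), seed = 1L) {
  validObject(cfg)
  params <- withSeed(seed, initModelParams(cfg))
  new("FRUNet", config = cfg, params = params, state = initModelState(cfg),
      seed = as.integer(seed))
}

#' Build a named structural or ablation variant
#'
#' `base` is the default architecture (3 levels, 64 channels everywhere).
#' `wide_channels` widens the encoder to 64/128/256; `deep_4level` adds a
#' fourth level at width 64; `deep_and_wide` does both with doubling
#' widths. `no_fft` computes attention from the spatial features
#' (spatial-attention ablation; identical parameter count to `base`
#' because the transform is parameter-free) and `no_attention` removes the
#' attention gate entirely (fewer parameters).
#'
#' @param name one of `base`, `wide_channels`, `deep_4level`,
#'   `deep_and_wide`, `no_fft`, `no_attention`.
#' @param inChannels 1 or 3.
#' @param channels optional width override (length `levels + 1`).
#' @param seed initialisation seed.
#' @return a [FRUNet-class] model.
#' @export
buildVariant <- function(name, inChannels = 1L, channels = NULL, seed = 1L) {
  cfg <- switch(name,
    base = modelConfig(inChannels = inChannels),
    wide_channels = modelConfig(inChannels = inChannels,
                                channels = c(64L, 128L, 256L, 256L)),
    deep_4level = modelConfig(inChannels = inChannels, levels = 4L,
                              channels = rep(64L, 5L)),
    deep_and_wide = modelConfig(inChannels = inChannels, levels = 4L,
                                channels = c(64L, 128L, 256L, 512L, 512L)),
    no_fft = modelConfig(inChannels = inChannels,
                         fca = fcaConfig(useFft = FALSE)),
    no_attention = modelConfig(inChannels = inChannels,
                               fca = fcaConfig(useAttention = FALSE)),
    stop(sprintf("unknown variant '%s'", name), call. = FALSE)
  )
  if (!is.null(channels)) {
    cfg@channels <- as.integer(channels)
    validObject(cfg)
  }
  buildModel(cfg, seed)
}

# ---- forward / backward through the whole network ----

frunetFwd <- function(model, x, training = FALSE, needCache = FALSE) {
  cfg <- model@config
  p <- model@params
  st <- model@state
  x <- as4d(x)
  d <- dim(x)
  if (d[3] != cfg@inChannels) {
    stop(sprintf("model expects %d input channel(s), got %d",
                 cfg@inChannels, d[3]), call. = FALSE)
  }
  div <- 2^cfg@levels
  if (d[1] %% div || d[2] %% div) {
    stop(sprintf(
      "input spatial dimensions (%d x %d) must be divisible by %d (2^levels)",
      d[1], d[2], div), call. = FALSE)
  }
  L <- cfg@levels
  ch <- cfg@channels
  K <- list() # caches
  t0 <- convFwd(x, p$stem, needCache)
  K$stem <- t0$cache
  t <- t0$out
  skips <- vector("list", L)
  K$enc <- vector("list", L)
  K$pool <- vector("list", L)
  K$down <- vector("list", L)
  for (l in seq_len(L)) {
    u <- residualUnitFwd(t, p$enc[[l]]$unit, st$enc[[l]], fcaAt(cfg, ch[l]),
                         training, needCache)
    st$enc[[l]] <- u$state
    K$enc[[l]] <- u$cache
    skips[[l]] <- u$out
    pl <- maxPoolFwd(u$out, needCache)
    K$pool[[l]] <- pl$cache
    t <- pl$out
    if (!is.null(p$down[[l]]$adjust)) {
      a <- convFwd(t, p$down[[l]]$adjust, needCache)
      K$down[[l]] <- a$cache
      t <- a$out
    }
  }
  bu <- residualUnitFwd(t, p$bottleneck$unit, st$bottleneck,
                        fcaAt(cfg, ch[L + 1]), training, needCache)
  st$bottleneck <- bu$state
  K$bottleneck <- bu$cache
  t <- bu$out
  K$dec <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dk <- list()
    if (cfg@upsampleMode == "transposed") {
      upr <- tconvFwd(t, p$dec[[l]]$up, needCache)
      dk$up <- upr$cache
      up <- upr$out
    } else {
      up <- upsampleFwd(t)
    }
    if (cfg@skipFusion == "concat") {
      fused <- abind4(skips[[l]], up)
      dk$splitAt <- dim(skips[[l]])[3]
    } else {
      fused <- up
    }
    fz <- convFwd(fused, p$dec[[l]]$fuse, needCache)
    dk$fuse <- fz$cache
    t <- fz$out
    if (cfg@skipFusion == "add") t <- t + skips[[l]]
    u <- residualUnitFwd(t, p$dec[[l]]$unit, st$dec[[l]], fcaAt(cfg, ch[l]),
                         training, needCache)
    st$dec[[l]] <- u$state
    dk$unit <- u$cache
    t <- u$out
    K$dec[[l]] <- dk
  }
  hd <- convFwd(t, p$head, needCache)
  K$head <- hd$cache
  prob <- sigmoid(hd$out)
  list(prob = prob, caches = if (needCache) K, state = st)
}

abind4 <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# dlogits: gradient of the loss with respect to the pre-sigmoid head output
frunetBwd <- function(model, caches, dlogits) {
  cfg <- model@config
  p <- model@params
  L <- cfg@levels
  ch <- cfg@channels
  g <- list()
  hb <- convBwd(dlogits, caches$head, p$head)
  g$head <- hb$grads
  dt <- hb$dx
  dskips <- vector("list", L)
  g$dec <- vector("list", L)
  for (l in seq_len(L)) { # decoder levels in reverse build order
    dk <- caches$dec[[l]]
    gu <- residualUnitBwd(dt, dk$unit, p$dec[[l]]$unit, fcaAt(cfg, ch[l]))
    dt <- gu$dx
    if (cfg@skipFusion == "add") {
      dskips[[l]] <- dt
    }
    gf <- convBwd(dt, dk$fuse, p$dec[[l]]$fuse)
    if (cfg@skipFusion == "concat") {
      sA <- dk$splitAt
      dskips[[l]] <- gf$dx[, , seq_len(sA), , drop = FALSE]
      dup <- gf$dx[, , -seq_len(sA), , drop = FALSE]
    } else {
      dup <- gf$dx
    }
    if (cfg@upsampleMode == "transposed") {
      gup <- tconvBwd(dup, dk$up, p$dec[[l]]$up)
      dt <- gup$dx
      g$dec[[l]] <- list(up = gup$grads, fuse = gf$grads, unit = gu$grads)
    } else {
      dt <- upsampleBwd(dup)
      g$dec[[l]] <- list(up = NULL, fuse = gf$grads, unit = gu$grads)
    }
  }
  gb <- residualUnitBwd(dt, caches$bottleneck, p$bottleneck$unit,
                        fcaAt(cfg, ch[L + 1]))
  g$bottleneck <- list(unit = gb$grads)
  dt <- gb$dx
  g$enc <- vector("list", L)
  g$down <- vector("list", L)
  for (l in rev(seq_len(L))) {
    if (!is.null(p$down[[l]]$adjust)) {
      ga <- convBwd(dt, caches$down[[l]], p$down[[l]]$adjust)
      g$down[[l]] <- list(adjust = ga$grads)
      dt <- ga$dx
    } else {
      g$down[[l]] <- list(adjust = NULL)
    }
    dunit <- maxPoolBwd(dt, caches$pool[[l]]) + dskips[[l]]
    gu <- residualUnitBwd(dunit, caches$enc[[l]], p$enc[[l]]$unit,
                          fcaAt(cfg, ch[l]))
    g$enc[[l]] <- list(unit = gu$grads)
    dt <- gu$dx
  }
  gs <- convBwd(dt, caches$stem, p$stem)
  g$stem <- gs$grads
  # reorder to match params layout
  g[names(model@params)]
}

#' Forward inference to a probability map
#'
#' Runs the network in inference mode (batch normalisation uses running
#' statistics), returning the per-pixel foreground probability. The output
#' is deterministic and strictly inside (0,1).
#'
#' @param model a [FRUNet-class] model.
#' @param images array `(row, col, channel, batch)`, intensities in
#'   \[0,1\] (trailing singleton dimensions may be omitted).
#' @return array `(row, col, 1, batch)` of probabilities.
#' @export
predictProb <- function(model, images) {
  frunetFwd(model, images, training = FALSE)$prob
}

#' Predicted binary mask
#'
#' @inheritParams predictProb
#' @param threshold probability cutoff; defaults to the model config's.
#' @return integer array of 0/1 with the input's spatial size.
#' @export
predictMask <- function(model, images, threshold = NULL) {
  thr <- threshold %||% model@config@threshold
  (predictProb(model, images) > thr) * 1L
}

#' @export
#' @describeIn predictProb S4 `predict` method; returns the probability map.
#' @param object a [FRUNet-class] model.
#' @param ... passed on (first element taken as the image batch).
setMethod("predict", "FRUNet", function(object, ...) {
  predictProb(object, ..1)
})

# ---- parameter counting ----

countLeaves <- function(x) {
  if (is.null(x)) return(0L)
  if (is.numeric(x)) return(length(x))
  if (is.list(x)) return(sum(vapply(x, countLeaves, integer(1))))
  0L
}

#' Number of trainable parameters
#'
#' Counts every trainable scalar: convolution kernels and biases and
#' batch-normalisation scale/shift terms. Running statistics are not
#' trainable and are excluded. The count is independent of input
#' resolution and batch size (the network is fully convolutional).
#'
#' @param model a [FRUNet-class] model (or a bare parameter list).
#' @return integer.
#' @export
countParameters <- function(model) {
  if (is(model, "FRUNet")) countLeaves(model@params) else countLeaves(model)
}

# ---- checkpointing ----

configToList <- function(cfg) {
  list(
    inChannels = cfg@inChannels, levels = cfg@levels,
    channels = as.integer(cfg@channels),
    fca = list(gamma = cfg@fca@gamma, useFft = cfg@fca@useFft,
               useAttention = cfg@fca@useAttention,
               applyFftshift = cfg@fca@applyFftshift),
    upsampleMode = cfg@upsampleMode, skipFusion = cfg@skipFusion,
    threshold = cfg@threshold
  )
}

configFromList <- function(x) {
  modelConfig(
    inChannels = x$inChannels, levels = x$levels,
    channels = as.integer(unlist(x$channels)),
    fca = fcaConfig(gamma = x$fca$gamma, useFft = x$fca$useFft,
                    useAttention = x$fca$useAttention,
                    applyFftshift = x$fca$applyFftshift),
    upsampleMode = x$upsampleMode, skipFusion = x$skipFusion,
    threshold = x$threshold
  )
}

flattenTensors <- function(x, prefix = "") {
  if (is.null(x)) return(list())
  if (is.numeric(x)) return(setNames(list(x), prefix))
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste(prefix, nm, sep = "/") else nm
    out <- c(out, flattenTensors(x[[nm]], key))
  }
  out
}

# names in `x` may be synthesised for unnamed list elements
assignTensors <- function(template, tensors, prefix = "") {
  if (is.null(template)) return(NULL)
  if (is.numeric(template)) {
    val <- tensors[[prefix]]
    if (is.null(val)) stop("checkpoint is missing tensor ", prefix)
    dim(val) <- dim(template)
    return(val)
  }
  for (nm in names(template)) {
    key <- if (nzchar(prefix)) paste(prefix, nm, sep = "/") else nm
    template[[nm]] <- assignTensors(template[[nm]], tensors, key)
  }
  template
}

nameLevels <- function(p) {
  # give enc/dec/down list elements stable hierarchical names
  for (f in c("enc", "down", "dec")) {
    if (!is.null(p[[f]]) && is.null(names(p[[f]]))) {
      names(p[[f]]) <- paste0("level", seq_along(p[[f]]))
    }
  }
  p
}

#' Save a model checkpoint
#'
#' Writes a single archive holding every parameter tensor keyed by its
#' hierarchical layer name (e.g. `enc/level1/unit/fca1/conv1/w`), the
#' batch-normalisation running statistics, and the model configuration
#' serialised as YAML.
#'
#' @param model a [FRUNet-class] model.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  obj <- list(
    format = "frunet-checkpoint-1",
    config_yaml = yaml::as.yaml(configToList(model@config)),
    seed = model@seed,
    tensors = flattenTensors(nameLevels(model@params)),
    state = flattenTensors(nameLevels(model@state))
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [saveCheckpoint].
#' @return a [FRUNet-class] model; evaluation of the reloaded model
#'   reproduces the saved model's outputs bitwise.
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "frunet-checkpoint-1")) {
    stop("not a frunet checkpoint: ", path, call. = FALSE)
  }
  cfg <- configFromList(yaml::yaml.load(obj$config_yaml))
  model <- buildModel(cfg, seed = obj$seed)
  model@params <- stripLevelNames(
    assignTensors(nameLevels(model@params), obj$tensors))
  model@state <- stripLevelNames(
    assignTensors(nameLevels(model@state), obj$state))
  model
}

stripLevelNames <- function(p) {
  for (f in c("enc", "down", "dec")) {
    if (!is.null(p[[f]])) names(p[[f]]) <- NULL
  }
  p
}
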
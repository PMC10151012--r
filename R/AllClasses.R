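#' Configuration of a Fourier channel attention block
#'
#' Holds the options that define one FCA block: the channel count it
#' operates on, the exponent applied to the amplitude spectrum, and the
#' ablation switches.
#'
#' @slot channels integer, number of feature channels (NA until bound to a
#'   model level).
#' @slot gamma positive exponent applied elementwise to the amplitude
#'   spectrum. Values below 1 compress the dominant low-frequency
#'   magnitudes, raising the relative contribution of high frequencies.
#' @slot useFft logical; if FALSE the attention weights are computed from
#'   the spatial features directly (spatial-attention ablation).
#' @slot useAttention logical; if FALSE the block is a plain two-convolution
#'   residual block and `useFft` is ignored.
#' @slot applyFftshift logical; recenter the zero-frequency component. The
#'   global-average-pooled attention weights are invariant to this
#'   permutation, so it only matters for spectrum visualisation.
#' @exportClass FcaConfig
setClass("FcaConfig",
  representation(
    channels = "integer",
    gamma = "numeric",
    useFft = "logical",
    useAttention = "logical",
    applyFftshift = "logical"
  ),
  prototype(
    channels = NA_integer_,
    gamma = 0.8,
    useFft = TRUE,
    useAttention = TRUE,
    applyFftshift = TRUE
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@gamma) != 1L || !is.finite(object@gamma) ||
        object@gamma <= 0) {
      msg <- c(msg, "gamma must be a single positive number")
    }
    if (!is.na(object@channels) && object@channels < 1L) {
      msg <- c(msg, "channels must be a positive integer")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Create an FCA block configuration
#'
#' @param channels number of feature channels (may be left `NA` when the
#'   configuration is attached to a model, which binds it per level).
#' @param gamma positive exponent applied to the amplitude spectrum
#'   (default 0.8).
#' @param useFft compute attention from the amplitude spectrum (TRUE) or
#'   from the spatial features (FALSE; ablation variant).
#' @param useAttention enable the attention gate at all; FALSE reduces the
#'   block to a plain two-convolution residual block.
#' @param applyFftshift recenter the zero frequency before the 1x1
#'   convolution.
#' @return an [FcaConfig-class] object.
#' @export
fcaConfig <- function(channels = NA_integer_, gamma = 0.8, useFft = TRUE,
                      useAttention = TRUE, applyFftshift = TRUE) {
  new("FcaConfig",
    channels = as.integer(channels), gamma = as.numeric(gamma),
    useFft = isTRUE(useFft), useAttention = isTRUE(useAttention),
    applyFftshift = isTRUE(applyFftshift)
  )
}

#' Architecture configuration of a FRUNet model
#'
#' @slot inChannels 1 (grayscale) or 3 (RGB) input channels.
#' @slot levels number of 2x2 max-pooling (and mirrored upsampling) stages.
#' @slot channels integer vector of length `levels + 1`: feature widths of
#'   each encoder level followed by the bottleneck width.
#' @slot fca the [FcaConfig-class] shared by every residual unit.
#' @slot upsampleMode `"nearest_conv"` (parameter-free nearest-neighbour
#'   x2 upsampling, the default) or `"transposed"`.
#' @slot skipFusion `"concat"` (channel concatenation followed by a 3x3
#'   width-adjustment convolution, the U-Net convention) or `"add"`.
#' @slot threshold probability cutoff used when binarising the output map.
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(
    inChannels = "integer",
    levels = "integer",
    channels = "integer",
    fca = "FcaConfig",
    upsampleMode = "character",
    skipFusion = "character",
    threshold = "numeric"
  ),
  prototype(
    inChannels = 1L,
    levels = 3L,
    channels = c(64L, 64L, 64L, 64L),
    fca = new("FcaConfig"),
    upsampleMode = "nearest_conv",
    skipFusion = "concat",
    threshold = 0.5
  ),
  validity = function(object) {
    msg <- character()
    if (!object@inChannels %in% c(1L, 3L)) {
      msg <- c(msg, "inChannels must be 1 or 3")
    }
    if (object@levels < 1L) msg <- c(msg, "levels must be >= 1")
    if (length(object@channels) != object@levels + 1L) {
      msg <- c(msg, sprintf(
        "channels must have length levels + 1 = %d (got %d)",
        object@levels + 1L, length(object@channels)
      ))
    }
    if (any(object@channels < 1L)) msg <- c(msg, "channels must be positive")
    if (!object@upsampleMode %in% c("nearest_conv", "transposed")) {
      msg <- c(msg, "upsampleMode must be 'nearest_conv' or 'transposed'")
    }
    if (!object@skipFusion %in% c("concat", "add")) {
      msg <- c(msg, "skipFusion must be 'concat' or 'add'")
    }
    if (object@threshold <= 0 || object@threshold >= 1) {
      msg <- c(msg, "threshold must lie in (0,1)")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Create a model configuration
#'
#' Defaults reproduce the base architecture: three downsampling stages and
#' 64 channels at every hidden layer.
#'
#' @param inChannels 1 for grayscale input, 3 for RGB.
#' @param levels number of downsampling stages (default 3).
#' @param channels feature widths per encoder level plus bottleneck
#'   (length `levels + 1`; default all 64).
#' @param fca an [FcaConfig-class]; its `channels` field is bound per level.
#' @param upsampleMode,skipFusion decoder operators; see
#'   [ModelConfig-class].
#' @param threshold binarisation cutoff for predicted masks (default 0.5).
#' @return a [ModelConfig-class] object.
#' @export
modelConfig <- function(inChannels = 1L, levels = 3L,
                        channels = rep(64L, levels + 1L),
                        fca = fcaConfig(),
                        upsampleMode = "nearest_conv",
                        skipFusion = "concat",
                        threshold = 0.5) {
  new("ModelConfig",
    inChannels = as.integer(inChannels), levels = as.integer(levels),
    channels = as.integer(channels), fca = fca,
    upsampleMode = upsampleMode, skipFusion = skipFusion,
    threshold = as.numeric(threshold)
  )
}

#' A FRUNet segmentation model
#'
#' Container for the architecture configuration, the trainable parameters
#' (a hierarchical named list of arrays) and the non-trainable state
#' (batch-normalisation running statistics).
#'
#' @slot config the [ModelConfig-class].
#' @slot params hierarchical named list of numeric arrays (kernels, biases,
#'   batch-normalisation scale/shift).
#' @slot state hierarchical named list of running means/variances for every
#'   batch-normalisation layer.
#' @slot seed integer seed used for weight initialisation.
#' @exportClass FRUNet
setClass("FRUNet",
  representation(
    config = "ModelConfig",
    params = "list",
    state = "list",
    seed = "integer"
  )
)

#' Training configuration
#'
#' @slot batchSize images per optimisation step (default 2).
#' @slot lrInitial initial Adam learning rate (default 1e-4).
#' @slot lrReduced learning rate after the plateau switch (default 5e-5).
#' @slot plateauPatience consecutive non-improving validation epochs that
#'   trigger the single learning-rate reduction (default 5).
#' @slot plateauTol minimum validation-loss improvement that counts
#'   (default 1e-4).
#' @slot maxEpochs training epoch budget.
#' @slot earlyStopPatience epochs without validation-Dice improvement
#'   before stopping early (default 15).
#' @slot seed master seed for shuffling and initialisation.
#' @slot variant structural/ablation variant name (see [buildVariant]).
#' @slot lossMode `"combined"`, `"bce_only"` or `"dice_only"`.
#' @slot augment apply random geometric augmentation to training batches.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(
    batchSize = "integer",
    lrInitial = "numeric",
    lrReduced = "numeric",
    plateauPatience = "integer",
    plateauTol = "numeric",
    maxEpochs = "integer",
    earlyStopPatience = "integer",
    seed = "integer",
    variant = "character",
    lossMode = "character",
    augment = "logical"
  ),
  prototype(
    batchSize = 2L, lrInitial = 1e-4, lrReduced = 5e-5,
    plateauPatience = 5L, plateauTol = 1e-4, maxEpochs = 30L,
    earlyStopPatience = 15L, seed = 1L, variant = "base",
    lossMode = "combined", augment = FALSE
  ),
  validity = function(object) {
    msg <- character()
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (object@lrReduced >= object@lrInitial) {
      msg <- c(msg, "lrReduced must be smaller than lrInitial")
    }
    if (!object@lossMode %in% c("combined", "bce_only", "dice_only")) {
      msg <- c(msg, "lossMode must be combined, bce_only or dice_only")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Create a training configuration
#'
#' @param batchSize images per step (default 2).
#' @param lrInitial,lrReduced Adam learning rates before/after the plateau
#'   switch (defaults 1e-4 and 5e-5).
#' @param plateauPatience consecutive epochs without validation-loss
#'   improvement that trigger the single reduction (default 5).
#' @param plateauTol improvement below this does not count (default 1e-4).
#' @param maxEpochs epoch budget.
#' @param earlyStopPatience stop after this many epochs without
#'   validation-Dice improvement (default 15).
#' @param seed master seed.
#' @param variant model variant name, see [buildVariant].
#' @param lossMode training objective: combined BCE+Dice (default) or one
#'   of the single-term ablations.
#' @param augment apply random augmentation to training samples.
#' @return a [TrainConfig-class] object.
#' @export
trainConfig <- function(batchSize = 2L, lrInitial = 1e-4, lrReduced = 5e-5,
                        plateauPatience = 5L, plateauTol = 1e-4,
                        maxEpochs = 30L, earlyStopPatience = 15L,
                        seed = 1L, variant = "base", lossMode = "combined",
                        augment = FALSE) {
  new("TrainConfig",
    batchSize = as.integer(batchSize), lrInitial = lrInitial,
    lrReduced = lrReduced, plateauPatience = as.integer(plateauPatience),
    plateauTol = plateauTol, maxEpochs = as.integer(maxEpochs),
    earlyStopPatience = as.integer(earlyStopPatience),
    seed = as.integer(seed), variant = variant, lossMode = lossMode,
    augment = isTRUE(augment)
  )
}

#' Synthetic dataset configuration
#'
#' @slot mode `"nuclei"` (bright ellipses, grayscale), `"dense_nuclei"`
#'   (higher counts, near-contact permitted) or `"glands"` (annular
#'   ring+lumen structures at low contrast, RGB with
#'   hematoxylin--eosin-like tinting).
#' @slot nImages number of images to generate.
#' @slot size image size `(rows, cols)`.
#' @slot objectCountRange inclusive range of objects per image.
#' @slot radiusRange range of object semi-major axes in pixels.
#' @slot contrast foreground-background intensity separation in (0,1].
#' @slot noiseSd standard deviation of the additive Gaussian pixel noise;
#'   the low-frequency background texture amplitude scales with it, so
#'   `noiseSd = 0` yields a flat background.
#' @slot seed integer seed; the dataset is a pure function of the config.
#' @slot allowOverlap permit overlapping object supports.
#' @slot retryCap placement attempts per object before generation fails.
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(
    mode = "character",
    nImages = "integer",
    size = "integer",
    objectCountRange = "integer",
    radiusRange = "numeric",
    contrast = "numeric",
    noiseSd = "numeric",
    seed = "integer",
    allowOverlap = "logical",
    retryCap = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("nuclei", "dense_nuclei", "glands")) {
      msg <- c(msg, "mode must be nuclei, dense_nuclei or glands")
    }
    if (length(object@size) != 2L || any(object@size < 8L)) {
      msg <- c(msg, "size must be two integers >= 8")
    }
    if (max(object@radiusRange) >= min(object@size) / 2) {
      msg <- c(msg, "radiusRange max must be below min(size)/2")
    }
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@contrast <= 0 || object@contrast > 1) {
      msg <- c(msg, "contrast must lie in (0,1]")
    }
    if (diff(object@objectCountRange) < 0) {
      msg <- c(msg, "objectCountRange must be increasing")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Create a synthetic dataset configuration
#'
#' Mode-specific defaults emulate the qualitative character of three
#' public benchmark settings: fields of bright nuclei of varying size and
#' density on a noisy background (grayscale), dense near-contact nuclei,
#' and larger annular gland-like structures with low contrast against an
#' H&E-tinted background (RGB).
#'
#' @param mode `"nuclei"`, `"dense_nuclei"` or `"glands"`.
#' @param nImages number of images.
#' @param size `(rows, cols)`, default `c(64, 64)`.
#' @param objectCountRange objects per image; defaults by mode.
#' @param radiusRange semi-major axis range in pixels; defaults by mode.
#' @param contrast foreground/background separation in (0,1]; defaults by
#'   mode (glands are low-contrast).
#' @param noiseSd additive Gaussian noise sd (default 0.05).
#' @param seed dataset seed.
#' @param allowOverlap permit overlapping objects (defaults TRUE only for
#'   `dense_nuclei`).
#' @param retryCap placement attempts per object (default 200).
#' @return a [SynthConfig-class] object.
#' @export
synthConfig <- function(mode = c("nuclei", "dense_nuclei", "glands"),
                        nImages = 10L, size = c(64L, 64L),
                        objectCountRange = NULL, radiusRange = NULL,
                        contrast = NULL, noiseSd = 0.05, seed = 1L,
                        allowOverlap = NULL, retryCap = 200L) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    nuclei = list(count = c(5L, 15L), radius = c(3, 8), contrast = 0.7,
                  overlap = FALSE),
    dense_nuclei = list(count = c(15L, 30L), radius = c(2, 6),
                        contrast = 0.6, overlap = TRUE),
    glands = list(count = c(2L, 5L), radius = c(8, 16), contrast = 0.3,
                  overlap = FALSE)
  )
  new("SynthConfig",
    mode = mode, nImages = as.integer(nImages), size = as.integer(size),
    objectCountRange = as.integer(objectCountRange %||% defaults$count),
    radiusRange = as.numeric(radiusRange %||% defaults$radius),
    contrast = as.numeric(contrast %||% defaults$contrast),
    noiseSd = as.numeric(noiseSd), seed = as.integer(seed),
    allowOverlap = isTRUE(allowOverlap %||% defaults$overlap),
    retryCap = as.integer(retryCap)
  )
}

setMethod("show", "FcaConfig", function(object) {
  cat(sprintf(
    "FCA block config: channels=%s gamma=%g fft=%s attention=%s fftshift=%s\n",
    ifelse(is.na(object@channels), "?", object@channels), object@gamma,
    object@useFft, object@useAttention, object@applyFftshift
  ))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "FRUNet config: in=%d levels=%d channels=[%s] upsample=%s fusion=%s\n",
    object@inChannels, object@levels,
    paste(object@channels, collapse = ","),
    object@upsampleMode, object@skipFusion
  ))
})

setMethod("show", "FRUNet", function(object) {
  cfg <- object@config
  cat("FRUNet segmentation model\n")
  cat(sprintf(
    "  input channels: %d | levels: %d | widths: [%s]\n",
    cfg@inChannels, cfg@levels, paste(cfg@channels, collapse = ",")
  ))
  cat(sprintf(
    "  FCA: fft=%s attention=%s gamma=%g\n",
    cfg@fca@useFft, cfg@fca@useAttention, cfg@fca@gamma
  ))
  cat(sprintf("  trainable parameters: %d\n", countParameters(object)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
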
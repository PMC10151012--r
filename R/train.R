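# Adam training loop with a single plateau learning-rate reduction,
# best-checkpoint tracking, k-fold cross-validation and the ablation
# driver. Fully seeded: (seed, config, data) determine every epoch.

adamInit <- function(params) {
  list(m = mapLeaves(params, function(a) a * 0),
       v = mapLeaves(params, function(a) a * 0))
}

adamRec <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-7) {
  if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
  if (is.numeric(p)) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    return(list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v))
  }
  for (nm in names(p)) {
    r <- adamRec(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, b1, b2, eps)
    p[[nm]] <- r$p
    m[[nm]] <- r$m
    v[[nm]] <- r$v
  }
  list(p = p, m = m, v = v)
}

stackSamples <- function(samples) {
  d <- dim(samples[[1]]$image)
  n <- length(samples)
  x <- array(0, c(d[1], d[2], d[3], n))
  y <- array(0, c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- samples[[i]]$image
    y[, , 1, i] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

valPass <- function(model, samples, lossMode, threshold, chunk = 8L) {
  n <- length(samples)
  lossSum <- 0
  dice <- numeric(n)
  i <- 1L
  while (i <= n) {
    idx <- i:min(i + chunk - 1L, n)
    b <- stackSamples(samples[idx])
    prob <- frunetFwd(model, b$x, training = FALSE)$prob
    lossSum <- lossSum + lossAndGrad(b$y, prob, lossMode)$loss * length(idx)
    for (k in seq_along(idx)) {
      pred <- (prob[, , , k] > threshold) * 1L
      dice[idx[k]] <- metricsFromCounts(
        confusionCounts(b$y[, , 1, k], pred))[["dice"]]
    }
    i <- i + chunk
  }
  list(loss = lossSum / n, dice = mean(dice))
}

#' Train a FRUNet model
#'
#' Runs Adam (beta 0.9/0.999, epsilon 1e-7) at `cfg@lrInitial`. When the
#' validation loss fails to improve by more than `cfg@plateauTol` for
#' `cfg@plateauPatience` consecutive epochs, the learning rate switches
#' once to `cfg@lrReduced`. The checkpoint with the best validation Dice
#' is saved. Training stops early after `cfg@earlyStopPatience` epochs
#' without validation-Dice improvement. Everything (shuffling,
#' augmentation draws) is driven by `cfg@seed`, so identical inputs give
#' identical per-epoch losses.
#'
#' @param model a [FRUNet-class] model; its input channel count must match
#'   the samples'.
#' @param trainSamples,valSamples non-empty sample lists (all images of
#'   one size).
#' @param cfg a [TrainConfig-class].
#' @param checkpointPath where to write the best checkpoint (default: a
#'   temporary file).
#' @param verbose print one line per epoch.
#' @return list with `log` (data.frame: epoch, train_loss, val_loss,
#'   val_dice, lr), `model` (weights at the best-validation-Dice epoch),
#'   `finalModel`, `checkpointPath`, `bestEpoch`.
#' @export
trainModel <- function(model, trainSamples, valSamples, cfg = trainConfig(),
                       checkpointPath = tempfile(fileext = ".rds"),
                       verbose = FALSE) {
  if (!length(trainSamples) || !length(valSamples)) {
    stop("training and validation sample lists must be non-empty",
         call. = FALSE)
  }
  if (dim(trainSamples[[1]]$image)[3] != model@config@inChannels) {
    stop(sprintf("model expects %d input channel(s) but samples have %d",
                 model@config@inChannels,
                 dim(trainSamples[[1]]$image)[3]), call. = FALSE)
  }
  withSeed(cfg@seed, {
    opt <- adamInit(model@params)
    t <- 0L
    lr <- cfg@lrInitial
    reduced <- FALSE
    bestValLoss <- Inf
    plateauBad <- 0L
    bestDice <- -Inf
    diceBad <- 0L
    bestEpoch <- NA_integer_
    log <- vector("list", cfg@maxEpochs)
    n <- length(trainSamples)
    for (epoch in seq_len(cfg@maxEpochs)) {
      perm <- sample(n)
      losses <- numeric(0)
      i <- 1L
      while (i <= n) {
        idx <- perm[i:min(i + cfg@batchSize - 1L, n)]
        batch <- trainSamples[idx]
        if (cfg@augment) batch <- lapply(batch, augmentSample)
        b <- stackSamples(batch)
        fw <- frunetFwd(model, b$x, training = TRUE, needCache = TRUE)
        model@state <- fw$state
        lg <- lossAndGrad(b$y, fw$prob, cfg@lossMode)
        dlogits <- lg$dprob * fw$prob * (1 - fw$prob)
        grads <- frunetBwd(model, fw$caches, dlogits)
        t <- t + 1L
        r <- adamRec(model@params, grads, opt$m, opt$v, lr, t)
        model@params <- r$p
        opt$m <- r$m
        opt$v <- r$v
        losses <- c(losses, lg$loss)
        i <- i + cfg@batchSize
      }
      vl <- valPass(model, valSamples, cfg@lossMode, model@config@threshold)
      log[[epoch]] <- data.frame(
        epoch = epoch, train_loss = mean(losses), val_loss = vl$loss,
        val_dice = vl$dice, lr = lr)
      if (verbose) {
        message(sprintf(
          "epoch %3d  train %.4f  val %.4f  dice %.4f  lr %g",
          epoch, mean(losses), vl$loss, vl$dice, lr))
      }
      # plateau schedule: a single reduction
      if (vl$loss < bestValLoss - cfg@plateauTol) {
        bestValLoss <- vl$loss
        plateauBad <- 0L
      } else {
        plateauBad <- plateauBad + 1L
        if (!reduced && plateauBad >= cfg@plateauPatience) {
          lr <- cfg@lrReduced
          reduced <- TRUE
          plateauBad <- 0L
        }
      }
      if (vl$dice > bestDice) {
        bestDice <- vl$dice
        bestEpoch <- epoch
        diceBad <- 0L
        saveCheckpoint(model, checkpointPath)
      } else {
        diceBad <- diceBad + 1L
        if (diceBad >= cfg@earlyStopPatience) break
      }
    }
    list(
      log = do.call(rbind, log[!vapply(log, is.null, logical(1))]),
      model = loadCheckpoint(checkpointPath),
      finalModel = model,
      checkpointPath = checkpointPath,
      bestEpoch = bestEpoch
    )
  })
}

#' Evaluate a model on a sample list
#'
#' Forward pass, binarisation at `threshold`, then the five pixel metrics
#' per image plus a summary row (id `"mean"`, or `"pooled"` when metrics
#' are computed from counts pooled over the whole set).
#'
#' @param model a [FRUNet-class] model.
#' @param samples sample list.
#' @param threshold probability cutoff (default: model config's, 0.5).
#' @param csvPath optional path; the report is written as CSV (one row
#'   per image plus the summary row).
#' @param pooled use pooled confusion counts for the summary row instead
#'   of the per-image mean.
#' @return data.frame with columns id, dice, miou, recall, precision, f1;
#'   attribute `"sd"` holds the per-image standard deviations.
#' @export
evaluateModel <- function(model, samples, threshold = NULL, csvPath = NULL,
                          pooled = FALSE) {
  thr <- threshold %||% model@config@threshold
  rows <- vector("list", length(samples))
  pool <- list(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    prob <- frunetFwd(model, array(s$image, c(dim(s$image), 1L)),
                      training = FALSE)$prob
    pred <- (prob[, , 1, 1] > thr) * 1L
    cc <- confusionCounts(s$mask, pred)
    pool <- Map(`+`, pool, cc)
    m <- metricsFromCounts(cc)
    rows[[i]] <- data.frame(id = s$id, t(m))
  }
  df <- do.call(rbind, rows)
  summary <- if (pooled) {
    data.frame(id = "pooled", t(metricsFromCounts(pool)))
  } else {
    data.frame(id = "mean", t(colMeans(df[, -1])))
  }
  out <- rbind(df, summary)
  attr(out, "sd") <- vapply(df[, -1], stats::sd, numeric(1))
  if (!is.null(csvPath)) write.csv(out, csvPath, row.names = FALSE)
  out
}

#' k-fold cross-validation
#'
#' Partitions the samples into `folds` near-equal folds (deterministic in
#' `cfg@seed`), trains one model per fold from an initialisation seed
#' offset by the fold index, evaluates on the held-out fold, and
#' aggregates the fold means.
#'
#' @param samples sample list.
#' @param cfg a [TrainConfig-class]; `cfg@variant` picks the architecture.
#' @param folds number of folds (default 5).
#' @param inChannels input channels (default inferred from the samples).
#' @return list with `perFold` (data.frame of fold means), `mean` and
#'   `sd` (named vectors over the five metrics), and `reports` (the full
#'   per-fold evaluation tables).
#' @export
crossValidate <- function(samples, cfg = trainConfig(), folds = 5L,
                          inChannels = NULL) {
  if (length(samples) < folds) {
    stop("need at least as many samples as folds", call. = FALSE)
  }
  inCh <- inChannels %||% dim(samples[[1]]$image)[3]
  ids <- seq_along(samples)
  sp <- makeSplits(ids, trainN = length(ids), testN = 0L, kfold = TRUE,
                   seed = cfg@seed, folds = folds)
  reports <- vector("list", folds)
  rows <- vector("list", folds)
  for (k in seq_len(folds)) {
    valIdx <- sp$folds[[k]]
    trIdx <- setdiff(ids, valIdx)
    model <- buildVariant(cfg@variant, inChannels = inCh,
                          seed = cfg@seed + k)
    run <- trainModel(model, samples[trIdx], samples[valIdx], cfg)
    rep <- evaluateModel(run$model, samples[valIdx])
    reports[[k]] <- rep
    rows[[k]] <- data.frame(fold = k,
                            rep[rep$id == "mean", -1, drop = FALSE])
  }
  perFold <- do.call(rbind, rows)
  list(
    perFold = perFold,
    mean = colMeans(perFold[, -1]),
    sd = vapply(perFold[, -1], stats::sd, numeric(1)),
    reports = reports
  )
}

#' Run the ablation suite
#'
#' Trains `{base, no_fft, no_attention}` with the combined loss plus
#' `base` with each single-term loss, under identical train/validation
#' membership, data order and initialisation seeds, and reports one
#' metrics row per condition.
#'
#' @param samples sample list.
#' @param cfg a [TrainConfig-class] shared by every condition.
#' @param valFraction fraction held out for validation/evaluation.
#' @param channels optional width override passed to [buildVariant] (used
#'   for width-reduced desk-scale runs).
#' @return data.frame: condition, variant, loss, dice, miou, recall,
#'   precision, f1.
#' @export
runAblationSuite <- function(samples, cfg = trainConfig(),
                             valFraction = 0.2, channels = NULL) {
  inCh <- dim(samples[[1]]$image)[3]
  ids <- seq_along(samples)
  nVal <- max(1L, round(valFraction * length(ids)))
  sp <- makeSplits(ids, trainN = length(ids) - nVal, testN = nVal,
                   seed = cfg@seed)
  conds <- data.frame(
    variant = c("base", "no_fft", "no_attention", "base", "base"),
    loss = c("combined", "combined", "combined", "bce_only", "dice_only"),
    stringsAsFactors = FALSE
  )
  rows <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    ccfg <- cfg
    ccfg@variant <- conds$variant[i]
    ccfg@lossMode <- conds$loss[i]
    model <- buildVariant(ccfg@variant, inChannels = inCh,
                          channels = channels, seed = cfg@seed)
    run <- trainModel(model, samples[sp$train], samples[sp$test], ccfg)
    rep <- evaluateModel(run$model, samples[sp$test])
    rows[[i]] <- data.frame(
      condition = paste(conds$variant[i], conds$loss[i], sep = "+"),
      variant = conds$variant[i], loss = conds$loss[i],
      rep[rep$id == "mean", -1, drop = FALSE])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
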
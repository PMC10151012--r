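# Training objective: pixelwise binary cross-entropy plus a smoothed Dice
# term, summed. Sums for the Dice term run over the pixels of one image;
# batch values are means of per-image values.

PROB_EPS <- 1e-7

checkMaskPair <- function(y, yhat) {
  if (!identical(dim(as4d(y)), dim(as4d(yhat)))) {
    stop("mask and prediction shapes differ", call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) {
    stop("ground-truth mask must be strictly binary", call. = FALSE)
  }
}

perImage <- function(x, f) {
  x <- as4d(x)
  n <- dim(x)[4]
  vapply(seq_len(n), function(i) f(x[, , , i]), numeric(1))
}

#' Binary cross-entropy loss
#'
#' Pixel mean of `(y-1) log(1-p) - y log(p)`, with the predicted
#' probability clamped to `[1e-7, 1-1e-7]`. Always non-negative.
#'
#' @param y binary ground-truth mask (array, any of 2--4 dimensions).
#' @param yhat predicted probabilities of the same shape.
#' @return scalar loss (batch mean of per-image values).
#' @export
bceLoss <- function(y, yhat) {
  checkMaskPair(y, yhat)
  p <- pmin(pmax(yhat, PROB_EPS), 1 - PROB_EPS)
  mean((y - 1) * log(1 - p) - y * log(p))
}

#' Dice loss
#'
#' `1 - (2 * sum(y*p) + 1) / (sum(y) + sum(p) + 1)` with sums over the
#' pixels of one image; the smoothing constant 1 makes the empty--empty
#' case exact zero. Batch input returns the mean of per-image values.
#'
#' @inheritParams bceLoss
#' @return scalar loss in `[0, 1)`.
#' @export
diceLoss <- function(y, yhat) {
  checkMaskPair(y, yhat)
  y4 <- as4d(y)
  p4 <- as4d(yhat)
  n <- dim(y4)[4]
  vals <- vapply(seq_len(n), function(i) {
    yi <- y4[, , , i]
    pi <- p4[, , , i]
    1 - (2 * sum(yi * pi) + 1) / (sum(yi) + sum(pi) + 1)
  }, numeric(1))
  mean(vals)
}

#' Combined segmentation loss
#'
#' The training objective: sum of binary cross-entropy and Dice losses.
#' `mode` selects the single-term ablation objectives.
#'
#' @inheritParams bceLoss
#' @param mode `"combined"` (default), `"bce_only"` or `"dice_only"`.
#' @return scalar loss.
#' @export
combinedLoss <- function(y, yhat, mode = c("combined", "bce_only",
                                           "dice_only")) {
  mode <- match.arg(mode)
  switch(mode,
    combined = bceLoss(y, yhat) + diceLoss(y, yhat),
    bce_only = bceLoss(y, yhat),
    dice_only = diceLoss(y, yhat)
  )
}

# loss + gradient w.r.t. the probability map, for the training loop
lossAndGrad <- function(y4, p4, mode) {
  d <- dim(y4)
  n <- d[4]
  npx <- d[1] * d[2] * d[3]
  pc <- pmin(pmax(p4, PROB_EPS), 1 - PROB_EPS)
  useBce <- mode %in% c("combined", "bce_only")
  useDice <- mode %in% c("combined", "dice_only")
  loss <- 0
  dprob <- array(0, d)
  if (useBce) {
    loss <- loss + mean((y4 - 1) * log(1 - pc) - y4 * log(pc))
    dprob <- dprob + ((1 - y4) / (1 - pc) - y4 / pc) / (npx * n)
  }
  if (useDice) {
    for (i in seq_len(n)) {
      yi <- y4[, , , i]
      pi <- p4[, , , i]
      num <- 2 * sum(yi * pi) + 1
      den <- sum(yi) + sum(pi) + 1
      loss <- loss + (1 - num / den) / n
      dprob[, , , i] <- dprob[, , , i] - (2 * yi * den - num) / den^2 / n
    }
  }
  list(loss = loss, dprob = dprob)
}
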
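# Reading image/mask pairs, preprocessing (grayscale conversion, resizing,
# [0,1] scaling), geometric augmentation, and deterministic splits.
#
# Directory layout: <root>/images/*.png|tif(f), <root>/masks/*.png|tif(f)
# with matching file stems. Masks are single-channel, foreground at
# maximum intensity; any value above half the dtype maximum maps to 1.

LUMA <- c(0.299, 0.587, 0.114)

imgStems <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE))
  setNames(files, sub("\\.(png|tif|tiff)$", "", files, ignore.case = TRUE))
}

readImageArray <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  d <- dim(a)
  if (length(d) == 2L) dim(a) <- c(d, 1L)
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE] # drop alpha
  a
}

toGrayscale <- function(a) {
  if (dim(a)[3] == 1L) return(a)
  g <- a[, , 1] * LUMA[1] + a[, , 2] * LUMA[2] + a[, , 3] * LUMA[3]
  array(g, c(dim(a)[1:2], 1L))
}

toRgb <- function(a) {
  if (dim(a)[3] == 3L) return(a)
  array(rep(a[, , 1], 3L), c(dim(a)[1:2], 3L))
}

#' Load an image/mask dataset from directories
#'
#' Reads matching PNG/TIFF pairs, scales intensities to `[0,1]` (the image
#' reader divides by the dtype maximum), converts to the requested colour
#' mode (grayscale collapses RGB by the luminance weights 0.299/0.587/0.114),
#' optionally resizes (bilinear for images, nearest-neighbour for masks so
#' they stay binary) and binarises masks at half the intensity maximum.
#'
#' @param imageDir directory of images.
#' @param maskDir directory of masks with matching file stems.
#' @param mode `"grayscale"` or `"rgb"`.
#' @param resizeTo optional `(rows, cols)` target size.
#' @return list of samples sorted by id; each sample is a list with
#'   `image` (array rows x cols x channels), `mask` (binary matrix) and
#'   `id` (the file stem).
#' @export
loadDataset <- function(imageDir, maskDir, mode = c("grayscale", "rgb"),
                        resizeTo = NULL) {
  mode <- match.arg(mode)
  imgs <- imgStems(imageDir)
  msks <- imgStems(maskDir)
  orphans <- c(setdiff(names(imgs), names(msks)),
               setdiff(names(msks), names(imgs)))
  if (length(orphans)) {
    stop("unmatched image/mask stems: ", paste(sort(orphans), collapse = ", "),
         call. = FALSE)
  }
  lapply(names(imgs), function(id) {
    a <- tryCatch(readImageArray(file.path(imageDir, imgs[[id]])),
                  error = function(e) {
                    stop("cannot read image ", file.path(imageDir, imgs[[id]]),
                         ": ", conditionMessage(e), call. = FALSE)
                  })
    m <- readImageArray(file.path(maskDir, msks[[id]]))
    a <- if (mode == "grayscale") toGrayscale(a) else toRgb(a)
    m <- toGrayscale(m)[, , 1]
    if (!is.null(resizeTo)) {
      a <- resizeImage(a, resizeTo, bilinear = TRUE)
      m <- resizeImage(array(m, c(dim(m), 1L)), resizeTo,
                       bilinear = FALSE)[, , 1]
    }
    list(image = pmin(pmax(a, 0), 1), mask = (m > 0.5) * 1L, id = id)
  })
}

resizeImage <- function(a, size, bilinear = TRUE) {
  img <- EBImage::Image(a,
    colormode = if (dim(a)[3] == 3L) "Color" else "Grayscale")
  out <- EBImage::resize(img, w = size[1], h = size[2],
                         filter = if (bilinear) "bilinear" else "none")
  o <- EBImage::imageData(out)
  if (length(dim(o)) == 2L) dim(o) <- c(dim(o), 1L)
  o
}

# reflect an integer index into 1..n (mirror across the borders)
reflectIdx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  j <- ifelse(j < 0, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

# sample a (rows, cols, channels) array at fractional coordinates with
# reflection padding; bilinear or nearest
sampleAt <- function(a, rows, cols, bilinear) {
  d <- dim(a)
  out <- array(0, c(length(rows), d[3]))
  if (bilinear) {
    r0 <- floor(rows)
    c0 <- floor(cols)
    fr <- rows - r0
    fc <- cols - c0
    r0a <- reflectIdx(r0, d[1])
    r1a <- reflectIdx(r0 + 1, d[1])
    c0a <- reflectIdx(c0, d[2])
    c1a <- reflectIdx(c0 + 1, d[2])
    for (ch in seq_len(d[3])) {
      m <- a[, , ch]
      out[, ch] <-
        m[cbind(r0a, c0a)] * (1 - fr) * (1 - fc) +
        m[cbind(r1a, c0a)] * fr * (1 - fc) +
        m[cbind(r0a, c1a)] * (1 - fr) * fc +
        m[cbind(r1a, c1a)] * fr * fc
    }
  } else {
    ra <- reflectIdx(round(rows), d[1])
    ca <- reflectIdx(round(cols), d[2])
    for (ch in seq_len(d[3])) {
      out[, ch] <- a[, , ch][cbind(ra, ca)]
    }
  }
  out
}

#' Randomly augment an image/mask sample
#'
#' Draws, from the current RNG stream: a rotation in `±rotationRange`
#' degrees, a zoom factor in `zoomRange`, shifts up to `±shiftFrac` of
#' each axis, and a horizontal flip with probability `flipProb`. The same
#' geometric transform is applied to image (bilinear) and mask
#' (nearest-neighbour, re-binarised); out-of-frame regions are filled by
#' reflection padding. An optional vertical flip (probability
#' `verticalFlipProb`) is available as an alternative reading of
#' "reflection" as a transform.
#'
#' @param sample a sample as produced by [loadDataset] or
#'   [generateSynthetic].
#' @param rotationRange degrees (default 30).
#' @param zoomRange default `c(0.8, 1.2)`.
#' @param shiftFrac default 0.1.
#' @param flipProb horizontal flip probability (default 0.5).
#' @param verticalFlipProb default 0.
#' @return an augmented sample with unchanged shapes and a binary mask.
#' @export
augmentSample <- function(sample, rotationRange = 30,
                          zoomRange = c(0.8, 1.2), shiftFrac = 0.1,
                          flipProb = 0.5, verticalFlipProb = 0) {
  img <- sample$image
  d <- dim(img)
  theta <- runif(1, -rotationRange, rotationRange) * pi / 180
  zoom <- runif(1, zoomRange[1], zoomRange[2])
  shift <- c(runif(1, -shiftFrac, shiftFrac) * d[1],
             runif(1, -shiftFrac, shiftFrac) * d[2])
  hflip <- runif(1) < flipProb
  vflip <- verticalFlipProb > 0 && runif(1) < verticalFlipProb
  ctr <- (c(d[1], d[2]) + 1) / 2
  grid <- expand.grid(r = seq_len(d[1]), c = seq_len(d[2]))
  # inverse map: output pixel -> source location
  pr <- grid$r - ctr[1] - shift[1]
  pc <- grid$c - ctr[2] - shift[2]
  sr <- (cos(-theta) * pr - sin(-theta) * pc) / zoom + ctr[1]
  sc <- (sin(-theta) * pr + cos(-theta) * pc) / zoom + ctr[2]
  identityMap <- theta == 0 && zoom == 1 && all(shift == 0)
  if (identityMap) {
    newImg <- img
    newMask <- sample$mask
  } else {
    newImg <- array(sampleAt(img, sr, sc, bilinear = TRUE), d)
    newMask <- matrix(
      sampleAt(array(sample$mask, c(d[1], d[2], 1L)), sr, sc,
               bilinear = FALSE),
      d[1], d[2])
  }
  if (hflip) { # mirror columns: an exact involution
    newImg <- newImg[, rev(seq_len(d[2])), , drop = FALSE]
    newMask <- newMask[, rev(seq_len(d[2])), drop = FALSE]
  }
  if (vflip) {
    newImg <- newImg[rev(seq_len(d[1])), , , drop = FALSE]
    newMask <- newMask[rev(seq_len(d[1])), , drop = FALSE]
  }
  list(image = pmin(pmax(newImg, 0), 1), mask = (newMask > 0.5) * 1L,
       id = sample$id)
}

#' Deterministic train/validation/test and 5-fold splits
#'
#' Shuffles the ids with the given seed, takes the first `trainN` as
#' training and the next `testN` as test; any remainder becomes the
#' validation set. With `kfold`, the training ids are additionally
#' partitioned into `folds` near-equal folds (sizes differ by at most 1).
#'
#' @param ids character or integer vector of sample ids.
#' @param trainN,testN partition sizes; `trainN + testN` must not exceed
#'   `length(ids)`.
#' @param kfold also produce folds over the training ids.
#' @param seed shuffle seed; identical `(ids, seed)` give identical splits.
#' @param folds number of folds (default 5).
#' @return list with `train`, `val`, `test`, optional `folds` (list of id
#'   vectors) and `seed`.
#' @export
makeSplits <- function(ids, trainN, testN, kfold = FALSE, seed = 1L,
                       folds = 5L) {
  if (trainN + testN > length(ids)) {
    stop(sprintf("cannot split %d ids into %d train + %d test",
                 length(ids), trainN, testN), call. = FALSE)
  }
  perm <- withSeed(seed, sample(ids))
  train <- perm[seq_len(trainN)]
  test <- if (testN > 0) perm[trainN + seq_len(testN)] else perm[0]
  val <- if (trainN + testN < length(ids)) {
    perm[(trainN + testN + 1):length(ids)]
  } else {
    perm[0]
  }
  out <- list(train = train, val = val, test = test, seed = as.integer(seed))
  if (kfold) {
    out$folds <- split(train, rep(seq_len(folds), length.out = trainN))
    names(out$folds) <- paste0("fold", seq_len(folds))
  }
  out
}

#' Persist a split as YAML
#' @param split a split from [makeSplits].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSplits <- function(split, path) {
  yaml::write_yaml(lapply(split, function(x) {
    if (is.list(x)) lapply(x, as.character) else {
      if (length(x) > 1 || is.character(x)) as.character(x) else x
    }
  }), path)
  invisible(path)
}

#' Read a split written by [writeSplits]
#' @param path YAML file.
#' @return the split list.
#' @export
readSplits <- function(path) {
  s <- yaml::read_yaml(path)
  for (f in c("train", "val", "test")) s[[f]] <- as.character(s[[f]])
  s
}
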
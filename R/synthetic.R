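# Seeded synthetic microscopy-like data: bright elliptical nuclei on a
# noisy textured background (grayscale), dense near-contact nuclei, and
# annular gland-like ring+lumen structures at low contrast on an
# H&E-tinted background (RGB). The mask is the exact union of object
# supports and the dataset is a pure function of its configuration.

BG_GRAY <- 0.25 # nuclei background base level
BG_HE <- c(0.90, 0.70, 0.78) # eosin-pink stroma background
WALL_HE <- c(0.45, 0.30, 0.62) # hematoxylin-purple gland wall
LUMEN_HE <- c(0.97, 0.97, 0.97) # near-white lumen

ellipseSupport <- function(rows, cols, cy, cx, a, b, theta) {
  g <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  dr <- g$r - cy
  dc <- g$c - cx
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  matrix(u^2 + v^2 <= 1, rows, cols)
}

smoothNoiseField <- function(rows, cols, sigma) {
  f <- matrix(rnorm(rows * cols), rows, cols)
  f <- EBImage::imageData(EBImage::gblur(EBImage::Image(f), sigma = sigma))
  s <- stats::sd(f)
  if (s > 0) f / s else f
}

# one-pixel 8-neighbourhood dilation (keeps disjoint objects in
# separate connected components)
dilate1 <- function(m) {
  rows <- nrow(m)
  cols <- ncol(m)
  v <- m
  v[-1, ] <- v[-1, ] | m[-rows, ]
  v[-rows, ] <- v[-rows, ] | m[-1, ]
  out <- v
  out[, -1] <- out[, -1] | v[, -cols]
  out[, -cols] <- out[, -cols] | v[, -1]
  out
}

placeObjects <- function(cfg, rows, cols) {
  count <- if (diff(cfg@objectCountRange) == 0) cfg@objectCountRange[1] else {
    sample(cfg@objectCountRange[1]:cfg@objectCountRange[2], 1)
  }
  objs <- list()
  blocked <- matrix(FALSE, rows, cols)
  for (k in seq_len(count)) {
    placed <- FALSE
    for (try in seq_len(cfg@retryCap)) {
      a <- runif(1, cfg@radiusRange[1], cfg@radiusRange[2])
      b <- a / runif(1, 1, 3) # eccentricity at most 3:1
      b <- max(b, 1)
      cy <- runif(1, a + 1, rows - a - 1)
      cx <- runif(1, a + 1, cols - a - 1)
      theta <- runif(1, 0, pi)
      sup <- ellipseSupport(rows, cols, cy, cx, a, b, theta)
      if (cfg@allowOverlap || !any(sup & blocked)) {
        objs[[length(objs) + 1]] <- list(cy = cy, cx = cx, a = a, b = b,
                                         theta = theta, sup = sup)
        if (!cfg@allowOverlap) blocked <- blocked | dilate1(sup)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(
        "synthetic generation failed: could not place object %d of %d within %d attempts (reduce counts or radii, or allow overlap)",
        k, count, cfg@retryCap), call. = FALSE)
    }
  }
  objs
}

renderNuclei <- function(cfg, objs) {
  rows <- cfg@size[1]
  cols <- cfg@size[2]
  mask <- matrix(FALSE, rows, cols)
  img <- matrix(BG_GRAY, rows, cols)
  if (cfg@noiseSd > 0) {
    img <- img + cfg@noiseSd * smoothNoiseField(rows, cols, min(rows, cols) / 8)
  }
  fgBase <- BG_GRAY + cfg@contrast * (1 - BG_GRAY)
  for (o in objs) {
    jitter <- if (cfg@noiseSd > 0) runif(1, 0.9, 1) else 1
    img[o$sup] <- BG_GRAY + jitter * cfg@contrast * (1 - BG_GRAY)
    mask <- mask | o$sup
  }
  if (cfg@noiseSd > 0) img <- img + rnorm(rows * cols, sd = cfg@noiseSd)
  list(image = array(pmin(pmax(img, 0), 1), c(rows, cols, 1L)),
       mask = mask * 1L, fgBase = fgBase)
}

renderGlands <- function(cfg, objs) {
  rows <- cfg@size[1]
  cols <- cfg@size[2]
  mask <- matrix(FALSE, rows, cols)
  img <- array(rep(BG_HE, each = rows * cols), c(rows, cols, 3L))
  if (cfg@noiseSd > 0) {
    tex <- cfg@noiseSd * smoothNoiseField(rows, cols, min(rows, cols) / 8)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + tex
  }
  for (o in objs) {
    outer <- o$sup
    wallFrac <- runif(1, 0.15, 0.30) # wall thickness vs outer radius
    inner <- ellipseSupport(rows, cols, o$cy, o$cx, o$a * (1 - wallFrac),
                            o$b * (1 - wallFrac), o$theta)
    wall <- outer & !inner
    for (ch in 1:3) {
      m <- img[, , ch]
      # `contrast` controls how much the wall separates from the
      # background (the hard, gland-like aspect); the pale lumen stays
      # fully visible, as in H&E tissue
      m[wall] <- BG_HE[ch] + cfg@contrast * (WALL_HE[ch] - BG_HE[ch])
      m[inner] <- LUMEN_HE[ch]
      img[, , ch] <- m
    }
    mask <- mask | outer
  }
  if (cfg@noiseSd > 0) {
    img <- img + rnorm(length(img), sd = cfg@noiseSd)
  }
  list(image = pmin(pmax(img, 0), 1), mask = mask * 1L)
}

#' Generate a seeded synthetic segmentation dataset
#'
#' `nuclei` mode draws bright ellipses (random centres, axes and
#' orientation, eccentricity at most 3:1) on a dark background;
#' `dense_nuclei` uses higher counts with near-contact permitted;
#' `glands` draws larger annular ring+lumen structures at low contrast on
#' an H&E-like tinted RGB background. The background texture is
#' low-frequency smoothed noise whose amplitude scales with `noiseSd`
#' (`noiseSd = 0` gives a flat background), plus iid Gaussian pixel
#' noise. The mask is the exact union of object supports. The dataset is
#' fully determined by the configuration, including its seed.
#'
#' @param cfg a [SynthConfig-class] from [synthConfig].
#' @return list of samples (`image`, `mask`, `id`).
#' @export
generateSynthetic <- function(cfg) {
  validObject(cfg)
  withSeed(cfg@seed, {
    lapply(seq_len(cfg@nImages), function(i) {
      # a stuck layout is redrawn from scratch a few times before the
      # packing is declared infeasible
      objs <- NULL
      for (attempt in seq_len(10L)) {
        objs <- tryCatch(placeObjects(cfg, cfg@size[1], cfg@size[2]),
                         error = function(e) e)
        if (!inherits(objs, "error")) break
      }
      if (inherits(objs, "error")) stop(objs)
      r <- if (cfg@mode == "glands") renderGlands(cfg, objs) else {
        renderNuclei(cfg, objs)
      }
      list(image = r$image, mask = r$mask,
           id = sprintf("%s_%04d", cfg@mode, i))
    })
  })
}

#' Write samples in the on-disk dataset layout
#'
#' Materialises `<root>/images/<id>.png` and `<root>/masks/<id>.png` so
#' the full file-based pipeline ([loadDataset]) can run end-to-end.
#' Masks survive the round trip bitwise.
#'
#' @param samples list of samples.
#' @param root output directory (created if needed).
#' @return `root`, invisibly.
#' @export
writeDataset <- function(samples, root) {
  imgDir <- file.path(root, "images")
  maskDir <- file.path(root, "masks")
  ok <- dir.create(imgDir, recursive = TRUE, showWarnings = FALSE) |
    dir.exists(imgDir)
  if (!ok || !(dir.create(maskDir, showWarnings = FALSE) |
               dir.exists(maskDir))) {
    stop("cannot create dataset directories under ", root, call. = FALSE)
  }
  for (s in samples) {
    a <- s$image
    img <- if (dim(a)[3] == 3L) EBImage::Image(a, colormode = "Color") else {
      EBImage::Image(a[, , 1])
    }
    EBImage::writeImage(img, file.path(imgDir, paste0(s$id, ".png")))
    EBImage::writeImage(EBImage::Image(s$mask * 1.0),
                        file.path(maskDir, paste0(s$id, ".png")))
  }
  invisible(root)
}
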
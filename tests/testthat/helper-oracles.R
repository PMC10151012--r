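# Independent brute-force oracles used across the test files. These stay
# deliberately naive (double loops, direct formulas) so they share no code
# with the implementation they check.

# sliding-window "same" convolution with zero padding, stride 1
naiveConvSame <- function(x, w, b) {
  d <- dim(x) # (H, W, Cin)
  k <- dim(w)[1]
  p <- (k - 1) / 2
  cout <- dim(w)[4]
  out <- array(0, c(d[1], d[2], cout))
  for (co in seq_len(cout)) {
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        acc <- b[co]
        for (ci in seq_len(d[3])) {
          for (di in seq_len(k)) {
            for (dj in seq_len(k)) {
              si <- i + di - 1 - p
              sj <- j + dj - 1 - p
              if (si >= 1 && si <= d[1] && sj >= 1 && sj <= d[2]) {
                acc <- acc + x[si, sj, ci] * w[di, dj, ci, co]
              }
            }
          }
        }
        out[i, j, co] <- acc
      }
    }
  }
  out
}

naiveGelu <- function(x) x * pnorm(x)

# orthonormal 2-D DFT modulus by direct O(N^4) summation
naiveDftMod <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  out <- matrix(0, h, w)
  for (u in seq_len(h)) {
    for (v in seq_len(w)) {
      acc <- 0 + 0i
      for (i in seq_len(h)) {
        for (j in seq_len(w)) {
          acc <- acc + m[i, j] *
            exp(-2i * pi * ((i - 1) * (u - 1) / h + (j - 1) * (v - 1) / w))
        }
      }
      out[u, v] <- Mod(acc) / sqrt(h * w)
    }
  }
  out
}

# per-pixel metric oracle from first principles
oracleMetrics <- function(y, pred) {
  tp <- sum(y * pred)
  fp <- sum((1 - y) * pred)
  fn <- sum(y * (1 - pred))
  tn <- sum((1 - y) * (1 - pred))
  r <- function(n, d) if (d == 0) 1 else n / d
  prec <- r(tp, tp + fp)
  rec <- r(tp, tp + fn)
  c(dice = r(2 * tp, 2 * tp + fp + fn),
    miou = (r(tp, tp + fn + fp) + r(tn, tn + fn + fp)) / 2,
    recall = rec, precision = prec,
    f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
}

randMask <- function(h, w, p = 0.5) {
  matrix(rbinom(h * w, 1, p), h, w)
}

# tiny all-zero FCA parameters (zero kernels and biases)
zeroFcaParams <- function(channels, useAttention = TRUE) {
  p <- withr::with_seed(1, initFcaParams(channels, useAttention))
  frunet:::mapLeaves(p, function(a) a * 0)
}

smallSample <- function(h = 32, w = 32, seed = 1) {
  withr::with_seed(seed, list(
    image = array(runif(h * w), c(h, w, 1L)),
    mask = matrix(rbinom(h * w, 1, 0.3), h, w),
    id = sprintf("s%03d", seed)
  ))
}
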
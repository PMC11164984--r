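# Independent brute-force oracles used to validate the fast implementations.
# These are deliberately naive: direct definitions, explicit loops.

# Otsu: scan every interior histogram-bin edge, compute the between-class
# variance from the raw pixel values, return the lowest maximizer.
bruteOtsu <- function(x, nBins = 256) {
  x <- as.numeric(x)
  r <- range(x)
  edges <- seq(r[1], r[2], length.out = nBins + 1)
  candidates <- edges[-c(1, nBins + 1)]
  best <- -Inf; thr <- NA_real_
  for (t in candidates) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(x)
    bcv <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-15) { best <- bcv; thr <- t }
  }
  thr
}

# Spearman: Pearson on average ranks.
bruteSpearman <- function(x, y)
  cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))

# Kendall tau-b by explicit enumeration of all pairs.
bruteKendall <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Pearson over the masked pixels of one patch, straight from the definition.
bruteMaskedCorr <- function(a, b, mask, rows, cols,
                            method = "pearson", minValid = 15) {
  m <- mask[rows, cols]
  if (sum(m) < minValid) return(NA_real_)
  xs <- a[rows, cols][m]; ys <- b[rows, cols][m]
  if (length(unique(xs)) == 1 || length(unique(ys)) == 1) return(NA_real_)
  cor(xs, ys, method = method)
}

# Closed-form Bayes factor for Gaussian posterior/prior of delta-rho.
gaussianTailBF <- function(postMean, postSd, priorMean, priorSd, t) {
  p1 <- pnorm(t, postMean, postSd, lower.tail = FALSE)
  q1 <- pnorm(t, priorMean, priorSd, lower.tail = FALSE)
  (p1 / (1 - p1)) * ((1 - q1) / q1)
}

# deterministic test image pair with a controllable correlation structure
makeTestImage <- function(seed = 1, H = 64, W = 64, rho = 0.8,
                          name = "fixture") {
  set.seed(seed)
  z1 <- matrix(rnorm(H * W), H, W)
  z2 <- rho * z1 + sqrt(1 - rho^2) * matrix(rnorm(H * W), H, W)
  MultiChannelImage(name, list(pnorm(z1), pnorm(z2)))
}
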
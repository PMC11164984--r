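#' Otsu threshold of one channel
#'
#' Finds the intensity threshold that maximizes the between-class variance
#' (equivalently, minimizes the intra-class variance) of the pixel intensity
#' histogram, segmenting the channel into background (<= threshold) and
#' signal (> threshold). Candidate thresholds are the interior edges of an
#' `nBins`-bin histogram over the observed intensity range; for each
#' candidate the class statistics are computed exactly from the pixel
#' values, and ties are broken toward the lowest maximizing threshold
#' (deterministic, and conservative in keeping pixels as signal).
#'
#' @param raster numeric matrix of intensities in \[0, 1\].
#' @param nBins number of histogram bins (default 256, the 8-bit convention).
#' @return the threshold, a single number strictly inside the observed
#'   intensity range, with attribute `nBins`.
#' @seealso [channelThresholds()], [jointMask()]
#' @export
otsuThreshold <- function(raster, nBins = 256) {
  if (length(raster) == 0L) stop("empty raster")
  if (nBins < 2L) stop("nBins must be >= 2")
  x <- as.numeric(raster)
  r <- range(x)
  if (r[1] == r[2])
    stop("degenerate image: channel is constant (intensity ", r[1],
         "), no threshold separates background from signal")
  edges <- seq(r[1], r[2], length.out = nBins + 1L)
  candidates <- edges[-c(1L, nBins + 1L)]
  # exact class statistics per candidate via sorted cumulative sums
  xs <- sort(x)
  cs <- cumsum(xs)
  n <- length(xs)
  total <- cs[n]
  k <- findInterval(candidates, xs) # pixels <= candidate
  inner <- k > 0L & k < n           # both classes non-empty
  bcv <- rep(-Inf, length(candidates))
  kk <- k[inner]
  mu0 <- cs[kk] / kk
  mu1 <- (total - cs[kk]) / (n - kk)
  w0 <- kk / n
  bcv[inner] <- w0 * (1 - w0) * (mu0 - mu1)^2
  if (!any(is.finite(bcv)))
    stop("degenerate image: no candidate threshold separates two classes")
  thr <- candidates[which.max(bcv)] # which.max takes the first (lowest) tie
  structure(thr, nBins = as.integer(nBins))
}

#' Otsu thresholds for every channel of an image
#'
#' @param image a [MultiChannelImage-class].
#' @param nBins histogram bins passed to [otsuThreshold()].
#' @return data.frame with columns `image`, `channel`, `threshold`, `n_bins`.
#' @export
channelThresholds <- function(image, nBins = 256) {
  k <- nChannels(image)
  thr <- vapply(seq_len(k),
                function(i) as.numeric(otsuThreshold(channelData(image, i),
                                                     nBins)),
                numeric(1))
  data.frame(image = imageName(image), channel = seq_len(k),
             threshold = thr, n_bins = as.integer(nBins))
}

#' Joint above-background mask for a channel pair
#'
#' A pixel is valid iff its intensity is strictly above the Otsu threshold in
#' BOTH analyzed channels; pixels exactly at a threshold count as background.
#'
#' @param image a [MultiChannelImage-class].
#' @param chA,chB the two analyzed channel IDs.
#' @param thresholds per-channel thresholds: a numeric vector indexed by
#'   channel, or a data.frame as returned by [channelThresholds()]. Computed
#'   from the image when omitted.
#' @param nBins histogram bins used when thresholds are computed here.
#' @return logical matrix of the image's dimensions.
#' @export
jointMask <- function(image, chA, chB, thresholds = NULL, nBins = 256) {
  if (chA == chB) stop("the two analyzed channels must be distinct")
  a <- channelData(image, chA)
  b <- channelData(image, chB)
  if (is.null(thresholds)) thresholds <- channelThresholds(image, nBins)
  if (is.data.frame(thresholds)) {
    tv <- thresholds$threshold[match(c(chA, chB), thresholds$channel)]
  } else {
    tv <- thresholds[c(chA, chB)]
  }
  if (any(is.na(tv))) stop("no threshold available for channels ",
                           chA, " and/or ", chB)
  (a > tv[1]) & (b > tv[2])
}
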
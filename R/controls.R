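#' Pixel-wise shuffle control
#'
#' Builds a null-control image by randomly permuting the pixels of each
#' selected channel. Each channel receives its own independent permutation —
#' a shared permutation would preserve the cross-channel association the
#' control is meant to destroy. Pixel multisets (and hence per-channel
#' intensity histograms and Otsu thresholds) are preserved exactly.
#'
#' @param image a [MultiChannelImage-class].
#' @param seed shuffle seed (deterministic output for a fixed seed).
#' @param channels channel IDs to shuffle; others pass through unchanged.
#'   Default: all channels.
#' @return a [MultiChannelImage-class] named `<name>_shuffled`.
#' @export
shufflePixels <- function(image, seed = 1, channels = NULL) {
  if (is.null(channels)) channels <- seq_len(nChannels(image))
  chs <- image@channels
  for (ch in channels) {
    set.seed(substreamSeed(seed, paste0("pixel_", imageName(image), "_", ch)))
    m <- chs[[ch]]
    chs[[ch]] <- matrix(sample(as.numeric(m)), nrow(m), ncol(m))
  }
  MultiChannelImage(paste0(imageName(image), "_shuffled"), chs)
}

#' Block-wise shuffle control
#'
#' Tiles each selected channel into `blockSide x blockSide` blocks and
#' permutes the block positions, leaving block interiors untouched — the
#' default 3x3 blocks retain short-range spatial autocorrelation in the null
#' control, following the block-scrambling approach to colocalization null
#' distributions. Remainder margins (dimensions not divisible by
#' `blockSide`) are left in place so the image keeps its shape. Channels are
#' permuted independently.
#'
#' @inheritParams shufflePixels
#' @param blockSide block side length in pixels (default 3).
#' @return a [MultiChannelImage-class] named `<name>_shuffled`.
#' @export
shuffleBlocks <- function(image, blockSide = 3, seed = 1, channels = NULL) {
  bs <- as.integer(blockSide)
  if (bs < 1L) stop("blockSide must be >= 1")
  d <- dim(image)
  if (any(d < bs))
    stop("image '", imageName(image), "' (", d[1], " x ", d[2],
         ") is smaller than one ", bs, " x ", bs, " block")
  if (is.null(channels)) channels <- seq_len(nChannels(image))
  nbr <- d[1] %/% bs; nbc <- d[2] %/% bs
  if (d[1] %% bs || d[2] %% bs)
    message("block shuffle: remainder margin of ", d[1] %% bs, " row(s) and ",
            d[2] %% bs, " column(s) left unshuffled")
  chs <- image@channels
  for (ch in channels) {
    set.seed(substreamSeed(seed, paste0("block_", imageName(image), "_", ch)))
    perm <- sample.int(nbr * nbc)
    m <- chs[[ch]]
    out <- m
    for (k in seq_len(nbr * nbc)) {
      # destination block k <- source block perm[k] (row-major block order)
      dr <- (k - 1L) %/% nbc; dc <- (k - 1L) %% nbc
      sr <- (perm[k] - 1L) %/% nbc; sc <- (perm[k] - 1L) %% nbc
      out[dr * bs + 1:bs, dc * bs + 1:bs] <- m[sr * bs + 1:bs, sc * bs + 1:bs]
    }
    chs[[ch]] <- out
  }
  MultiChannelImage(paste0(imageName(image), "_shuffled"), chs)
}

#' Generate a shuffled control group
#'
#' One shuffled control image per sample image (N controls for N samples,
#' mirroring a paired design), shuffling only the two analyzed channels.
#'
#' @param group sample [ImageGroup-class].
#' @param mode `"pixel"` or `"block"`.
#' @param blockSide block side for `mode = "block"` (default 3).
#' @param seed master seed.
#' @param channels channel IDs to shuffle (default: the first two).
#' @return an [ImageGroup-class] labelled `<label>_shuffled`.
#' @export
makeControlGroup <- function(group, mode = c("pixel", "block"), blockSide = 3,
                             seed = 1, channels = c(1, 2)) {
  mode <- match.arg(mode)
  imgs <- lapply(groupImages(group), function(im) {
    if (mode == "pixel") shufflePixels(im, seed, channels)
    else shuffleBlocks(im, blockSide, seed, channels)
  })
  ImageGroup(paste0(groupLabel(group), "_shuffled"), imgs)
}
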
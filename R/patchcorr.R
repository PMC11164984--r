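#' Correlation between two intensity vectors
#'
#' Thin wrapper around [stats::cor()] that maps undefined correlations
#' (constant input on either side, length < 2) to `NA` so callers can treat
#' the patch as invalid. Pearson is the product-moment coefficient; Spearman
#' is Pearson on average-ranked data (ties receive their mean rank), which
#' makes it the rank method of choice when many tied intensities are
#' present; Kendall is the tie-corrected tau-b.
#'
#' @param xs,ys equal-length numeric vectors.
#' @param method `"pearson"` (default), `"spearman"`, or `"kendall"`.
#' @return correlation in \[-1, 1\], or `NA` when undefined.
#' @export
correlate <- function(xs, ys, method = c("pearson", "spearman", "kendall")) {
  method <- match.arg(method)
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  if (length(xs) < 2L) return(NA_real_)
  if (anyNA(xs) || anyNA(ys)) return(NA_real_)
  if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
  r <- cor(xs, ys, method = method)
  if (!is.finite(r)) return(NA_real_)
  clip01(r, -1, 1)
}

#' Axis-aligned patch grid over an image
#'
#' Tiles an image into `n x n` equal, non-overlapping patches of
#' `floor(height/n) x floor(width/n)` pixels; trailing remainder rows and
#' columns are excluded from every patch.
#'
#' @param imageDim integer pair `c(height, width)`.
#' @param nPatchesSide patches per side (`1 <= n <= min(imageDim)`).
#' @return data.frame with one row per patch: `row`, `col` (0-based patch
#'   coordinates), `rowStart`, `rowEnd`, `colStart`, `colEnd` (1-based pixel
#'   ranges), plus attributes `droppedRows`/`droppedCols`.
#' @examples
#' g <- patchGrid(c(64, 64), 16)  # 256 patches of 4 x 4
#' nrow(g)
#' @export
patchGrid <- function(imageDim, nPatchesSide) {
  n <- as.integer(nPatchesSide)
  h <- imageDim[1]; w <- imageDim[2]
  if (n < 1L) stop("nPatchesSide must be >= 1")
  if (n > min(h, w))
    stop("nPatchesSide (", n, ") exceeds the smaller image side (",
         min(h, w), ")")
  ph <- h %/% n; pw <- w %/% n
  g <- expand.grid(row = 0:(n - 1L), col = 0:(n - 1L))
  g <- g[order(g$row, g$col), , drop = FALSE]
  rownames(g) <- NULL
  g$rowStart <- g$row * ph + 1L
  g$rowEnd <- (g$row + 1L) * ph
  g$colStart <- g$col * pw + 1L
  g$colEnd <- (g$col + 1L) * pw
  attr(g, "droppedRows") <- h - n * ph
  attr(g, "droppedCols") <- w - n * pw
  g
}

#' Patch-grid correlations under the validity mask
#'
#' For every patch of an `n x n` grid, computes the correlation between the
#' two channels over the valid (above-Otsu-in-both-channels) pixels only —
#' background pixels never enter the correlation. A patch contributes a value
#' only if it holds at least `minValid` valid pixels (default 15); otherwise
#' the cell is `NA`.
#'
#' @param image a [MultiChannelImage-class].
#' @param chA,chB analyzed channel IDs.
#' @param mask logical matrix from [jointMask()] (computed here when `NULL`).
#' @param nPatchesSide patches per image side.
#' @param method correlation method, see [correlate()].
#' @param minValid minimum valid pixels per patch (default 15).
#' @return a [PatchCorrelations-class].
#' @export
patchCorrelations <- function(image, chA = 1, chB = 2, mask = NULL,
                              nPatchesSide = 16,
                              method = c("pearson", "spearman", "kendall"),
                              minValid = 15) {
  method <- match.arg(method)
  a <- channelData(image, chA)
  b <- channelData(image, chB)
  if (is.null(mask)) mask <- jointMask(image, chA, chB)
  if (!identical(dim(mask), dim(a)))
    stop("mask dimensions do not match the image")
  n <- as.integer(nPatchesSide)
  g <- patchGrid(dim(a), n)
  vals <- matrix(NA_real_, n, n)
  for (p in seq_len(nrow(g))) {
    ri <- g$rowStart[p]:g$rowEnd[p]
    ci <- g$colStart[p]:g$colEnd[p]
    m <- mask[ri, ci]
    if (sum(m) >= minValid)
      vals[g$row[p] + 1L, g$col[p] + 1L] <-
        correlate(a[ri, ci][m], b[ri, ci][m], method)
  }
  new("PatchCorrelations", imageName = imageName(image), nPatchesSide = n,
      values = vals, valid = !is.na(vals), method = method)
}

#' Adaptive patch-number search
#'
#' When the requested grid is too fine for the image's foreground (fewer than
#' `minValidPatches` patches pass the minimum-pixel rule), the grid is
#' coarsened by halving (`n, n/2, n/4, ..., 2`) until a configuration with
#' enough valid patches is found. Images for which no configuration succeeds
#' are excluded — reported via a warning and a `NULL` return, never an error.
#'
#' @inheritParams patchCorrelations
#' @param requestedN the grid side asked for (>= 2).
#' @param minValidPatches minimum valid patches an image must contribute
#'   (default 2).
#' @return a [PatchCorrelations-class] (its `nPatchesSide` slot holds the
#'   grid actually used), or `NULL` when the image is excluded.
#' @export
adaptivePatchSearch <- function(image, chA = 1, chB = 2, mask = NULL,
                                requestedN = 16,
                                method = c("pearson", "spearman", "kendall"),
                                minValid = 15, minValidPatches = 2) {
  method <- match.arg(method)
  if (requestedN < 2L) stop("requestedN must be >= 2")
  if (is.null(mask)) mask <- jointMask(image, chA, chB)
  n <- as.integer(requestedN)
  while (n >= 2L) {
    if (n <= min(dim(image))) {
      pc <- patchCorrelations(image, chA, chB, mask, n, method, minValid)
      if (sum(pc@valid) >= minValidPatches) {
        if (n != requestedN)
          warning("ADAPTIVE: image '", imageName(image), "' used ", n,
                  " x ", n, " patches instead of the requested ",
                  requestedN, call. = FALSE)
        return(pc)
      }
    }
    n <- n %/% 2L
  }
  warning("EXCLUDED: image '", imageName(image),
          "' has no patch configuration with >= ", minValidPatches,
          " valid patches", call. = FALSE)
  NULL
}

#' Sliding-window local correlation map
#'
#' Stride-1 square window of `windowSide` pixels; each interior pixel
#' receives the correlation of the valid pixels in the window centred on it,
#' or `NA` when fewer than `minValid` valid pixels fall inside. This is the
#' fine-spatial-scale counterpart of the patch grid; window areas of 10–100
#' square pixels are recommended (the default 7x7 window has 49).
#'
#' Pearson maps are computed with summed-area tables, so the cost is
#' independent of the window size; rank methods evaluate each window
#' directly.
#'
#' @inheritParams patchCorrelations
#' @param windowSide window side length in pixels (odd, >= 3 recommended).
#' @return a [LocalCorrMap-class].
#' @export
localCorrelationMap <- function(image, chA = 1, chB = 2, mask = NULL,
                                windowSide = 7,
                                method = c("pearson", "spearman", "kendall"),
                                minValid = 15) {
  method <- match.arg(method)
  a <- channelData(image, chA)
  b <- channelData(image, chB)
  if (is.null(mask)) mask <- jointMask(image, chA, chB)
  w <- as.integer(windowSide)
  if (w < 2L) stop("windowSide must be >= 2")
  if (any(w > dim(a))) stop("window larger than the image")
  if (w * w < 10 || w * w > 100)
    warning("window area ", w * w,
            " px^2 is outside the recommended 10-100 px^2 band",
            call. = FALSE)
  out <- matrix(NA_real_, nrow(a), ncol(a))
  lo <- (w - 1L) %/% 2L
  hi <- w - 1L - lo
  rows <- (1L + lo):(nrow(a) - hi)
  cols <- (1L + lo):(ncol(a) - hi)
  if (method == "pearson") {
    m <- mask * 1
    am <- a * m; bm <- b * m
    S <- function(x) windowSums(x, w)
    nw <- S(m); Sa <- S(am); Sb <- S(bm)
    Saa <- S(am * a); Sbb <- S(bm * b); Sab <- S(am * b)
    cva <- Saa - Sa * Sa / nw
    cvb <- Sbb - Sb * Sb / nw
    cab <- Sab - Sa * Sb / nw
    den <- sqrt(pmax(cva, 0) * pmax(cvb, 0))
    r <- ifelse(nw >= minValid & den > 1e-12 * pmax(nw, 1), cab / den,
                NA_real_)
    out[rows, cols] <- clip01(r, -1, 1)
  } else {
    for (i in rows) for (j in cols) {
      ri <- (i - lo):(i + hi); ci <- (j - lo):(j + hi)
      mm <- mask[ri, ci]
      if (sum(mm) >= minValid)
        out[i, j] <- correlate(a[ri, ci][mm], b[ri, ci][mm], method)
    }
  }
  new("LocalCorrMap", windowSide = w, values = out, method = method)
}

# Sums of x over every w-by-w window whose top-left corner allows a full
# window, via a summed-area table; returns a matrix indexed by window CENTRE
# (same convention as localCorrelationMap), only centres with full windows.
windowSums <- function(x, w) {
  H <- nrow(x); W <- ncol(x)
  sat <- matrix(0, H + 1L, W + 1L)
  sat[-1L, -1L] <- t(apply(apply(x, 2, cumsum), 1, cumsum))
  i <- 1L:(H - w + 1L); j <- 1L:(W - w + 1L)
  s <- sat[i + w, j + w, drop = FALSE] - sat[i, j + w, drop = FALSE] -
    sat[i + w, j, drop = FALSE] + sat[i, j, drop = FALSE]
  lo <- (w - 1L) %/% 2L
  out <- matrix(NA_real_, H, W)
  out[i + lo, j + lo] <- s
  hi <- w - 1L - lo
  out[(1L + lo):(H - hi), (1L + lo):(W - hi), drop = FALSE]
}

#' Valid patch correlations of a group, per image
#'
#' Convenience collector: runs [adaptivePatchSearch()] on every image of a
#' group and returns the per-image vectors of valid patch correlations,
#' dropping excluded images. Images whose channels defeat thresholding
#' (constant intensity) are excluded with a warning rather than aborting
#' the run.
#'
#' @param group an [ImageGroup-class].
#' @inheritParams adaptivePatchSearch
#' @return list with `corrs` (named list of numeric vectors), `patches`
#'   (named list of [PatchCorrelations-class]), `excluded` (character).
#' @export
groupPatchCorrelations <- function(group, chA = 1, chB = 2, requestedN = 16,
                                   method = "pearson", minValid = 15,
                                   minValidPatches = 2) {
  patches <- list(); corrs <- list(); excluded <- character()
  masks <- list()
  for (im in groupImages(group)) {
    mk <- tryCatch(jointMask(im, chA, chB), error = function(e) {
      warning("EXCLUDED: image '", imageName(im), "': ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(mk)) {
      excluded <- c(excluded, imageName(im))
      next
    }
    pc <- adaptivePatchSearch(im, chA, chB, mk, requestedN, method,
                              minValid, minValidPatches)
    if (is.null(pc)) {
      excluded <- c(excluded, imageName(im))
    } else {
      patches[[imageName(im)]] <- pc
      corrs[[imageName(im)]] <- validCorrelations(pc)
      masks[[imageName(im)]] <- mk
    }
  }
  list(corrs = corrs, patches = patches, masks = masks, excluded = excluded)
}
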
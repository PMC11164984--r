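#' Synthetic patch correlations from the hierarchical model
#'
#' Generative counterpart of the model fitted by [fitModel()]: per-image mean
#' correlations are drawn from a Normal(rhoBar, sigma) truncated to (-1, 1),
#' then patch correlations from a Student-t (df `nu`, scale `sigmaPatch`)
#' around each image mean, clipped to \[-1, 1\]. Used for parameter-recovery
#' studies where the ground truth is known exactly.
#'
#' @param spec a [CorrSynthSpec-class].
#' @return list of `nImages` numeric vectors of length `patchesPerImage`.
#' @export
generateCorrelations <- function(spec) {
  sp <- if (is.na(spec@sigmaPatch)) spec@sigma else spec@sigmaPatch
  set.seed(substreamSeed(spec@seed, "corr_synth"))
  lapply(seq_len(spec@nImages), function(i) {
    rhoI <- rtruncNorm(1, spec@rhoBar, spec@sigma, -1, 1)
    clip01(rhoI + sp * rt(spec@patchesPerImage, df = spec@nu), -1, 1)
  })
}

#' Synthetic two-channel fluorescence image
#'
#' Places `nCells` random disks ("cells") on a dark noisy background. Inside
#' the disks, the two channel intensities are derived from a standard
#' bivariate Gaussian with correlation `rhoTrue` (via its Cholesky factor)
#' and monotone-mapped through the Gaussian CDF into
#' (`foregroundFloor`, 1\] — so the latent foreground correlation is
#' controlled exactly and the realized intensity correlation tracks it
#' closely (the rank-preserving map attenuates Pearson's r by a few
#' percent). The foreground/background intensity separation is bimodal by
#' construction, so Otsu gating recovers the disks.
#'
#' @param spec an [ImageSynthSpec-class].
#' @param name sample identifier of the returned image.
#' @return a two-channel [MultiChannelImage-class], plus attribute
#'   `foreground` (the true foreground mask).
#' @export
generateImagePair <- function(spec, name = "synthimg") {
  set.seed(substreamSeed(spec@seed, "image_synth"))
  H <- spec@height; W <- spec@width
  rmax <- spec@cellRadiusRange[2]
  if (2 * rmax + 2 > min(H, W))
    stop("cell radii too large for the image dimensions")
  fg <- matrix(FALSE, H, W)
  grad <- matrix(0, H, W)
  rowIdx <- matrix(seq_len(H), H, W)
  colIdx <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (k in seq_len(spec@nCells)) {
    r <- runif(1, spec@cellRadiusRange[1], spec@cellRadiusRange[2])
    cy <- runif(1, r + 1, H - r)
    cx <- runif(1, r + 1, W - r)
    d2 <- (rowIdx - cy)^2 + (colIdx - cx)^2
    inside <- d2 <= r^2
    fg <- fg | inside
    # smooth radial ramp (1 at the centre, 0.5 at the rim)
    grad[inside] <- pmax(grad[inside], 1 - 0.5 * sqrt(d2[inside]) / r)
  }
  nf <- sum(fg)
  ch <- list()
  z1 <- rnorm(nf)
  z2 <- spec@rhoTrue * z1 + sqrt(1 - spec@rhoTrue^2) * rnorm(nf)
  f0 <- spec@foregroundFloor
  mk <- function(z) {
    m <- matrix(rnorm(H * W, spec@backgroundLevel, spec@noiseSd), H, W)
    v <- f0 + (1 - f0) * pnorm(z)
    if (spec@gradient) v <- f0 + (1 - f0) * (0.4 * grad[fg] + 0.6 * pnorm(z))
    m[fg] <- v
    clip01(m)
  }
  out <- MultiChannelImage(name, list(mk(z1), mk(z2)))
  attr(out, "foreground") <- fg
  out
}

#' Write a synthetic two-condition dataset to disk
#'
#' Generates `nImages` sample images and `nImages` control images (different
#' true correlations, independent seeds), writes them as 16-bit TIFFs under
#' the channel naming convention into `<dir>/sample` and `<dir>/control`,
#' and records the ground truth in `<dir>/ground_truth.json` — a
#' ready-to-analyze folder pair exercising the full file-based pipeline.
#'
#' @param sampleSpec,controlSpec [ImageSynthSpec-class]s for the two
#'   conditions; their `seed` slots seed image `i` via derived substreams.
#' @param nImages images per condition (default 6).
#' @param dir output directory (created).
#' @return list with `sampleDir`, `controlDir`, `truthFile`.
#' @export
generateConditionPair <- function(sampleSpec, controlSpec, nImages = 6,
                                  dir = tempfile("synthcoloc")) {
  dirs <- list(sampleDir = file.path(dir, "sample"),
               controlDir = file.path(dir, "control"),
               truthFile = file.path(dir, "ground_truth.json"))
  for (cond in c("sample", "control")) {
    spec <- if (cond == "sample") sampleSpec else controlSpec
    folder <- if (cond == "sample") dirs$sampleDir else dirs$controlDir
    for (i in seq_len(nImages)) {
      si <- spec
      si@seed <- substreamSeed(spec@seed, paste0(cond, "_img_", i))
      im <- generateImagePair(si, name = sprintf("%s_%02d", cond, i))
      writeImageChannels(im, folder)
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(nImages = nImages,
         rhoTrueSample = sampleSpec@rhoTrue,
         rhoTrueControl = controlSpec@rhoTrue,
         seedSample = sampleSpec@seed, seedControl = controlSpec@seed),
    dirs$truthFile, auto_unbox = TRUE, digits = NA)
  dirs
}
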
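#' @import methods
#' @importFrom stats cor dnorm pnorm qnorm dcauchy pcauchy qcauchy dexp rexp
#'   rnorm runif rt quantile sd density complete.cases setNames
#' @importFrom utils write.csv read.csv
NULL

#' Multichannel fluorescence image
#'
#' An in-memory representation of one microscopy field of view: one 2-D
#' intensity raster per recorded channel, all of identical dimensions, with
#' intensities normalized to \[0, 1\] by the container bit depth. Channel
#' identifiers are the positions 1..k in the `channels` list (the loader
#' enforces that the `_c<id>` suffixes found on disk are contiguous from 1).
#'
#' @slot name sample identifier (the file name stem before the `_c<id>` suffix).
#' @slot channels list of numeric matrices, one per channel, identical
#'   dimensions, values in \[0, 1\].
#' @export
setClass("MultiChannelImage",
  representation(name = "character", channels = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || is.na(object@name))
      msg <- c(msg, "'name' must be a single string")
    if (length(object@channels) < 1L)
      msg <- c(msg, "at least one channel is required")
    ok <- vapply(object@channels, function(ch)
      is.matrix(ch) && is.numeric(ch) && length(ch) > 0L, logical(1))
    if (!all(ok)) {
      msg <- c(msg, "all channels must be non-empty numeric matrices")
    } else {
      d <- vapply(object@channels, dim, integer(2))
      if (length(object@channels) > 1L && any(d != d[, 1]))
        msg <- c(msg, "all channels must share the same dimensions")
      rng <- range(unlist(lapply(object@channels, range), use.names = FALSE))
      if (rng[1] < 0 || rng[2] > 1)
        msg <- c(msg, "channel intensities must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' Group of images from one biological condition
#'
#' All images of a condition (e.g. sample or control) live in one group; they
#' must agree in channel count so that a common channel pair can be analyzed.
#'
#' @slot label condition name, e.g. `"sample"` or `"control"`.
#' @slot images list of [MultiChannelImage-class] objects.
#' @export
setClass("ImageGroup",
  representation(label = "character", images = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@label) != 1L)
      msg <- c(msg, "'label' must be a single string")
    if (length(object@images) < 1L)
      msg <- c(msg, "an ImageGroup must contain at least one image")
    ok <- vapply(object@images, is, logical(1), class2 = "MultiChannelImage")
    if (!all(ok)) {
      msg <- c(msg, "all elements must be MultiChannelImage objects")
    } else {
      k <- vapply(object@images, function(im) length(im@channels), integer(1))
      if (length(unique(k)) > 1L)
        msg <- c(msg, "all images in a group must have the same channel count")
    }
    if (length(msg)) msg else TRUE
  })

#' Patch-grid correlations for one image
#'
#' Correlation of the two analyzed channels over the above-background pixels
#' of each cell of an n-by-n patch grid. Cells failing the minimum-pixel rule
#' (or with undefined correlation) are invalid and carry `NA`, never 0.
#'
#' @slot imageName sample identifier.
#' @slot nPatchesSide patches per image side (grid is nPatchesSide^2 cells).
#' @slot values numeric matrix of patch correlations; `NA` where invalid.
#' @slot valid logical matrix; `TRUE` where a correlation was computed.
#' @slot method one of `"pearson"`, `"spearman"`, `"kendall"`.
#' @export
setClass("PatchCorrelations",
  representation(imageName = "character", nPatchesSide = "integer",
                 values = "matrix", valid = "matrix", method = "character"),
  validity = function(object) {
    msg <- character()
    n <- object@nPatchesSide
    if (!identical(dim(object@values), c(n, n)) ||
        !identical(dim(object@valid), c(n, n)))
      msg <- c(msg, "'values' and 'valid' must be nPatchesSide x nPatchesSide")
    v <- object@values[object@valid]
    if (length(v) && (any(!is.finite(v)) || any(abs(v) > 1 + 1e-12)))
      msg <- c(msg, "valid correlations must be finite and in [-1, 1]")
    if (any(!is.na(object@values[!object@valid])))
      msg <- c(msg, "invalid cells must be NA")
    if (!object@method %in% c("pearson", "spearman", "kendall"))
      msg <- c(msg, "unknown correlation method")
    if (length(msg)) msg else TRUE
  })

#' Sliding-window local correlation map
#'
#' Stride-1 square-window correlation of the two analyzed channels over valid
#' (above-background-in-both) pixels; `NA` where a window holds fewer than the
#' minimum number of valid pixels or lies outside the image interior.
#'
#' @slot windowSide window side length in pixels.
#' @slot values numeric matrix, same shape as the image.
#' @slot method correlation method used.
#' @export
setClass("LocalCorrMap",
  representation(windowSide = "integer", values = "matrix",
                 method = "character"),
  validity = function(object) {
    v <- object@values[is.finite(object@values)]
    if (length(v) && any(abs(v) > 1 + 1e-12))
      return("defined local correlations must lie in [-1, 1]")
    TRUE
  })

#' Hyperprior specification of the hierarchical model
#'
#' Scales of the truncated Cauchy hyperpriors on the group-level mean
#' correlation (on (-1,1)), the between-image spread sigma and the
#' spread-of-spreads tau (both on (0,1)), and the rate of the exponential
#' prior on the group-level Student-t degrees of freedom.
#'
#' @slot rhoScale Cauchy scale for the group mean correlations (default 0.3).
#' @slot sigmaScale Cauchy scale for sigma (default 0.3).
#' @slot tauScale Cauchy scale for tau (default 0.3).
#' @slot nuRate exponential rate for the group degrees of freedom (default 1).
#' @export
setClass("PriorSpec",
  representation(rhoScale = "numeric", sigmaScale = "numeric",
                 tauScale = "numeric", nuRate = "numeric"),
  prototype(rhoScale = 0.3, sigmaScale = 0.3, tauScale = 0.3, nuRate = 1),
  validity = function(object) {
    if (any(c(object@rhoScale, object@sigmaScale, object@tauScale,
              object@nuRate) <= 0))
      return("all prior scales/rates must be positive")
    TRUE
  })

#' Inference configuration
#'
#' @slot viIterations number of stochastic-gradient steps for the variational
#'   fit (default 10000).
#' @slot posteriorSamples number of posterior draws returned (default 100000).
#' @slot seed master seed; named substreams are derived from it.
#' @slot engine `"vi"` (mean-field ADVI, default) or `"mcmc"` (asymptotically
#'   exact Gibbs/MH sampler via JAGS, used for validation).
#' @export
setClass("FitConfig",
  representation(viIterations = "integer", posteriorSamples = "integer",
                 seed = "integer", engine = "character"),
  prototype(viIterations = 10000L, posteriorSamples = 100000L,
            seed = 42L, engine = "vi"),
  validity = function(object) {
    msg <- character()
    if (object@viIterations < 1L || object@posteriorSamples < 1L)
      msg <- c(msg, "iteration and sample counts must be positive")
    if (!object@engine %in% c("vi", "mcmc"))
      msg <- c(msg, "engine must be 'vi' or 'mcmc'")
    if (length(msg)) msg else TRUE
  })

#' Joint posterior draws of the hierarchical model
#'
#' Columns hold the global parameters (`rho_S`, `rho_C`, `sigma_S`, `sigma_C`,
#' `nu_S`, `nu_C`, `tau_S`, `tau_C`) and the image-level parameters
#' (`rho_I_<cond>_<i>`, `sigma_I_<cond>_<i>`, `nu_I_<cond>_<i>`).
#'
#' @slot draws numeric matrix, one row per draw.
#' @slot nSample number of sample-condition images.
#' @slot nControl number of control-condition images.
#' @slot engine inference engine that produced the draws.
#' @export
setClass("HierarchicalDraws",
  representation(draws = "matrix", nSample = "integer", nControl = "integer",
                 engine = "character"),
  validity = function(object) {
    need <- c("rho_S", "rho_C", "sigma_S", "sigma_C",
              "nu_S", "nu_C", "tau_S", "tau_C")
    if (!all(need %in% colnames(object@draws)))
      return("draws must contain all eight global parameter columns")
    TRUE
  })

#' Result of the Bayes-factor analysis
#'
#' @slot deltaPosterior posterior draws of delta-rho = rho_S - rho_C.
#' @slot deltaPrior prior draws of delta-rho.
#' @slot deltaRho0 hypothesis threshold (default 0.1).
#' @slot bf Bayes factor BF\[H1: delta-rho > delta-rho0 : H0\].
#' @slot bfBound `"none"`, or `"lower"`/`"upper"` when a zero-mass tail made
#'   the Bayes factor a one-sided bound.
#' @slot evidence Lee-Wagenmakers evidence label for `bf`.
#' @slot summaries data.frame of posterior means and equal-tailed credible
#'   intervals for the global parameters and delta-rho.
#' @slot bfCurve data.frame with columns `threshold`, `log10_bf`, `bounded`.
#' @slot fit the [HierarchicalDraws-class] behind the result.
#' @export
setClass("BayesResult",
  representation(deltaPosterior = "numeric", deltaPrior = "numeric",
                 deltaRho0 = "numeric", bf = "numeric", bfBound = "character",
                 evidence = "character", summaries = "data.frame",
                 bfCurve = "data.frame", fit = "ANY"),
  validity = function(object) {
    msg <- character()
    if (object@bf <= 0) msg <- c(msg, "Bayes factor must be positive")
    if (any(abs(object@deltaPosterior) >= 2) ||
        any(abs(object@deltaPrior) >= 2))
      msg <- c(msg, "delta-rho draws must lie in (-2, 2)")
    if (length(msg)) msg else TRUE
  })

#' Specification of a synthetic two-channel image
#'
#' Emulates a two-channel immunofluorescence field: disk-shaped cells with a
#' tunable true foreground intensity correlation on a dark noisy background.
#'
#' @slot height,width image dimensions in pixels (>= 32).
#' @slot nCells number of cell-like disks.
#' @slot cellRadiusRange min/max disk radius in pixels.
#' @slot rhoTrue target latent foreground correlation in (-1, 1).
#' @slot backgroundLevel mean background intensity.
#' @slot noiseSd background Gaussian noise sd.
#' @slot foregroundFloor lowest foreground intensity (keeps the histogram
#'   bimodal so Otsu gating separates signal from background).
#' @slot gradient add a shared radial intensity ramp per cell, introducing
#'   within-cell spatial autocorrelation (used to exercise block shuffles; the
#'   ramp inflates the realized cross-channel correlation).
#' @slot seed generator seed.
#' @export
setClass("ImageSynthSpec",
  representation(height = "integer", width = "integer", nCells = "integer",
                 cellRadiusRange = "numeric", rhoTrue = "numeric",
                 backgroundLevel = "numeric", noiseSd = "numeric",
                 foregroundFloor = "numeric", gradient = "logical",
                 seed = "integer"),
  prototype(height = 256L, width = 256L, nCells = 8L,
            cellRadiusRange = c(12, 30), rhoTrue = 0.7,
            backgroundLevel = 0.05, noiseSd = 0.02,
            foregroundFloor = 0.35, gradient = FALSE, seed = 1L),
  validity = function(object) {
    msg <- character()
    if (object@height < 32L || object@width < 32L)
      msg <- c(msg, "image dimensions must be at least 32 pixels")
    if (abs(object@rhoTrue) >= 1)
      msg <- c(msg, "rhoTrue must lie in (-1, 1)")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
    if (length(object@cellRadiusRange) != 2L ||
        any(object@cellRadiusRange <= 0) ||
        diff(object@cellRadiusRange) < 0)
      msg <- c(msg, "cellRadiusRange must be an increasing positive pair")
    if (length(msg)) msg else TRUE
  })

#' Specification of synthetic patch-correlation data
#'
#' Draws per-image mean correlations from a truncated normal around a true
#' group mean, then patch correlations from a Student-t around each image
#' mean, clipped to \[-1, 1\] — the generative direction of the hierarchical
#' model.
#'
#' @slot rhoBar true group-level mean correlation.
#' @slot sigma between-image sd of the image means.
#' @slot sigmaPatch within-image Student-t scale (defaults to `sigma`).
#' @slot nu Student-t degrees of freedom.
#' @slot nImages number of images.
#' @slot patchesPerImage patch correlations per image.
#' @slot seed generator seed.
#' @export
setClass("CorrSynthSpec",
  representation(rhoBar = "numeric", sigma = "numeric", sigmaPatch = "numeric",
                 nu = "numeric", nImages = "integer",
                 patchesPerImage = "integer", seed = "integer"),
  prototype(rhoBar = 0.6, sigma = 0.1, sigmaPatch = NA_real_, nu = 10,
            nImages = 6L, patchesPerImage = 50L, seed = 1L),
  validity = function(object) {
    msg <- character()
    if (abs(object@rhoBar) >= 1) msg <- c(msg, "rhoBar must be in (-1, 1)")
    if (object@sigma <= 0 || object@sigma >= 1)
      msg <- c(msg, "sigma must be in (0, 1)")
    if (object@nu <= 0) msg <- c(msg, "nu must be positive")
    if (object@nImages < 1L || object@patchesPerImage < 1L)
      msg <- c(msg, "counts must be positive")
    if (length(msg)) msg else TRUE
  })

#' Completed pipeline run
#'
#' Bundle of everything a two-condition colocalization run produced; the input
#' to [renderOutputs()].
#'
#' @slot sample,control the two [ImageGroup-class]s analyzed.
#' @slot samplePatches,controlPatches lists of [PatchCorrelations-class],
#'   parallel to the groups (excluded images absent).
#' @slot localMaps named list of [LocalCorrMap-class] for the sample images.
#' @slot masks named list of joint validity masks (logical matrices, sample
#'   images; control masks under `controlMasks`).
#' @slot controlMasks named list of control-image masks.
#' @slot controlLocalMaps named list of control-image local maps.
#' @slot thresholds data.frame of per-image, per-channel Otsu thresholds.
#' @slot bayes the [BayesResult-class].
#' @slot config echo of the effective run configuration (list).
#' @slot excluded names of images excluded by the adaptive patch search.
#' @export
setClass("ColocRun",
  representation(sample = "ImageGroup", control = "ImageGroup",
                 samplePatches = "list", controlPatches = "list",
                 localMaps = "list", masks = "list",
                 controlMasks = "list", controlLocalMaps = "list",
                 thresholds = "data.frame", bayes = "BayesResult",
                 config = "list", excluded = "character"))

#' Report of files written for a run
#'
#' @slot plotFiles sample-condition plot artifacts: three per sample image
#'   plus three global plots (`3n + 3` files for `n` sample images).
#' @slot controlPlotFiles mirrored per-image plots for the control condition.
#' @slot sidecarFiles CSV/JSON sidecars holding every number shown in a plot.
#' @slot summaryFile path of the machine-readable summary JSON.
#' @slot outDir output directory.
#' @export
setClass("RunReport",
  representation(plotFiles = "character", controlPlotFiles = "character",
                 sidecarFiles = "character", summaryFile = "character",
                 outDir = "character"))
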
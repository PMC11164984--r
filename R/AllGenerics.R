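#' @rdname MultiChannelImage-class
#' @param name sample identifier.
#' @param channels list of numeric matrices in \[0, 1\], identical dimensions.
#' @return a [MultiChannelImage-class].
#' @examples
#' im <- MultiChannelImage("demo", list(matrix(runif(64), 8), matrix(runif(64), 8)))
#' nChannels(im)
#' @export
MultiChannelImage <- function(name, channels) {
  new("MultiChannelImage", name = as.character(name), channels = channels)
}

#' @rdname ImageGroup-class
#' @param label condition name.
#' @param images list of [MultiChannelImage-class]s.
#' @export
ImageGroup <- function(label, images) {
  new("ImageGroup", label = as.character(label), images = images)
}

#' @rdname PriorSpec-class
#' @param rhoScale,sigmaScale,tauScale,nuRate hyperprior scales/rates.
#' @export
PriorSpec <- function(rhoScale = 0.3, sigmaScale = 0.3, tauScale = 0.3,
                      nuRate = 1) {
  new("PriorSpec", rhoScale = rhoScale, sigmaScale = sigmaScale,
      tauScale = tauScale, nuRate = nuRate)
}

#' @rdname FitConfig-class
#' @param viIterations,posteriorSamples,seed,engine see slot documentation.
#' @export
FitConfig <- function(viIterations = 10000, posteriorSamples = 100000,
                      seed = 42, engine = c("vi", "mcmc")) {
  engine <- match.arg(engine)
  new("FitConfig", viIterations = as.integer(viIterations),
      posteriorSamples = as.integer(posteriorSamples),
      seed = as.integer(seed), engine = engine)
}

#' @rdname ImageSynthSpec-class
#' @param height,width,nCells,cellRadiusRange,rhoTrue,backgroundLevel,noiseSd,foregroundFloor,gradient,seed
#'   see slot documentation.
#' @export
ImageSynthSpec <- function(height = 256, width = 256, nCells = 8,
                           cellRadiusRange = c(12, 30), rhoTrue = 0.7,
                           backgroundLevel = 0.05, noiseSd = 0.02,
                           foregroundFloor = 0.35, gradient = FALSE,
                           seed = 1) {
  new("ImageSynthSpec", height = as.integer(height), width = as.integer(width),
      nCells = as.integer(nCells), cellRadiusRange = as.numeric(cellRadiusRange),
      rhoTrue = rhoTrue, backgroundLevel = backgroundLevel, noiseSd = noiseSd,
      foregroundFloor = foregroundFloor, gradient = gradient,
      seed = as.integer(seed))
}

#' @rdname CorrSynthSpec-class
#' @param rhoBar,sigma,sigmaPatch,nu,nImages,patchesPerImage,seed see slot
#'   documentation.
#' @export
CorrSynthSpec <- function(rhoBar = 0.6, sigma = 0.1, sigmaPatch = NA,
                          nu = 10, nImages = 6, patchesPerImage = 50,
                          seed = 1) {
  new("CorrSynthSpec", rhoBar = rhoBar, sigma = sigma,
      sigmaPatch = as.numeric(sigmaPatch), nu = nu,
      nImages = as.integer(nImages),
      patchesPerImage = as.integer(patchesPerImage), seed = as.integer(seed))
}

## ---- accessors ----

#' Accessors for image containers
#'
#' @param x a [MultiChannelImage-class] or [ImageGroup-class].
#' @param i channel or image index.
#' @name image-accessors
NULL

#' @rdname image-accessors
#' @export
setGeneric("imageName", function(x) standardGeneric("imageName"))
#' @rdname image-accessors
#' @export
setMethod("imageName", "MultiChannelImage", function(x) x@name)

#' @rdname image-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname image-accessors
#' @export
setMethod("nChannels", "MultiChannelImage", function(x) length(x@channels))
#' @rdname image-accessors
#' @export
setMethod("nChannels", "ImageGroup", function(x) nChannels(x@images[[1]]))

#' @rdname image-accessors
#' @export
setGeneric("channelData", function(x, i) standardGeneric("channelData"))
#' @rdname image-accessors
#' @export
setMethod("channelData", "MultiChannelImage", function(x, i) {
  i <- as.integer(i)
  if (i < 1L || i > length(x@channels))
    stop("channel ", i, " not present in image '", x@name, "'")
  x@channels[[i]]
})

#' @rdname image-accessors
#' @export
setMethod("dim", "MultiChannelImage", function(x) dim(x@channels[[1]]))

#' @rdname image-accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @rdname image-accessors
#' @export
setMethod("groupLabel", "ImageGroup", function(x) x@label)

#' @rdname image-accessors
#' @export
setGeneric("groupImages", function(x) standardGeneric("groupImages"))
#' @rdname image-accessors
#' @export
setMethod("groupImages", "ImageGroup", function(x) x@images)

#' @rdname image-accessors
#' @export
setMethod("length", "ImageGroup", function(x) length(x@images))

#' @rdname image-accessors
#' @export
setMethod("[[", "ImageGroup", function(x, i) x@images[[i]])

#' Accessors for patch correlations
#'
#' `corrValues` returns the n-by-n correlation grid (`NA` where invalid),
#' `validPatches` the validity grid, `validCorrelations` the vector of
#' computed correlations, `corrMethod` the method, and `nPatchesSide` the
#' grid side.
#'
#' @param x a [PatchCorrelations-class].
#' @name patch-accessors
NULL

#' @rdname patch-accessors
#' @export
setGeneric("corrValues", function(x) standardGeneric("corrValues"))
#' @rdname patch-accessors
#' @export
setMethod("corrValues", "PatchCorrelations", function(x) x@values)
#' @rdname patch-accessors
#' @export
setMethod("corrValues", "LocalCorrMap", function(x) x@values)

#' @rdname patch-accessors
#' @export
setGeneric("validPatches", function(x) standardGeneric("validPatches"))
#' @rdname patch-accessors
#' @export
setMethod("validPatches", "PatchCorrelations", function(x) x@valid)

#' @rdname patch-accessors
#' @export
setGeneric("validCorrelations", function(x) standardGeneric("validCorrelations"))
#' @rdname patch-accessors
#' @export
setMethod("validCorrelations", "PatchCorrelations",
          function(x) x@values[x@valid])

#' @rdname patch-accessors
#' @export
setGeneric("corrMethod", function(x) standardGeneric("corrMethod"))
#' @rdname patch-accessors
#' @export
setMethod("corrMethod", "PatchCorrelations", function(x) x@method)

#' @rdname patch-accessors
#' @export
setGeneric("nPatchesSide", function(x) standardGeneric("nPatchesSide"))
#' @rdname patch-accessors
#' @export
setMethod("nPatchesSide", "PatchCorrelations", function(x) x@nPatchesSide)

#' Accessors for fit results
#'
#' `posteriorDraws` returns the draw matrix; `globalDraws` only the eight
#' global parameter columns; `deltaRho` the draws of the group difference
#' `rho_S - rho_C`; `bayesFactor` the Bayes factor of a result.
#'
#' @param x a [HierarchicalDraws-class] or [BayesResult-class].
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))
#' @rdname fit-accessors
#' @export
setMethod("posteriorDraws", "HierarchicalDraws", function(x) x@draws)

#' @rdname fit-accessors
#' @export
setGeneric("globalDraws", function(x) standardGeneric("globalDraws"))
#' @rdname fit-accessors
#' @export
setMethod("globalDraws", "HierarchicalDraws", function(x)
  x@draws[, c("rho_S", "rho_C", "sigma_S", "sigma_C",
              "nu_S", "nu_C", "tau_S", "tau_C"), drop = FALSE])

#' @rdname fit-accessors
#' @export
setGeneric("deltaRho", function(x) standardGeneric("deltaRho"))
#' @rdname fit-accessors
#' @export
setMethod("deltaRho", "HierarchicalDraws",
          function(x) x@draws[, "rho_S"] - x@draws[, "rho_C"])
#' @rdname fit-accessors
#' @export
setMethod("deltaRho", "BayesResult", function(x) x@deltaPosterior)

#' @rdname fit-accessors
#' @export
setGeneric("bayesFactor", function(x) standardGeneric("bayesFactor"))
#' @rdname fit-accessors
#' @export
setMethod("bayesFactor", "BayesResult", function(x) x@bf)

## ---- show methods ----

setMethod("show", "MultiChannelImage", function(object) {
  d <- dim(object)
  cat("MultiChannelImage '", object@name, "': ", length(object@channels),
      " channel(s), ", d[1], " x ", d[2], " px\n", sep = "")
})

setMethod("show", "ImageGroup", function(object) {
  cat("ImageGroup '", object@label, "': ", length(object@images),
      " image(s), ", nChannels(object), " channel(s) each\n", sep = "")
  for (im in object@images)
    cat("  - ", im@name, " (", paste(dim(im), collapse = " x "), ")\n",
        sep = "")
})

setMethod("show", "PatchCorrelations", function(object) {
  cat("PatchCorrelations for '", object@imageName, "': ",
      object@nPatchesSide, " x ", object@nPatchesSide, " grid (",
      object@method, "), ", sum(object@valid), "/",
      length(object@valid), " valid patches\n", sep = "")
})

setMethod("show", "LocalCorrMap", function(object) {
  cat("LocalCorrMap: ", paste(dim(object@values), collapse = " x "),
      " px, window ", object@windowSide, " (", object@method, "), ",
      sum(is.finite(object@values)), " defined pixels\n", sep = "")
})

setMethod("show", "HierarchicalDraws", function(object) {
  cat("HierarchicalDraws: ", nrow(object@draws), " draws (engine=",
      object@engine, "), ", object@nSample, " sample / ", object@nControl,
      " control image(s)\n", sep = "")
  g <- colMeans(globalDraws(object))
  cat("  posterior means: ",
      paste(sprintf("%s=%.3f", names(g), g), collapse = ", "), "\n", sep = "")
})

setMethod("show", "BayesResult", function(object) {
  bnd <- switch(object@bfBound, lower = " (lower bound)",
                upper = " (upper bound)", "")
  cat("BayesResult: BF[H1: delta-rho > ", object@deltaRho0,
      " : H0] = ", format(object@bf, digits = 6), bnd, "\n  ",
      object@evidence, "\n", sep = "")
  s <- object@summaries
  for (p in c("rho_S", "rho_C", "delta_rho")) {
    r <- s[s$parameter == p, ]
    cat(sprintf("  %-9s %.3f  [%.3f; %.3f] %d%% CI\n", p, r$mean, r$lower,
                r$upper, round(100 * r$level)))
  }
})

setMethod("show", "ColocRun", function(object) {
  cat("ColocRun: ", length(object@sample), " sample vs ",
      length(object@control), " control image(s); ",
      length(object@excluded), " excluded\n", sep = "")
  show(object@bayes)
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport in ", object@outDir, ": ", length(object@plotFiles),
      " sample-condition plots (3n + 3), ", length(object@controlPlotFiles),
      " mirrored control plots, ", length(object@sidecarFiles),
      " numeric sidecars\n", sep = "")
})
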
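#' Pipeline configuration
#'
#' Validates and assembles the configuration of a full two-condition run.
#' Exactly one control source must be active: a folder of experimental
#' control images (`controlMode = "images"` with `controlDir`), or a
#' generated shuffle null (`controlMode = "pixel"` or `"block"`, no
#' `controlDir`).
#'
#' @param sampleDir folder of sample-condition channel files.
#' @param controlDir folder of control-condition channel files (only with
#'   `controlMode = "images"`).
#' @param controlMode `"images"`, `"pixel"`, or `"block"`.
#' @param channels the two analyzed channel IDs (distinct).
#' @param nPatches requested patches per image side (default 16).
#' @param method correlation method (default `"pearson"`).
#' @param minValid minimum valid pixels per patch (default 15).
#' @param deltaRho0 Bayes-factor threshold (default 0.1).
#' @param viIterations,posteriorSamples,engine,seed inference settings, see
#'   [FitConfig-class].
#' @param blockSide block side for `controlMode = "block"` (default 3).
#' @param windowSide local-correlation window side (default 7).
#' @param outDir output directory; `NULL` skips artifact rendering.
#' @return a validated configuration list of class `colocConfig`.
#' @export
colocConfig <- function(sampleDir, controlDir = NULL,
                        controlMode = c("images", "pixel", "block"),
                        channels = c(1, 2), nPatches = 16,
                        method = c("pearson", "spearman", "kendall"),
                        minValid = 15, deltaRho0 = 0.1,
                        viIterations = 10000, posteriorSamples = 100000,
                        blockSide = 3, windowSide = 7, seed = 42,
                        outDir = NULL, engine = c("vi", "mcmc")) {
  controlMode <- match.arg(controlMode)
  method <- match.arg(method)
  engine <- match.arg(engine)
  channels <- as.integer(channels)
  if (length(channels) != 2L || channels[1] == channels[2])
    stop("exactly two distinct channels must be analyzed")
  if (controlMode == "images" && is.null(controlDir))
    stop("controlMode 'images' requires controlDir")
  if (controlMode != "images" && !is.null(controlDir))
    stop("pass either controlDir or a shuffle controlMode, not both")
  structure(list(sampleDir = sampleDir, controlDir = controlDir,
                 controlMode = controlMode, channels = channels,
                 nPatches = as.integer(nPatches), method = method,
                 minValid = as.integer(minValid), deltaRho0 = deltaRho0,
                 viIterations = as.integer(viIterations),
                 posteriorSamples = as.integer(posteriorSamples),
                 blockSide = as.integer(blockSide),
                 windowSide = as.integer(windowSide),
                 seed = as.integer(seed), outDir = outDir, engine = engine),
            class = "colocConfig")
}

#' Run the full colocalization pipeline
#'
#' Load both conditions, gate background by per-channel Otsu thresholds,
#' compute masked patch correlations with the adaptive patch search, fit the
#' hierarchical model, compute the Bayes factor at `deltaRho0`, and (when
#' `outDir` is set) render the `3n + 3` plot artifacts with numeric
#' sidecars. Per-image thresholds, adaptive patch changes and exclusions are
#' logged with stable, greppable prefixes (`THRESHOLD:`, `ADAPTIVE:`,
#' `EXCLUDED:`, `WARN:`).
#'
#' @param config a configuration from [colocConfig()].
#' @return a [ColocRun-class] (with the [RunReport-class] attached as
#'   attribute `report` when artifacts were rendered).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "colocConfig"))
    stop("config must be created by colocConfig()")
  chA <- config$channels[1]; chB <- config$channels[2]

  sample <- loadImageGroup(config$sampleDir, "sample")
  control <- switch(config$controlMode,
    images = loadImageGroup(config$controlDir, "control"),
    pixel = makeControlGroup(sample, "pixel", seed = config$seed,
                             channels = config$channels),
    block = makeControlGroup(sample, "block", blockSide = config$blockSide,
                             seed = config$seed, channels = config$channels))
  if (max(config$channels) > nChannels(sample))
    stop("channel ", max(config$channels), " not present in the sample images")

  thresholds <- do.call(rbind, c(
    lapply(groupImages(sample), channelThresholds),
    lapply(groupImages(control), channelThresholds)))
  thresholds$condition <- rep(c("sample", "control"),
                              c(length(sample) * nChannels(sample),
                                length(control) * nChannels(control)))
  for (i in seq_len(nrow(thresholds)))
    message(sprintf("THRESHOLD: %s [%s] channel %d -> %.4f",
                    thresholds$image[i], thresholds$condition[i],
                    thresholds$channel[i], thresholds$threshold[i]))

  sRes <- groupPatchCorrelations(sample, chA, chB, config$nPatches,
                                 config$method, config$minValid)
  cRes <- groupPatchCorrelations(control, chA, chB, config$nPatches,
                                 config$method, config$minValid)
  excluded <- c(sRes$excluded, cRes$excluded)
  if (length(sRes$corrs) == 0L)
    stop("all sample images were excluded; nothing to analyze")
  if (length(cRes$corrs) == 0L)
    stop("all control images were excluded; nothing to analyze")

  fitCfg <- FitConfig(viIterations = config$viIterations,
                      posteriorSamples = config$posteriorSamples,
                      seed = config$seed, engine = config$engine)
  bayes <- bayesColoc(sRes$corrs, cRes$corrs, PriorSpec(), fitCfg,
                      deltaRho0 = config$deltaRho0)

  localMaps <- lapply(names(sRes$patches), function(nm) {
    im <- groupImages(sample)[[match(nm, vapply(groupImages(sample),
                                                imageName, character(1)))]]
    localCorrelationMap(im, chA, chB, sRes$masks[[nm]],
                        config$windowSide, config$method, config$minValid)
  })
  names(localMaps) <- names(sRes$patches)
  ctrlMaps <- lapply(names(cRes$patches), function(nm) {
    im <- groupImages(control)[[match(nm, vapply(groupImages(control),
                                                 imageName, character(1)))]]
    localCorrelationMap(im, chA, chB, cRes$masks[[nm]],
                        config$windowSide, config$method, config$minValid)
  })
  names(ctrlMaps) <- names(cRes$patches)

  run <- new("ColocRun", sample = sample, control = control,
             samplePatches = sRes$patches, controlPatches = cRes$patches,
             localMaps = localMaps, masks = sRes$masks,
             controlMasks = cRes$masks, controlLocalMaps = ctrlMaps,
             thresholds = thresholds, bayes = bayes,
             config = unclass(config)[!vapply(unclass(config), is.null,
                                              logical(1))],
             excluded = excluded)
  if (!is.null(config$outDir))
    attr(run, "report") <- renderOutputs(run, config$outDir)
  run
}
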
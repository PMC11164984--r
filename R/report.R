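# plot helpers -----------------------------------------------------------

corrPalette <- function(n = 101)
  grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))(n)

# draw a correlation grid/map; NA cells grey
plotCorrField <- function(values, main) {
  z <- t(values[rev(seq_len(nrow(values))), , drop = FALSE])
  graphics::par(mar = c(2, 2, 3, 5))
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)),
                  matrix(0, nrow(z), ncol(z)),
                  col = "grey85", axes = FALSE, xlab = "", ylab = "",
                  main = main)
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z,
                  zlim = c(-1, 1), col = corrPalette(), add = TRUE)
  ticks <- seq(-1, 1, by = 0.5)
  graphics::mtext(sprintf("corr: blue -1 .. red +1; grey = not defined"),
                  side = 1, line = 0.5, cex = 0.8)
  invisible(ticks)
}

writeMatrixCsv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  path
}

pngDevice <- function(path, width = 600, height = 600) {
  grDevices::png(path, width = width, height = height)
  path
}

perImageArtifacts <- function(prefix, pc, lmap, mask, imgDir) {
  plots <- character(); sidecars <- character()
  # patched correlation grid
  p <- pngDevice(file.path(imgDir, paste0(prefix, "_patches.png")))
  plotCorrField(corrValues(pc),
                sprintf("%s: %d x %d patch correlations (%s)",
                        pc@imageName, nPatchesSide(pc), nPatchesSide(pc),
                        corrMethod(pc)))
  grDevices::dev.off()
  plots <- c(plots, p)
  sidecars <- c(sidecars, writeMatrixCsv(
    corrValues(pc), file.path(imgDir, paste0(prefix, "_patches.csv"))))
  # local correlation map
  p <- pngDevice(file.path(imgDir, paste0(prefix, "_localcorr.png")))
  plotCorrField(corrValues(lmap),
                sprintf("%s: local correlation (window %d)",
                        pc@imageName, lmap@windowSide))
  grDevices::dev.off()
  plots <- c(plots, p)
  sidecars <- c(sidecars, writeMatrixCsv(
    corrValues(lmap), file.path(imgDir, paste0(prefix, "_localcorr.csv"))))
  # joint above-background mask
  p <- pngDevice(file.path(imgDir, paste0(prefix, "_mask.png")))
  graphics::par(mar = c(2, 2, 3, 2))
  graphics::image(t(mask[rev(seq_len(nrow(mask))), ]) * 1,
                  col = c("black", "white"), axes = FALSE,
                  main = paste0(pc@imageName, ": above-background mask"))
  grDevices::dev.off()
  plots <- c(plots, p)
  sidecars <- c(sidecars, writeMatrixCsv(
    mask * 1L, file.path(imgDir, paste0(prefix, "_mask.csv"))))
  list(plots = plots, sidecars = sidecars)
}

#' Write all artifacts of a completed run
#'
#' Emits the standard output tree: per analyzed sample image a patched
#' correlation map, a local correlation map and a mask overlay (three plots
#' per image), plus three global plots (posterior distributions of all
#' global parameters, prior/posterior of delta-rho with the Bayes factor at
#' the threshold, and the Bayes-factor range curve) — `3n + 3` plot files
#' for `n` analyzed sample images. Control-condition per-image plots are
#' mirrored separately. Every number shown in a plot is also written to a
#' CSV/JSON sidecar (`summary.json`, `posterior_draws.csv`, `bf_curve.csv`,
#' and one CSV per image map), so no plot carries unique data.
#'
#' @param run a [ColocRun-class] from [runPipeline()].
#' @param outDir output directory (created).
#' @return a [RunReport-class].
#' @export
renderOutputs <- function(run, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  imgDir <- file.path(outDir, "images")
  dir.create(imgDir, showWarnings = FALSE)
  plots <- character(); ctrlPlots <- character(); sidecars <- character()

  for (nm in names(run@samplePatches)) {
    art <- perImageArtifacts(nm, run@samplePatches[[nm]],
                             run@localMaps[[nm]], run@masks[[nm]], imgDir)
    plots <- c(plots, art$plots)
    sidecars <- c(sidecars, art$sidecars)
  }
  for (nm in names(run@controlPatches)) {
    art <- perImageArtifacts(paste0("control_", nm),
                             run@controlPatches[[nm]],
                             run@controlLocalMaps[[nm]],
                             run@controlMasks[[nm]], imgDir)
    ctrlPlots <- c(ctrlPlots, art$plots)
    sidecars <- c(sidecars, art$sidecars)
  }

  res <- run@bayes
  g <- globalDraws(res@fit)
  gd <- cbind(g, delta_rho = g[, "rho_S"] - g[, "rho_C"])

  # global plot 1: posterior distributions of all global parameters
  p <- pngDevice(file.path(outDir, "posterior.png"), 900, 600)
  graphics::par(mfrow = c(2, 3), mar = c(4, 4, 3, 1))
  for (par0 in c("rho", "sigma", "tau", "nu")) {
    dS <- density(g[, paste0(par0, "_S")])
    dC <- density(g[, paste0(par0, "_C")])
    graphics::plot(dS, col = "darkorange", lwd = 2, main = par0,
                   xlab = par0, ylim = c(0, max(dS$y, dC$y)))
    graphics::lines(dC, col = "steelblue", lwd = 2)
    graphics::legend("topright", c("sample", "control"),
                     col = c("darkorange", "steelblue"), lwd = 2, bty = "n")
  }
  graphics::plot(density(gd[, "delta_rho"]), lwd = 2, main = "delta rho",
                 xlab = "rho_S - rho_C")
  graphics::abline(v = res@deltaRho0, lty = 2)
  grDevices::dev.off()
  plots <- c(plots, p)

  # global plot 2: prior vs posterior of delta-rho and the Bayes factor
  p <- pngDevice(file.path(outDir, "bf.png"), 700, 500)
  graphics::par(mar = c(4, 4, 3, 1))
  dpo <- density(res@deltaPosterior)
  dpr <- density(res@deltaPrior)
  graphics::plot(dpo, col = "darkorange", lwd = 2,
                 xlim = c(-1.5, 1.5), ylim = c(0, max(dpo$y, dpr$y)),
                 main = sprintf("BF[H1: delta rho > %.2f : H0] = %.4g (%s)",
                                res@deltaRho0, res@bf, res@evidence),
                 xlab = "delta rho")
  graphics::lines(dpr, col = "grey40", lwd = 2)
  graphics::abline(v = res@deltaRho0, lty = 2)
  graphics::legend("topleft", c("posterior", "prior"),
                   col = c("darkorange", "grey40"), lwd = 2, bty = "n")
  grDevices::dev.off()
  plots <- c(plots, p)

  # global plot 3: Bayes-factor range curve
  p <- pngDevice(file.path(outDir, "bf_range.png"), 700, 500)
  graphics::par(mar = c(4, 4, 3, 1))
  graphics::plot(res@bfCurve$threshold, res@bfCurve$log10_bf, type = "b",
                 pch = 16, xlab = "delta rho threshold",
                 ylab = "log10 Bayes factor",
                 main = "Bayes factor vs threshold")
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = res@deltaRho0, lty = 2)
  grDevices::dev.off()
  plots <- c(plots, p)

  # numeric sidecars
  f <- file.path(outDir, "posterior_draws.csv")
  utils::write.csv(as.data.frame(gd), f, row.names = FALSE)
  sidecars <- c(sidecars, f)
  f <- file.path(outDir, "bf_curve.csv")
  utils::write.csv(res@bfCurve, f, row.names = FALSE)
  sidecars <- c(sidecars, f)

  summaryFile <- file.path(outDir, "summary.json")
  jsonlite::write_json(list(
    settings = run@config,
    thresholds = run@thresholds,
    bf = res@bf,
    bf_bound = res@bfBound,
    evidence = res@evidence,
    delta_rho0 = res@deltaRho0,
    posterior_summary = res@summaries,
    bf_curve = res@bfCurve,
    excluded_images = run@excluded,
    n_sample_images = length(run@samplePatches),
    n_control_images = length(run@controlPatches),
    plot_files = basename(plots),
    control_plot_files = basename(ctrlPlots)
  ), summaryFile, auto_unbox = TRUE, digits = NA)
  sidecars <- c(sidecars, summaryFile)

  new("RunReport", plotFiles = plots, controlPlotFiles = ctrlPlots,
      sidecarFiles = sidecars, summaryFile = summaryFile, outDir = outDir)
}
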
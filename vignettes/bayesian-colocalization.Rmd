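---
title: "Bayesian colocalization analysis of two-channel fluorescence images"
author: "BayesColoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian colocalization analysis of two-channel fluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BayesColoc)
```

## The problem

Colocalization — the spatial overlap of two fluorescently labelled molecular
species — is usually quantified by correlating pixel intensities between two
channels. Two well-known difficulties make the naive approach unreliable.
First, background pixels dilute the correlation: including them
systematically lowers the measured colocalization, and manual background
annotation is slow and subjective. Second, pixel intensities are spatially
autocorrelated, so treating pixels (or even image patches) as independent
replicates in a t-test exaggerates certainty. BayesColoc addresses both:
background is removed automatically with per-channel Otsu thresholds, and
inference happens in a hierarchical Bayesian model that separates
within-image from between-image variability, comparing the sample condition
against a control condition rather than against an abstract zero.

## The pipeline

1. **Loading.** Each channel of an image is a separate file named
   `[image name]_c[channel ID].[tiff|tif|jpg|jpeg|png]`; all images of one
   biological condition live in one folder. Intensities are rescaled to
   [0, 1] by the container bit depth (not by the observed maximum), so
   thresholds remain comparable across images captured with identical
   settings. RGB files are collapsed to a single plane by luminance with a
   warning; channel IDs must be contiguous from 1, and gaps are errors
   rather than silently renumbered.

2. **Background gating.** For each channel, the Otsu threshold maximizes
   the between-class variance of the intensity histogram. We use 256
   histogram bins by default (the 8-bit convention), compute class
   statistics exactly from the pixel values at every interior bin edge,
   break ties toward the lowest maximizing threshold (deterministic, and
   conservative in the sense of keeping more pixels as signal), and treat
   pixels exactly at the threshold as background (strict `>`). A pixel is
   *valid* when it is above threshold in **both** analyzed channels.

3. **Patch correlations.** The image is tiled into an `n × n` grid
   (default 16) of equal patches (`floor` division; remainder rows/columns
   are dropped rather than merged, keeping patches equal-area so their
   correlations are exchangeable, as the hierarchical likelihood assumes).
   Within each patch, the correlation — Pearson, Spearman (average ranks,
   the rank method of choice under many ties), or Kendall tau-b
   (tie-corrected) — is computed over the valid pixels only. A patch
   contributes a value only if it has at least 15 valid pixels. If fewer
   than 2 patches of an image are valid, the grid is coarsened by halving
   (`n, n/2, …, 2`); an image with no workable configuration is excluded
   with a warning, never an error. The choice of halving and the 2-patch
   floor are our own (any fixed, terminating schedule would do; halving is
   reproducible and fast), as is the decision to correlate masked pixels
   only — background removal is the stated purpose of the gating, so
   letting background pixels into a qualifying patch would defeat it.

4. **Controls.** If no experimental control images exist, null controls
   are generated from the sample images by shuffling: pixel-wise, or
   block-wise with 3 × 3 blocks, which retains short-range autocorrelation
   in the null. Each of the two analyzed channels receives an
   *independent* permutation — a shared permutation would preserve exactly
   the cross-channel association the control must destroy. Remainder
   margins are left unshuffled so the image keeps its shape; one control
   is generated per sample image, mirroring a paired design.

5. **Hierarchical model.** Per condition $c \in \{S, C\}$:
   $$\bar\rho_c, \sigma_c, \tau_c \sim \mathrm{Cauchy}(0, 0.3)\ \text{truncated to } (-1,1),\ (0,1),\ (0,1);\quad \nu_c \sim \mathrm{Exp}(1)$$
   per image $I$:
   $$\bar\rho_I \sim \mathcal N(\bar\rho_c, \sigma_c)\ \text{on } (-1,1),\quad \sigma_I \sim \mathcal N(\sigma_c, \tau_c)\ \text{on } (0,1),\quad \nu_I \sim \mathrm{Exp}(\text{mean } \nu_c)$$
   and each patch correlation $r \sim \mathrm{StudentT}(\nu_I, \bar\rho_I, \sigma_I)$.
   The heavy-tailed likelihood makes the fit robust to outlier patches.
   $\sigma_c$ is the spread of image means within a condition, $\tau_c$
   the spread of the within-image scales. We read the image-level
   degrees-of-freedom prior as Exponential with *mean* $\nu_c$ (density
   $\nu_c^{-1} e^{-x/\nu_c}$), each image conditioned on its own
   condition's $\nu_c$. The likelihood is deliberately **not** truncated
   to $[-1, 1]$ even though correlations are bounded; the Student-t tails
   absorb boundary effects. $\nu$ is floored at 0.01 inside the likelihood
   for numerical safety (negligible prior mass is affected).

6. **Inference.** The default engine is mean-field ADVI: a fully
   factorized Gaussian in unconstrained space (scaled-logistic bijections
   for interval constraints, log for positivity), optimized by stochastic
   gradient ascent on the ELBO. The gradients of the log joint —
   truncated-Cauchy and truncated-Normal priors included — are analytic,
   and a finite-difference check is part of the test suite. Optimization
   uses Adam (base step 0.05 with a mild 1/(1+5t/T) decay), one Monte-Carlo
   sample per step, and Polyak averaging of the variational parameters over
   the final 25% of iterations; 10,000 iterations and 100,000 posterior
   draws are the defaults. `engine = "mcmc"` runs the identical model
   through JAGS (Gibbs/Metropolis, asymptotically exact) and is used in the
   test suite to validate the variational answers; on our fixtures the two
   engines agree on the group means to well under 0.05. Truncated Cauchy
   and Normal draws use inverse-CDF sampling — exact, rejection-free and
   seed-stable. One master seed derives named substreams for every source
   of randomness, so `mcmc` runs are bit-reproducible and `vi` runs are
   reproducible for a fixed seed.

7. **Evidence.** The hypothesis is a *difference* threshold on
   $\Delta\rho = \bar\rho_S - \bar\rho_C$:
   $$\mathrm{BF}[H_1 : \Delta\rho > \Delta\rho_0 : H_0] =
     \frac{P(\Delta\rho > \Delta\rho_0 \mid \text{data})}
          {P(\Delta\rho \le \Delta\rho_0 \mid \text{data})} \cdot
     \frac{P(\Delta\rho \le \Delta\rho_0)}{P(\Delta\rho > \Delta\rho_0)}$$
   with tail probabilities estimated from posterior draws and from
   Monte-Carlo draws of the prior (the difference of truncated Cauchys has
   no closed form). The default $\Delta\rho_0 = 0.1$ reflects that smaller
   correlation differences are biologically hard to interpret; users may
   raise it for a more stringent test. When a tail holds zero of the $M$
   draws its proportion is replaced by $1/(M+1)$ and the Bayes factor is
   flagged as a one-sided bound. Because the Bayes factor is sensitive to
   $\Delta\rho_0$, a threshold sweep ($\log_{10}$ BF vs threshold) is part
   of every report. Verbal labels follow the Lee–Wagenmakers bands at
   1/3/10/30/100, in both directions. Credible intervals are equal-tailed
   quantile intervals, not HPD intervals.

## Outputs

A two-condition run writes, per analyzed sample image, a patched
correlation map, a sliding-window local correlation map (stride 1, default
window 7 × 7 = 49 px², inside the recommended 10–100 px² band; windows
with fewer than 15 valid pixels are undefined), and the joint
above-background mask — plus three global artifacts: the posterior plot of
all global parameters, the prior/posterior plot of $\Delta\rho$ with the
Bayes factor, and the threshold sweep. That is $3n + 3$ plot files for $n$
sample images; control-image triples are mirrored separately (we read the
per-dataset plot count as counting the sample condition). Every number in
every plot also lands in a CSV/JSON sidecar (`summary.json`,
`posterior_draws.csv`, `bf_curve.csv`, one CSV per map), so plots carry no
unique data.

## The synthetic generator, and what passing tests mean

`generateImagePair()` emulates a two-channel immunofluorescence field:
disk-shaped cells on a dark noisy background, with foreground intensities
built from a latent bivariate Gaussian with a chosen correlation
$\rho_{\text{true}}$ (Cholesky construction) and mapped monotonically into
the intensity range. The map attenuates Pearson's r slightly (for
$\rho_{\text{true}} = 0.8$ the realized foreground correlation is about
0.785); tests assert recovery within ±0.05. The bimodal intensity design
guarantees Otsu gating recovers ≥95% of true foreground pixels.
`generateCorrelations()` skips the pixel level entirely and simulates from
the hierarchical model itself, for parameter-recovery studies with exact
ground truth.

What the generator does **not** emulate: point-spread-function blur,
photon (Poisson) noise, uneven illumination, saturated pixels, nuclei vs
cytoplasm morphology, or channel bleed-through. Passing tests therefore
demonstrate that the statistical machinery recovers known truth under the
model's own assumptions and under a simple, idealized image-formation
model — not that any particular real staining is analyzed correctly.
Image quality, controls, and acquisition settings remain the user's
responsibility.

## Numerical and design choices

- **Histogram bins:** 256; candidate thresholds are interior bin edges;
  class statistics are exact (cumulative sums over sorted pixels), so the
  threshold scales exactly with a global intensity rescaling.
- **Undefined correlations** (constant channel within a patch) are `NA`
  and the patch is invalid — never coerced to 0.
- **Local maps** use summed-area tables for Pearson (cost independent of
  window size); rank methods evaluate windows directly.
- **Problem sizes in the test suite:** the parameter-recovery study runs
  20 replicates of 6 images × 50 patches per condition at
  $\bar\rho_S = 0.6$, $\bar\rho_C = 0$, $\sigma = 0.1$; image-level runs
  use six 256 × 256 images per condition. These sizes give tight Monte
  Carlo error while keeping a full run in minutes on one core.
- **Engine choice in validation:** recovery and coverage are assessed with
  the default VI engine — the one users actually get — and the exact
  sampler serves as an independent cross-check of the variational fit.

## Known limitations

- Only single-plane 2-D images (no z-stacks, time series, or LIF
  containers); exactly two channels are analyzed per run.
- Mean-field VI underestimates posterior correlations between parameters;
  our checks show calibrated group-mean intervals on simulated data, but
  users wanting exact inference can set `engine = "mcmc"`.
- The model treats patch correlations as exchangeable within an image;
  spatial dependence between neighbouring patches is not modelled.
- Manders/overlap coefficients and object-based colocalization are out of
  scope.

## A minimal session

```{r example, eval = FALSE}
d <- generateConditionPair(ImageSynthSpec(rhoTrue = 0.7, seed = 101),
                           ImageSynthSpec(rhoTrue = 0.0, seed = 202),
                           nImages = 6, dir = "fixtures")
cfg <- colocConfig(d$sampleDir, d$controlDir, "images",
                   nPatches = 16, deltaRho0 = 0.1, seed = 7, outDir = "out")
run <- runPipeline(cfg)
run
```
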
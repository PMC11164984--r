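# BayesColoc

Bayesian quantification of colocalization between two fluorescence channels
in multichannel microscopy images.

Colocalization studies ask whether two labelled species (say, two proteins
detected by different antibodies) occupy the same places in a cell.
Correlating raw pixel intensities is fragile: background pixels dilute the
signal, and spatial autocorrelation makes pixel-level t-tests overconfident.
BayesColoc automates the whole analysis for folders of images:

1. **Background gating** — per-channel Otsu thresholds (256-bin histogram,
   exact class statistics, lowest-maximizer tie-break); only pixels above
   threshold in *both* channels enter any correlation.
2. **Patch correlations** — the image is tiled into an n × n grid (default
   16 × 16) and Pearson / Spearman / Kendall tau-b correlations are computed
   over the valid pixels of each patch (≥ 15 valid pixels required; grids
   too fine for the foreground are coarsened automatically by halving).
3. **Null controls** — experimental control images, or controls generated by
   pixel-wise or 3 × 3 block-wise shuffling of the sample images (blocks
   retain short-range autocorrelation; channels get independent
   permutations).
4. **Hierarchical inference** — patch correlations r feed a two-level
   Student-t model. Per condition c ∈ {S, C}:

       rho_c, sigma_c, tau_c ~ Cauchy(0, 0.3) truncated to (-1,1) / (0,1) / (0,1)
       nu_c                  ~ Exponential(1)
       per image I: rho_I ~ N(rho_c, sigma_c) on (-1,1)
                    sigma_I ~ N(sigma_c, tau_c) on (0,1)
                    nu_I ~ Exponential(mean nu_c)
       per patch:   r ~ StudentT(nu_I, rho_I, sigma_I)

   fitted by mean-field ADVI with analytic gradients (a JAGS-based exact
   sampler is available as `engine = "mcmc"` for validation).
5. **Evidence** — a Bayes factor on the group difference
   Δρ = rho_S − rho_C at a threshold Δρ₀ (default 0.1):

       BF[H1: Δρ > Δρ₀ : H0] = P(Δρ > Δρ₀ | data) / P(Δρ ≤ Δρ₀ | data)
                             · P(Δρ ≤ Δρ₀) / P(Δρ > Δρ₀)

   with a threshold-sweep curve (log₁₀ BF vs Δρ₀) and Lee–Wagenmakers
   evidence labels.

Input files follow the convention `[image name]_c[channel ID].[ext]`
(tiff/tif/jpg/jpeg/png), one folder per biological condition. A run on n
sample images emits 3n + 3 plot artifacts (per image: patch map, local
correlation map, mask; plus posterior, Bayes-factor and threshold-sweep
plots), each backed by CSV/JSON sidecars.

## Worked example

Everything is testable without real data via the built-in synthetic
generator (disk-shaped "cells" with a known latent foreground correlation
on a dark noisy background):

```r
library(BayesColoc)

d <- generateConditionPair(ImageSynthSpec(rhoTrue = 0.7, seed = 101),
                           ImageSynthSpec(rhoTrue = 0.0, seed = 202),
                           nImages = 6, dir = "fixtures")
cfg <- colocConfig(d$sampleDir, d$controlDir, "images",
                   nPatches = 16, deltaRho0 = 0.1, seed = 7, outDir = "out")
run <- runPipeline(cfg)
run
```

```
ColocRun: 6 sample vs 6 control image(s); 0 excluded
BayesResult: BF[H1: delta-rho > 0.1 : H0] = 137434 (lower bound)
  extreme evidence for H1
  rho_S     0.653  [0.614; 0.691] 95% CI
  rho_C     -0.003  [-0.069; 0.063] 95% CI
  delta_rho 0.656  [0.579; 0.733] 95% CI
```

Reading: the sample condition's group-level mean patch correlation is
estimated at 0.65 (the generator's latent 0.7 is attenuated slightly by the
monotone intensity mapping), the uncorrelated control sits at ≈ 0, and the
posterior probability that their difference exceeds 0.1 is overwhelming —
"lower bound" means every posterior draw cleared the threshold, so the true
Bayes factor is at least the reported one. `out/` then contains the
3·6 + 3 = 21 plot artifacts, `summary.json`, `posterior_draws.csv` and
`bf_curve.csv`.

The same pipeline is scriptable from a shell via the installed
`exec/coloc` entry point:

```sh
coloc synth --rho 0.7 --rho-control 0.0 --n-images 6 --out fixtures
coloc run --sample-dir fixtures/sample --control-dir fixtures/control \
          --channels 1,2 --patches 16 --delta-rho0 0.1 --seed 42 --out out
# or, without control images:
coloc run --sample-dir fixtures/sample --control-mode block --block-side 3 \
          --out out
```

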
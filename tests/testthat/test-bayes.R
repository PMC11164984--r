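test_that("truncated-Cauchy prior draws match the quadrature oracle", {
  set.seed(61)
  draws <- BayesColoc:::rtruncCauchy(1e5, 0, 0.3, -1, 1)
  expect_true(all(draws > -1 & draws < 1))
  # Kolmogorov distance against a numerically integrated CDF
  Z <- integrate(function(x) dcauchy(x, 0, 0.3), -1, 1)$value
  grid <- seq(-0.99, 0.99, by = 0.02)
  cdf <- vapply(grid, function(q)
    integrate(function(x) dcauchy(x, 0, 0.3), -1, q)$value / Z, numeric(1))
  ecdfv <- ecdf(draws)(grid)
  expect_lt(max(abs(ecdfv - cdf)), 0.01)
})

test_that("prior delta-rho draws are bounded, symmetric and reproducible", {
  d <- samplePriorDeltaRho(PriorSpec(), 1e5, seed = 3)
  expect_true(all(d > -2 & d < 2))
  expect_lt(abs(mean(d > 0) - 0.5), 0.01)
  expect_identical(d, samplePriorDeltaRho(PriorSpec(), 1e5, seed = 3))
})

test_that("the Bayes factor reproduces the posterior/prior odds formula", {
  post <- c(rep(0.5, 75), rep(-0.5, 25))
  prior <- c(rep(0.5, 50), rep(-0.5, 50))
  expect_equal(as.numeric(computeBF(post, prior, 0.1)), 3)
  # posterior identical to prior -> BF 1
  expect_equal(as.numeric(computeBF(prior, prior, 0.1)), 1)
  # swapped-hypothesis product is exactly 1 on the same draws
  for (t in c(-0.3, 0, 0.1, 0.4)) {
    b1 <- as.numeric(computeBF(post, prior, t))
    b2 <- as.numeric(computeBF(post, prior, t, direction = "less"))
    expect_equal(b1 * b2, 1)
  }
  # zero-mass tails are clipped and flagged as bounds
  allAbove <- rep(0.9, 100)
  expect_equal(attr(computeBF(allAbove, prior, 0.1), "bound"), "lower")
  expect_equal(attr(computeBF(-allAbove, prior, 0.1), "bound"), "upper")
})

test_that("Monte-Carlo BF matches the Gaussian-tail closed form", {
  set.seed(62)
  post <- rnorm(1e5, 0.3, 0.2)
  prior <- rnorm(1e5, 0, 0.5)
  for (t in c(0, 0.1, 0.3)) {
    expected <- gaussianTailBF(0.3, 0.2, 0, 0.5, t)
    expect_equal(as.numeric(computeBF(post, prior, t)), expected,
                 tolerance = 0.05)
  }
})

test_that("the BF curve is consistent with pointwise computation", {
  set.seed(63)
  post <- rnorm(2e4, 0.25, 0.15)
  prior <- rnorm(2e4, 0, 0.4)
  cv <- bfCurve(post, prior, thresholds = c(-0.2, 0, 0.1, 0.3))
  expect_equal(cv$threshold[3], 0.1)
  for (k in seq_len(nrow(cv)))
    expect_equal(cv$bf[k],
                 as.numeric(computeBF(post, prior, cv$threshold[k])))
  expect_equal(cv$log10_bf, log10(cv$bf))
  # default grid covers the standard threshold 0.1
  expect_true(0.1 %in% bfCurve(post, prior)$threshold)
  expect_error(bfCurve(post, prior, thresholds = c(0, 1.2)), "inside")
})

test_that("posterior summaries are means with ordered equal-tailed CIs", {
  m <- cbind(rho_S = rep(0.4, 100), rho_C = rep(0.1, 100))
  s <- posteriorSummary(m)
  expect_equal(s$mean[s$parameter == "rho_S"], 0.4)
  expect_equal(s$lower[s$parameter == "rho_S"], 0.4)
  expect_equal(s$upper[s$parameter == "rho_S"], 0.4)
  expect_equal(s$mean[s$parameter == "delta_rho"], 0.3)
  set.seed(64)
  z <- cbind(x = rnorm(1e5))
  sz <- posteriorSummary(z)
  expect_equal(sz$lower, -1.96, tolerance = 0.02)
  expect_equal(sz$upper, 1.96, tolerance = 0.02)
  expect_true(all(sz$lower <= sz$upper))
})

test_that("evidence labels follow the Lee-Wagenmakers bands symmetrically", {
  expect_equal(interpretBF(1), "no evidence")
  expect_equal(interpretBF(8.94), "moderate evidence for H1")
  expect_equal(interpretBF(2), "anecdotal evidence for H1")
  expect_equal(interpretBF(20), "strong evidence for H1")
  expect_equal(interpretBF(50), "very strong evidence for H1")
  expect_equal(interpretBF(500), "extreme evidence for H1")
  for (b in c(2, 8, 20, 50, 500))
    expect_equal(sub("H0", "H1", interpretBF(1 / b)), interpretBF(b))
  expect_error(interpretBF(0), "positive")
})

test_that("the analytic log-joint gradient matches finite differences", {
  set.seed(65)
  s <- generateCorrelations(CorrSynthSpec(rhoBar = 0.5, nImages = 3,
                                          patchesPerImage = 8, seed = 3))
  c0 <- generateCorrelations(CorrSynthSpec(rhoBar = 0, nImages = 2,
                                           patchesPerImage = 8, seed = 4))
  S <- BayesColoc:::prepCondition(s, "sample")
  C <- BayesColoc:::prepCondition(c0, "control")
  lp <- BayesColoc:::makeLogPost(S$y, S$img, C$y, C$img, S$n, C$n,
                                 PriorSpec())
  for (rep in 1:3) {
    z <- rnorm(BayesColoc:::condBlockSize(3) + BayesColoc:::condBlockSize(2),
               sd = 0.7)
    g <- lp(z)$grad
    fd <- vapply(seq_along(z), function(i) {
      h <- 1e-6; zp <- z; zm <- z
      zp[i] <- z[i] + h; zm[i] <- z[i] - h
      (lp(zp)$lp - lp(zm)$lp) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - fd)), 1e-5)
  }
})

test_that("identical conditions give a delta-rho posterior centred at zero", {
  corrs <- generateCorrelations(CorrSynthSpec(rhoBar = 0.4, nImages = 4,
                                              patchesPerImage = 30, seed = 8))
  fit <- fitModel(corrs, corrs,
                  config = FitConfig(viIterations = 4000,
                                     posteriorSamples = 10000, seed = 2))
  expect_lt(abs(mean(deltaRho(fit))), 0.05)
})

test_that("posterior draws respect all truncation bounds (both engines)", {
  s <- generateCorrelations(CorrSynthSpec(rhoBar = 0.6, nImages = 3,
                                          patchesPerImage = 20, seed = 9))
  c0 <- generateCorrelations(CorrSynthSpec(rhoBar = 0, nImages = 3,
                                           patchesPerImage = 20, seed = 10))
  for (eng in c("vi", "mcmc")) {
    fit <- fitModel(s, c0, config = FitConfig(viIterations = 1500,
                                              posteriorSamples = 3000,
                                              seed = 3, engine = eng))
    d <- posteriorDraws(fit)
    rhoCols <- grep("^rho", colnames(d))
    sigCols <- grep("^(sigma|tau)", colnames(d))
    nuCols <- grep("^nu", colnames(d))
    expect_true(all(d[, rhoCols] > -1 & d[, rhoCols] < 1))
    expect_true(all(d[, sigCols] > 0 & d[, sigCols] < 1))
    expect_true(all(d[, nuCols] > 0))
    expect_equal(fit@nSample, 3L)
  }
})

test_that("variational and exact-sampler fits agree on the group means", {
  s <- generateCorrelations(CorrSynthSpec(rhoBar = 0.6, sigma = 0.1,
                                          nImages = 6, patchesPerImage = 50,
                                          seed = 11))
  c0 <- generateCorrelations(CorrSynthSpec(rhoBar = 0, sigma = 0.1,
                                           nImages = 6, patchesPerImage = 50,
                                           seed = 12))
  vi <- fitModel(s, c0, config = FitConfig(viIterations = 10000,
                                           posteriorSamples = 20000,
                                           seed = 5))
  mc <- fitModel(s, c0, config = FitConfig(posteriorSamples = 15000,
                                           seed = 5, engine = "mcmc"))
  for (p in c("rho_S", "rho_C"))
    expect_lt(abs(mean(posteriorDraws(vi)[, p]) -
                  mean(posteriorDraws(mc)[, p])), 0.05)
})

test_that("more data concentrates the group-mean posterior", {
  sdOf <- function(nImages, seed) {
    s <- generateCorrelations(CorrSynthSpec(rhoBar = 0.5, sigma = 0.1,
                                            nImages = nImages,
                                            patchesPerImage = 50,
                                            seed = seed))
    c0 <- generateCorrelations(CorrSynthSpec(rhoBar = 0, sigma = 0.1,
                                             nImages = nImages,
                                             patchesPerImage = 50,
                                             seed = seed + 100))
    fit <- fitModel(s, c0, config = FitConfig(viIterations = 6000,
                                              posteriorSamples = 10000,
                                              seed = 7))
    sd(posteriorDraws(fit)[, "rho_S"])
  }
  expect_lt(sdOf(24, 21), sdOf(6, 21) + 0.01)
})

test_that("degenerate inputs are rejected with informative errors", {
  good <- list(c(0.5, 0.6, 0.4), c(0.2, 0.3, 0.25))
  expect_error(fitModel(list(), good), "empty sample")
  expect_error(fitModel(good, list(c(0.1, NA, 0.2), c(0.1, 0.2, 0.3))),
               "non-finite")
  expect_warning(
    expect_error(fitModel(list(c(0.5)), good,
                          config = FitConfig(viIterations = 10,
                                             posteriorSamples = 10)),
                 "no sample image"),
    "dropped")
})
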
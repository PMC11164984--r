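# Two-level hierarchical Student-t model over patch correlations.
#
# For each condition c in {S, C}:
#   rho_c   ~ Cauchy(0, 0.3) truncated to (-1, 1)
#   sigma_c ~ Cauchy(0, 0.3) truncated to (0, 1)
#   tau_c   ~ Cauchy(0, 0.3) truncated to (0, 1)
#   nu_c    ~ Exponential(rate 1)
# per image I of condition c:
#   rho_I   ~ Normal(rho_c, sigma_c) truncated to (-1, 1)
#   sigma_I ~ Normal(sigma_c, tau_c) truncated to (0, 1)
#   nu_I    ~ Exponential(mean nu_c)
# per patch correlation r of image I:
#   r ~ StudentT(df = max(nu_I, 0.01), location = rho_I, scale = sigma_I)
#
# The df floor avoids undefined Student-t moments; the likelihood is not
# truncated to [-1, 1] — the heavy tails absorb boundary effects.
#
# Parameters live in unconstrained space through the standard bijections
# (scaled logistic for interval constraints, log for positivity); the
# variational family is a fully factorized Gaussian there (mean-field ADVI),
# and the gradients below are analytic.

# ---- unconstrained block layout (one condition, n images) ----
# [ z_rho, z_sigma, z_tau, z_nu, z_rhoI (n), z_sigmaI (n), z_nuI (n) ]

condBlockSize <- function(n) 4L + 3L * n

# log joint + gradient of one condition block, in unconstrained space
condLpGrad <- function(zb, y, imgIdx, n, prior) {
  srho <- sigmoid(zb[1]); rho <- 2 * srho - 1
  ssig <- sigmoid(zb[2]); sig <- ssig
  stau <- sigmoid(zb[3]); tau <- stau
  nu <- exp(zb[4])
  zrI <- zb[4L + 1:n];        srI <- sigmoid(zrI); rhoI <- 2 * srI - 1
  zsI <- zb[4L + n + 1:n];    ssI <- sigmoid(zsI); sigI <- ssI
  znI <- zb[4L + 2L * n + 1:n]; nuI <- exp(znI)

  grho <- 0; gsig <- 0; gtau <- 0; gnu <- 0
  grhoI <- numeric(n); gsigI <- numeric(n); gnuI <- numeric(n)

  # hyperpriors (truncation constants are additive constants)
  lp <- dtruncCauchy(rho, 0, prior@rhoScale, -1, 1, log = TRUE) +
    dtruncCauchy(sig, 0, prior@sigmaScale, 0, 1, log = TRUE) +
    dtruncCauchy(tau, 0, prior@tauScale, 0, 1, log = TRUE) +
    dexp(nu, prior@nuRate, log = TRUE)
  grho <- grho - 2 * rho / (prior@rhoScale^2 + rho^2)
  gsig <- gsig - 2 * sig / (prior@sigmaScale^2 + sig^2)
  gtau <- gtau - 2 * tau / (prior@tauScale^2 + tau^2)
  gnu <- gnu - prior@nuRate

  # rho_I ~ Normal(rho, sig) truncated to (-1, 1)
  alpha <- (-1 - rho) / sig; beta <- (1 - rho) / sig
  Z <- pnorm(beta) - pnorm(alpha)
  xi <- (rhoI - rho) / sig
  lp <- lp + sum(-log(sig) - xi^2 / 2 - 0.5 * log(2 * pi) - log(Z))
  da <- dnorm(alpha); db <- dnorm(beta)
  grhoI <- grhoI - xi / sig
  grho <- grho + sum(xi) / sig + n * (db - da) / (sig * Z)
  gsig <- gsig + sum(xi^2 - 1) / sig + n * (beta * db - alpha * da) / (sig * Z)

  # sigma_I ~ Normal(sig, tau) truncated to (0, 1)
  a2 <- (0 - sig) / tau; b2 <- (1 - sig) / tau
  Z2 <- pnorm(b2) - pnorm(a2)
  xi2 <- (sigI - sig) / tau
  lp <- lp + sum(-log(tau) - xi2^2 / 2 - 0.5 * log(2 * pi) - log(Z2))
  da2 <- dnorm(a2); db2 <- dnorm(b2)
  gsigI <- gsigI - xi2 / tau
  gsig <- gsig + sum(xi2) / tau + n * (db2 - da2) / (tau * Z2)
  gtau <- gtau + sum(xi2^2 - 1) / tau +
    n * (b2 * db2 - a2 * da2) / (tau * Z2)

  # nu_I ~ Exponential(mean nu)
  lp <- lp + sum(-log(nu) - nuI / nu)
  gnuI <- gnuI - 1 / nu
  gnu <- gnu - n / nu + sum(nuI) / nu^2

  # likelihood: r ~ StudentT(max(nu_I, 0.01), rho_I, sigma_I)
  nuE <- pmax(nuI, 0.01)
  rI <- rhoI[imgIdx]; sI <- sigI[imgIdx]; nE <- nuE[imgIdx]
  zz <- (y - rI) / sI
  ww <- 1 + zz^2 / nE
  constI <- lgamma((nuE + 1) / 2) - lgamma(nuE / 2) - 0.5 * log(nuE * pi)
  cnt <- tabulate(imgIdx, nbins = n)
  lp <- lp + sum(constI * cnt) - sum(log(sI)) -
    sum((nE + 1) / 2 * log(ww))
  common <- (nE + 1) * zz / (sI * nE * ww)
  grhoI <- grhoI + as.numeric(rowsum(common, imgIdx))
  gsigI <- gsigI + as.numeric(rowsum(-1 / sI + zz * common, imgIdx))
  dnuObs <- 0.5 * (digamma((nE + 1) / 2) - digamma(nE / 2)) - 1 / (2 * nE) -
    0.5 * log(ww) + (nE + 1) * zz^2 / (2 * nE^2 * ww)
  gnuI <- gnuI + ifelse(nuI > 0.01, as.numeric(rowsum(dnuObs, imgIdx)), 0)

  # log-Jacobians of the bijections and chain rule to unconstrained space
  lp <- lp + log(2) + logSigmoid(zb[1]) + logSigmoid(-zb[1]) +
    logSigmoid(zb[2]) + logSigmoid(-zb[2]) +
    logSigmoid(zb[3]) + logSigmoid(-zb[3]) + zb[4] +
    sum(log(2) + logSigmoid(zrI) + logSigmoid(-zrI)) +
    sum(logSigmoid(zsI) + logSigmoid(-zsI)) + sum(znI)

  gz <- numeric(condBlockSize(n))
  gz[1] <- grho * 2 * srho * (1 - srho) + (1 - 2 * srho)
  gz[2] <- gsig * ssig * (1 - ssig) + (1 - 2 * ssig)
  gz[3] <- gtau * stau * (1 - stau) + (1 - 2 * stau)
  gz[4] <- gnu * nu + 1
  gz[4L + 1:n] <- grhoI * 2 * srI * (1 - srI) + (1 - 2 * srI)
  gz[4L + n + 1:n] <- gsigI * ssI * (1 - ssI) + (1 - 2 * ssI)
  gz[4L + 2L * n + 1:n] <- gnuI * nuI + 1
  list(lp = lp, grad = gz)
}

# Full log joint + gradient over both condition blocks
makeLogPost <- function(yS, imgS, yC, imgC, nS, nC, prior) {
  dS <- condBlockSize(nS)
  function(z) {
    s <- condLpGrad(z[seq_len(dS)], yS, imgS, nS, prior)
    c_ <- condLpGrad(z[-seq_len(dS)], yC, imgC, nC, prior)
    list(lp = s$lp + c_$lp, grad = c(s$grad, c_$grad))
  }
}

# transform an unconstrained draw matrix (rows = draws) of one condition
# block into constrained parameters with named columns
constrainBlock <- function(Z, n, cond) {
  out <- matrix(NA_real_, nrow(Z), condBlockSize(n))
  out[, 1] <- 2 * sigmoid(Z[, 1]) - 1
  out[, 2] <- sigmoid(Z[, 2])
  out[, 3] <- sigmoid(Z[, 3])
  out[, 4] <- exp(Z[, 4])
  out[, 4L + 1:n] <- 2 * sigmoid(Z[, 4L + 1:n, drop = FALSE]) - 1
  out[, 4L + n + 1:n] <- sigmoid(Z[, 4L + n + 1:n, drop = FALSE])
  out[, 4L + 2L * n + 1:n] <- exp(Z[, 4L + 2L * n + 1:n, drop = FALSE])
  colnames(out) <- c(paste0(c("rho_", "sigma_", "tau_", "nu_"), cond),
                     paste0("rho_I_", cond, "_", 1:n),
                     paste0("sigma_I_", cond, "_", 1:n),
                     paste0("nu_I_", cond, "_", 1:n))
  out
}

# ---- mean-field ADVI with Adam steps and Polyak-averaged tail ----
adviFit <- function(lpgrad, d, iterations, seed, lr = 0.05) {
  set.seed(seed)
  mu <- numeric(d)
  omega <- rep(-2, d)
  m1 <- numeric(2 * d); m2 <- numeric(2 * d)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  avgStart <- max(1L, floor(0.75 * iterations))
  muAvg <- numeric(d); omAvg <- numeric(d); nAvg <- 0L
  elbo <- numeric(0)
  for (t in seq_len(iterations)) {
    eps <- rnorm(d)
    sdv <- exp(omega)
    z <- mu + sdv * eps
    lg <- lpgrad(z)
    g <- c(lg$grad, lg$grad * eps * sdv + 1)
    if (all(is.finite(g))) {
      m1 <- b1 * m1 + (1 - b1) * g
      m2 <- b2 * m2 + (1 - b2) * g^2
      step <- lr / (1 + 5 * t / iterations) *
        (m1 / (1 - b1^t)) / (sqrt(m2 / (1 - b2^t)) + epsA)
      mu <- mu + step[seq_len(d)]
      omega <- pmin(5, pmax(-12, omega + step[d + seq_len(d)]))
    }
    if (t >= avgStart) {
      muAvg <- muAvg + mu; omAvg <- omAvg + omega; nAvg <- nAvg + 1L
    }
    if (t %% 100L == 0L)
      elbo <- c(elbo, lg$lp + sum(omega) + 0.5 * d * log(2 * pi * exp(1)))
  }
  list(mu = muAvg / nAvg, omega = omAvg / nAvg, elbo = elbo)
}

# ---- data preparation shared by both engines ----
prepCondition <- function(corrs, label) {
  if (length(corrs) == 0L) stop("empty ", label, " condition")
  if (is.numeric(corrs)) corrs <- list(corrs)
  bad <- vapply(corrs, function(v) any(!is.finite(v)), logical(1))
  if (any(bad))
    stop("non-finite correlation values in ", label, " image(s) ",
         paste(which(bad), collapse = ", "))
  keep <- vapply(corrs, function(v) length(v) >= 2L, logical(1))
  if (!all(keep))
    warning("WARN: dropped ", sum(!keep), " ", label,
            " image(s) with fewer than 2 valid patch correlations",
            call. = FALSE)
  corrs <- corrs[keep]
  if (length(corrs) == 0L)
    stop("no ", label, " image contributes >= 2 valid patch correlations")
  list(y = unlist(corrs, use.names = FALSE),
       img = rep(seq_along(corrs), lengths(corrs)),
       n = length(corrs))
}

#' Fit the hierarchical colocalization model
#'
#' Fits the two-level Student-t model to the per-image patch correlation
#' lists of a sample and a control condition. The default engine is
#' mean-field ADVI (a factorized Gaussian in unconstrained space, optimized
#' by stochastic gradient ascent on the ELBO with analytic gradients); the
#' `"mcmc"` engine runs the same model through JAGS as an asymptotically
#' exact validation fallback. All reported draws respect the parameter
#' constraints by construction.
#'
#' @param sampleCorrs,controlCorrs lists of numeric vectors, one per image,
#'   holding that image's valid patch correlations. Images with fewer than 2
#'   values are dropped with a warning.
#' @param prior a [PriorSpec-class].
#' @param config a [FitConfig-class]; `config@seed` drives named substreams
#'   for VI initialization and posterior sampling.
#' @return a [HierarchicalDraws-class] with `config@posteriorSamples` rows.
#' @examples
#' s <- generateCorrelations(CorrSynthSpec(rhoBar = 0.6, seed = 1))
#' c0 <- generateCorrelations(CorrSynthSpec(rhoBar = 0.0, seed = 2))
#' fit <- fitModel(s, c0, config = FitConfig(viIterations = 500,
#'                                           posteriorSamples = 1000))
#' colMeans(globalDraws(fit))[c("rho_S", "rho_C")]
#' @export
fitModel <- function(sampleCorrs, controlCorrs, prior = PriorSpec(),
                     config = FitConfig()) {
  S <- prepCondition(sampleCorrs, "sample")
  C <- prepCondition(controlCorrs, "control")
  draws <- if (config@engine == "vi") {
    fitVI(S, C, prior, config)
  } else {
    fitJags(S, C, prior, config)
  }
  new("HierarchicalDraws", draws = draws, nSample = S$n, nControl = C$n,
      engine = config@engine)
}

fitVI <- function(S, C, prior, config) {
  lpgrad <- makeLogPost(S$y, S$img, C$y, C$img, S$n, C$n, prior)
  d <- condBlockSize(S$n) + condBlockSize(C$n)
  fit <- adviFit(lpgrad, d, config@viIterations,
                 seed = substreamSeed(config@seed, "vi_fit"))
  if (length(fit$elbo) >= 4) {
    tail4 <- utils::tail(fit$elbo, 4)
    if (diff(range(tail4)) > max(1, 0.05 * abs(mean(tail4))) * 10)
      warning("WARN: ELBO still moving over the last iterations; ",
              "consider more viIterations", call. = FALSE)
  }
  set.seed(substreamSeed(config@seed, "vi_draws"))
  ns <- config@posteriorSamples
  Z <- matrix(rnorm(ns * d), ns, d)
  Z <- sweep(Z, 2, exp(fit$omega), `*`)
  Z <- sweep(Z, 2, fit$mu, `+`)
  dS <- condBlockSize(S$n)
  cbind(constrainBlock(Z[, seq_len(dS), drop = FALSE], S$n, "S"),
        constrainBlock(Z[, -seq_len(dS), drop = FALSE], C$n, "C"))
}

jagsModelString <- function(prior) {
  sprintf("
model {
  for (c in 1:2) {
    rho[c]   ~ dt(0, %.10f, 1) T(-1, 1)
    sigma[c] ~ dt(0, %.10f, 1) T(0, 1)
    tau[c]   ~ dt(0, %.10f, 1) T(0, 1)
    nu[c]    ~ dexp(%.10f)
  }
  for (i in 1:nS) {
    rhoI_S[i]   ~ dnorm(rho[1], pow(sigma[1], -2)) T(-1, 1)
    sigmaI_S[i] ~ dnorm(sigma[1], pow(tau[1], -2)) T(0, 1)
    nuI_S[i]    ~ dexp(1 / nu[1])
  }
  for (j in 1:NS) {
    yS[j] ~ dt(rhoI_S[imgS[j]], pow(sigmaI_S[imgS[j]], -2), nuI_S[imgS[j]])
  }
  for (i in 1:nC) {
    rhoI_C[i]   ~ dnorm(rho[2], pow(sigma[2], -2)) T(-1, 1)
    sigmaI_C[i] ~ dnorm(sigma[2], pow(tau[2], -2)) T(0, 1)
    nuI_C[i]    ~ dexp(1 / nu[2])
  }
  for (j in 1:NC) {
    yC[j] ~ dt(rhoI_C[imgC[j]], pow(sigmaI_C[imgC[j]], -2), nuI_C[imgC[j]])
  }
}", prior@rhoScale^-2, prior@sigmaScale^-2, prior@tauScale^-2, prior@nuRate)
}

fitJags <- function(S, C, prior, config) {
  if (!requireNamespace("rjags", quietly = TRUE))
    stop("engine 'mcmc' requires the rjags package")
  data <- list(yS = S$y, imgS = S$img, nS = S$n, NS = length(S$y),
               yC = C$y, imgC = C$img, nC = C$n, NC = length(C$y))
  inits <- list(rho = c(0, 0), sigma = c(0.2, 0.2), tau = c(0.2, 0.2),
                nu = c(1, 1),
                rhoI_S = rep(0, S$n), sigmaI_S = rep(0.2, S$n),
                nuI_S = rep(1, S$n),
                rhoI_C = rep(0, C$n), sigmaI_C = rep(0.2, C$n),
                nuI_C = rep(1, C$n),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = substreamSeed(config@seed, "jags"))
  jm <- rjags::jags.model(textConnection(jagsModelString(prior)),
                          data = data, inits = inits, n.chains = 1,
                          n.adapt = 1000, quiet = TRUE)
  update(jm, 1000, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("rho", "sigma", "tau", "nu",
                                  "rhoI_S", "sigmaI_S", "nuI_S",
                                  "rhoI_C", "sigmaI_C", "nuI_C"),
                            n.iter = config@posteriorSamples,
                            progress.bar = "none")
  m <- as.matrix(sm[[1]])
  ren <- colnames(m)
  ren <- sub("^(rho|sigma|tau|nu)\\[1\\]$", "\\1_S", ren)
  ren <- sub("^(rho|sigma|tau|nu)\\[2\\]$", "\\1_C", ren)
  ren <- sub("^(rhoI)_(S|C)\\[([0-9]+)\\]$", "rho_I_\\2_\\3", ren)
  ren <- sub("^(sigmaI)_(S|C)\\[([0-9]+)\\]$", "sigma_I_\\2_\\3", ren)
  ren <- sub("^(nuI)_(S|C)\\[([0-9]+)\\]$", "nu_I_\\2_\\3", ren)
  colnames(m) <- ren
  ord <- c(paste0(c("rho_", "sigma_", "tau_", "nu_"), "S"),
           paste0("rho_I_S_", 1:S$n), paste0("sigma_I_S_", 1:S$n),
           paste0("nu_I_S_", 1:S$n),
           paste0(c("rho_", "sigma_", "tau_", "nu_"), "C"),
           paste0("rho_I_C_", 1:C$n), paste0("sigma_I_C_", 1:C$n),
           paste0("nu_I_C_", 1:C$n))
  m[, ord, drop = FALSE]
}
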
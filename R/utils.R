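# internal helpers: seed substreams and truncated distributions

# Deterministic sub-seed for a named source of randomness, derived from one
# master seed; stays inside the 32-bit integer range.
substreamSeed <- function(master, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(master) * 10007 + h * 97) %% 2147483647)
}

# Inverse-CDF sampling of a Cauchy(location, scale) truncated to (a, b):
# exact and rejection-free, so draws are seed-stable.
rtruncCauchy <- function(n, location = 0, scale = 1, a = -1, b = 1) {
  lo <- pcauchy(a, location, scale)
  hi <- pcauchy(b, location, scale)
  qcauchy(lo + runif(n) * (hi - lo), location, scale)
}

dtruncCauchy <- function(x, location = 0, scale = 1, a = -1, b = 1,
                         log = FALSE) {
  z <- pcauchy(b, location, scale) - pcauchy(a, location, scale)
  out <- dcauchy(x, location, scale, log = TRUE) - base::log(z)
  out[x <= a | x >= b] <- -Inf
  if (log) out else exp(out)
}

ptruncCauchy <- function(q, location = 0, scale = 1, a = -1, b = 1) {
  lo <- pcauchy(a, location, scale)
  hi <- pcauchy(b, location, scale)
  pmin(1, pmax(0, (pcauchy(q, location, scale) - lo) / (hi - lo)))
}

rtruncNorm <- function(n, mean = 0, sd = 1, a = -Inf, b = Inf) {
  lo <- pnorm(a, mean, sd)
  hi <- pnorm(b, mean, sd)
  qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

# clip into [lo, hi]; keeps dim attributes (x first in pmin/pmax)
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

logSigmoid <- function(z) ifelse(z < 0, z - log1p(exp(z)), -log1p(exp(-z)))
sigmoid <- function(z) 1 / (1 + exp(-z))
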
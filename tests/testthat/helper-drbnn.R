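# Shared fixtures and independent slow-path oracles for the test suite.

# central finite differences of a scalar function
fdGrad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- x; e[i] <- e[i] + h; up <- f(e)
    e[i] <- x[i] - h; dn <- f(e)
    (up - dn) / (2 * h)
  }, numeric(1))
}

# scalar-loop forward pass, independent of the vectorized implementation
slowForward <- function(state, x) {
  H <- ncol(state@hiddenWeights); k <- ncol(state@outputWeights)
  h <- numeric(H)
  for (j in seq_len(H))
    h[j] <- 1 / (1 + exp(-(state@hiddenBiases[j] +
                             sum(x * state@hiddenWeights[, j]))))
  f <- numeric(k)
  for (kk in seq_len(k))
    f[kk] <- state@outputBiases[kk] + sum(h * state@outputWeights[, kk])
  f
}

# slow accumulation of the log joint density, element by element
slowLogJoint <- function(state, X, Y, hyper = ardHyper()) {
  acc <- 0
  for (i in seq_len(nrow(X))) {
    f <- slowForward(state, X[i, ])
    for (kk in seq_len(ncol(Y)))
      acc <- acc - 0.5 * (Y[i, kk] - f[kk])^2
  }
  W <- state@hiddenWeights
  H <- ncol(W)
  for (j in seq_len(nrow(W))) {
    s2 <- state@ardScales[j]; u <- log(s2)
    for (h in seq_len(H))
      acc <- acc - 0.5 * (log(2 * pi) + u) - W[j, h]^2 / (2 * s2)
    acc <- acc + hyper@hiddenShape * log(hyper@hiddenRate) -
      lgamma(hyper@hiddenShape) - hyper@hiddenShape * u -
      hyper@hiddenRate / s2
  }
  t2 <- state@outputScale; v <- log(t2)
  for (b in as.vector(state@outputWeights))
    acc <- acc - 0.5 * (log(2 * pi) + v) - b^2 / (2 * t2)
  acc <- acc + hyper@outputShape * log(hyper@outputRate) -
    lgamma(hyper@outputShape) - hyper@outputShape * v -
    hyper@outputRate / t2
  for (b in c(state@hiddenBiases, state@outputBiases))
    acc <- acc + dnorm(b, 0, 5, log = TRUE)
  acc
}

# random strictly positive 3x3 frequency table summing to 1
randomFreqTable <- function() {
  raw <- matrix(rexp(9) + 0.01, 3, 3)
  raw / sum(raw)
}

# tiny simulated dataset used by several files
tinyDataset <- function(seed = 1, n = 60, bg = 4, theta = 0.3,
                        maf = 0.3, model = "additive") {
  simulateDataset(
    simulationDesign(nIndividuals = n, nBackgroundSnps = bg,
                     seed = seed),
    geneticModelSpec(model, theta = theta, causalMaf = maf))
}

# batch-means Monte-Carlo standard error for a (possibly autocorrelated)
# chain of draws
batchMeansSE <- function(x, nBatch = 25) {
  bs <- floor(length(x) / nBatch)
  m <- colMeans(matrix(x[seq_len(bs * nBatch)], bs, nBatch))
  sd(m) / sqrt(nBatch)
}
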
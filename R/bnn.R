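# Layout of the unconstrained parameter vector used for sampling:
#   [ W (p*H, column-major) | a (H) | B (H*k, column-major) | alpha (k) |
#     log sigma_j^2 (p) | log tau^2 (1) ]
# The ARD scales are sampled on the log scale; the inverse-gamma prior on
# sigma^2 plus the log-scale Jacobian is folded into logJoint.
paramIndex <- function(p, H, k) {
  nW <- p * H; nB <- H * k
  off <- 0L
  W <- seq_len(nW); off <- off + nW
  a <- off + seq_len(H); off <- off + H
  B <- off + seq_len(nB); off <- off + nB
  alpha <- off + seq_len(k); off <- off + k
  logSigma2 <- off + seq_len(p); off <- off + p
  logTau2 <- off + 1L
  list(W = W, a = a, B = B, alpha = alpha, logSigma2 = logSigma2,
       logTau2 = logTau2, total = off + 1L)
}

#' Construct or initialize a network state
#'
#' Builds a [NetworkState-class] either from explicit components or as a
#' random small-weight initialization for a given shape. The default
#' initialization draws weights from N(0, 0.01^2)... small enough that the
#' network starts near its linear regime, with ARD scales at the prior
#' mode.
#'
#' @param p,nHidden,k network shape: inputs, hidden units, outputs.
#' @param hyper [ARDHyper-class] used to place the initial scales at the
#'   prior mode `rate / (shape + 1)`.
#' @param initSd standard deviation of the random initial weights.
#' @return a [NetworkState-class].
#' @examples
#' set.seed(1); networkState(5, 3, 2)
#' @export
networkState <- function(p, nHidden, k, hyper = ardHyper(),
                         initSd = 0.01) {
  new("NetworkState",
      hiddenWeights = matrix(stats::rnorm(p * nHidden, 0, initSd),
                             p, nHidden),
      hiddenBiases = stats::rnorm(nHidden, 0, initSd),
      outputWeights = matrix(stats::rnorm(nHidden * k, 0, initSd),
                             nHidden, k),
      outputBiases = stats::rnorm(k, 0, initSd),
      ardScales = rep(hyper@hiddenRate / (hyper@hiddenShape + 1), p),
      outputScale = hyper@outputRate / (hyper@outputShape + 1))
}

#' ARD hyper-parameter constructor
#'
#' Defaults follow the settings used throughout the simulation study:
#' inverse-gamma shape 3 / rate 1 on the per-SNP hidden-weight scales and
#' shape 0.1 / rate 0.1 on the shared output-weight scale.
#'
#' @param hiddenShape,hiddenRate hidden-layer inverse-gamma parameters.
#' @param outputShape,outputRate output-layer inverse-gamma parameters.
#' @return an [ARDHyper-class].
#' @export
ardHyper <- function(hiddenShape = 3, hiddenRate = 1,
                     outputShape = 0.1, outputRate = 0.1) {
  new("ARDHyper", hiddenShape = hiddenShape, hiddenRate = hiddenRate,
      outputShape = outputShape, outputRate = outputRate)
}

packState <- function(state) {
  c(as.vector(state@hiddenWeights), state@hiddenBiases,
    as.vector(state@outputWeights), state@outputBiases,
    log(state@ardScales), log(state@outputScale))
}

unpackState <- function(theta, p, H, k) {
  idx <- paramIndex(p, H, k)
  new("NetworkState",
      hiddenWeights = matrix(theta[idx$W], p, H),
      hiddenBiases = theta[idx$a],
      outputWeights = matrix(theta[idx$B], H, k),
      outputBiases = theta[idx$alpha],
      ardScales = exp(theta[idx$logSigma2]),
      outputScale = exp(theta[idx$logTau2]))
}

#' Hidden-layer activations
#'
#' Logistic transformation of each hidden unit,
#' \eqn{h_j(x) = 1/(1 + \exp(-(a_j + x^T w_j)))}.
#'
#' @param state a [NetworkState-class].
#' @param x genotype row (length p) or an n x p genotype matrix.
#' @return vector of H activations in (0, 1), or an n x H matrix.
#' @export
hiddenActivation <- function(state, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != nrow(state@hiddenWeights))
    stopInvalid("genotype row length (", ncol(X),
                ") does not match network input count (",
                nrow(state@hiddenWeights), ")")
  Z <- sweep(X %*% state@hiddenWeights, 2, state@hiddenBiases, "+")
  Hm <- stats::plogis(Z)
  if (is.matrix(x)) Hm else drop(Hm)
}

#' Network forward map
#'
#' The full network output: logistic hidden layer followed by a linear
#' output layer, \eqn{f_k(x) = \alpha_k + \sum_j h_j(x) \beta_{kj}}.
#'
#' @param state a [NetworkState-class].
#' @param x genotype row (length p) or an n x p genotype matrix.
#' @return vector of k outputs, or an n x k matrix.
#' @examples
#' s <- networkState(4, 2, 3)
#' forward(s, c(0, 1, 2, 0))
#' @export
forward <- function(state, x) {
  Hm <- hiddenActivation(state, x)
  if (!is.matrix(Hm)) Hm <- matrix(Hm, nrow = 1)
  Fm <- sweep(Hm %*% state@outputWeights, 2, state@outputBiases, "+")
  if (is.matrix(x)) Fm else drop(Fm)
}

biasPriorSd <- 5  # fixed broad Normal(0, 5^2) prior on all biases

#' Log joint density of the Bayesian neural network
#'
#' Log likelihood plus log prior (up to additive constants that do not
#' involve the parameters of interest... constants of the inverse-gamma
#' and Gaussian densities are in fact included, so values are comparable
#' across hyper-parameters):
#' \itemize{
#'   \item likelihood: independent unit-variance Gaussians,
#'     \eqn{-\frac{1}{2}\sum_{ik}(y_{ik} - f_{ik})^2} (responses are
#'     assumed standardized);
#'   \item hidden weights fanning out of input j: Normal(0,
#'     \eqn{\sigma_j^2}) with \eqn{\sigma_j^2 \sim} InverseGamma(shape,
#'     rate) — the ARD hierarchy;
#'   \item output weights: Normal(0, \eqn{\tau^2}) with a shared
#'     \eqn{\tau^2 \sim} InverseGamma(shape, rate);
#'   \item biases: fixed broad Normal(0, 25).
#' }
#' The scales enter on the log scale (the sampling parameterization); the
#' log-scale Jacobian is included, so this is the density HMC targets.
#'
#' @param state a [NetworkState-class].
#' @param genotypes n x p genotype matrix.
#' @param responses n x k standardized response matrix.
#' @param hyper an [ARDHyper-class].
#' @return single real, the log joint density.
#' @seealso [gradLogJoint()], [bnnSample()]
#' @export
logJoint <- function(state, genotypes, responses, hyper = ardHyper()) {
  X <- as.matrix(genotypes); Y <- as.matrix(responses)
  p <- nrow(state@hiddenWeights); H <- ncol(state@hiddenWeights)
  k <- ncol(state@outputWeights)
  Fm <- forward(state, X)
  ll <- -0.5 * sum((Y - Fm)^2)
  ll + logPriorState(state, hyper)
}

logPriorState <- function(state, hyper) {
  W <- state@hiddenWeights
  H <- ncol(W); k <- ncol(state@outputWeights)
  s2 <- state@ardScales; u <- log(s2)
  t2 <- state@outputScale; v <- log(t2)
  rowSS <- rowSums(W^2)
  lpW <- sum(-0.5 * H * (log(2 * pi) + u) - rowSS / (2 * s2))
  lpB <- sum(-0.5 * (log(2 * pi) + v) - state@outputWeights^2 / (2 * t2))
  lpBias <- sum(stats::dnorm(c(state@hiddenBiases, state@outputBiases),
                             0, biasPriorSd, log = TRUE))
  # inverse-gamma on sigma^2 in log coordinates, Jacobian included:
  # a*log(b) - lgamma(a) - a*u - b*exp(-u)
  ah <- hyper@hiddenShape; bh <- hyper@hiddenRate
  lpU <- sum(ah * log(bh) - lgamma(ah) - ah * u - bh * exp(-u))
  ao <- hyper@outputShape; bo <- hyper@outputRate
  lpV <- ao * log(bo) - lgamma(ao) - ao * v - bo * exp(-v)
  lpW + lpB + lpBias + lpU + lpV
}

# Likelihood and prior parts separately, on the packed parameter vector.
# Used by the sampler so that annealing can temper the likelihood only.
bnnTarget <- function(genotypes, responses, nHidden, hyper = ardHyper()) {
  X <- as.matrix(genotypes); Y <- as.matrix(responses)
  p <- ncol(X); H <- as.integer(nHidden); k <- ncol(Y)
  idx <- paramIndex(p, H, k)
  ah <- hyper@hiddenShape; bh <- hyper@hiddenRate
  ao <- hyper@outputShape; bo <- hyper@outputRate

  logLik <- function(theta) {
    W <- matrix(theta[idx$W], p, H)
    Hm <- stats::plogis(sweep(X %*% W, 2, theta[idx$a], "+"))
    Fm <- sweep(Hm %*% matrix(theta[idx$B], H, k), 2,
                theta[idx$alpha], "+")
    -0.5 * sum((Y - Fm)^2)
  }
  gradLik <- function(theta) {
    W <- matrix(theta[idx$W], p, H)
    B <- matrix(theta[idx$B], H, k)
    Hm <- stats::plogis(sweep(X %*% W, 2, theta[idx$a], "+"))
    R <- Y - sweep(Hm %*% B, 2, theta[idx$alpha], "+")
    dB <- crossprod(Hm, R)
    dalpha <- colSums(R)
    dZ <- (R %*% t(B)) * Hm * (1 - Hm)
    dW <- crossprod(X, dZ)
    da <- colSums(dZ)
    g <- numeric(idx$total)
    g[idx$W] <- dW; g[idx$a] <- da
    g[idx$B] <- dB; g[idx$alpha] <- dalpha
    g
  }
  logPrior <- function(theta) {
    W <- matrix(theta[idx$W], p, H)
    u <- theta[idx$logSigma2]; v <- theta[idx$logTau2]
    rowSS <- rowSums(W^2)
    lp <- sum(-0.5 * H * (log(2 * pi) + u) - rowSS / (2 * exp(u))) +
      sum(-0.5 * (log(2 * pi) + v) - theta[idx$B]^2 / (2 * exp(v))) +
      sum(stats::dnorm(theta[c(idx$a, idx$alpha)], 0, biasPriorSd,
                       log = TRUE)) +
      sum(ah * log(bh) - lgamma(ah) - ah * u - bh * exp(-u)) +
      ao * log(bo) - lgamma(ao) - ao * v - bo * exp(-v)
    lp
  }
  gradPrior <- function(theta) {
    W <- matrix(theta[idx$W], p, H)
    u <- theta[idx$logSigma2]; v <- theta[idx$logTau2]
    s2 <- exp(u); t2 <- exp(v)
    g <- numeric(idx$total)
    g[idx$W] <- -W / s2            # recycles s2 down rows: W is p x H
    g[idx$a] <- -theta[idx$a] / biasPriorSd^2
    g[idx$B] <- -theta[idx$B] / t2
    g[idx$alpha] <- -theta[idx$alpha] / biasPriorSd^2
    g[idx$logSigma2] <- -0.5 * H + rowSums(W^2) / (2 * s2) - ah +
      bh / s2
    g[idx$logTau2] <- -0.5 * length(idx$B) +
      sum(theta[idx$B]^2) / (2 * t2) - ao + bo / t2
    g
  }
  list(logLik = logLik, gradLik = gradLik, logPrior = logPrior,
       gradPrior = gradPrior, index = idx, shape = c(p, H, k))
}

#' Gradient of the BNN log joint
#'
#' Exact analytic gradient of [logJoint()] with respect to the
#' unconstrained parameterization (weights, biases, log ARD scales),
#' computed by backpropagation through the two network layers plus the
#' prior terms. Returned in the same [NetworkState-class] shape, with the
#' scale components holding d/d(log sigma^2) and d/d(log tau^2).
#'
#' @inheritParams logJoint
#' @return a list with components `hiddenWeights`, `hiddenBiases`,
#'   `outputWeights`, `outputBiases`, `logArdScales`, `logOutputScale`.
#' @seealso [logJoint()]
#' @export
gradLogJoint <- function(state, genotypes, responses,
                         hyper = ardHyper()) {
  p <- nrow(state@hiddenWeights); H <- ncol(state@hiddenWeights)
  k <- ncol(state@outputWeights)
  tgt <- bnnTarget(genotypes, responses, H, hyper)
  theta <- packState(state)
  g <- tgt$gradLik(theta) + tgt$gradPrior(theta)
  idx <- tgt$index
  list(hiddenWeights = matrix(g[idx$W], p, H),
       hiddenBiases = g[idx$a],
       outputWeights = matrix(g[idx$B], H, k),
       outputBiases = g[idx$alpha],
       logArdScales = g[idx$logSigma2],
       logOutputScale = g[idx$logTau2])
}
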
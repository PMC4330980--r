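#' HMC settings constructor
#'
#' Defaults are the tuning used for the simulation study: step size 0.02,
#' 20 leapfrog steps, momentum persistence 0.75, initial annealing
#' temperature 1000, 375 iterations with the first 25 discarded as
#' burn-in.
#'
#' @param stepSize leapfrog step size.
#' @param nLeapfrog leapfrog steps per iteration.
#' @param momentumPersistence partial momentum-refresh coefficient in
#'   `[0, 1)`.
#' @param initialTemperature initial annealing temperature (>= 1).
#' @param nIterations total iterations.
#' @param nBurnin burn-in iterations (discarded; the annealing
#'   temperature reaches 1 at the last burn-in iteration).
#' @param seed integer RNG seed.
#' @return an [HMCSettings-class].
#' @export
hmcSettings <- function(stepSize = 0.02, nLeapfrog = 20L,
                        momentumPersistence = 0.75,
                        initialTemperature = 1000,
                        nIterations = 375L, nBurnin = 25L, seed = 1L) {
  new("HMCSettings", stepSize = stepSize,
      nLeapfrog = as.integer(nLeapfrog),
      momentumPersistence = momentumPersistence,
      initialTemperature = initialTemperature,
      nIterations = as.integer(nIterations),
      nBurnin = as.integer(nBurnin), seed = as.integer(seed))
}

#' Leapfrog integration
#'
#' Standard leapfrog (Stoermer-Verlet) integrator for Hamiltonian
#' dynamics with identity mass matrix: a half step on the momentum,
#' alternating full position/momentum steps, and a final momentum half
#' step. Time-reversible and second-order accurate, so the energy error
#' of a trajectory scales as the square of the step size.
#'
#' @param position,momentum numeric vectors of equal length.
#' @param stepSize positive step size.
#' @param nSteps number of full steps.
#' @param gradFn function returning the gradient of the log target
#'   density at a position.
#' @return list with elements `position`, `momentum`; `divergent` is TRUE
#'   when a non-finite gradient or coordinate was met (the trajectory is
#'   then unusable and the proposing iteration must be rejected).
#' @examples
#' # harmonic oscillator: -x is the gradient of log N(0,1)
#' leapfrog(1, 0, 0.1, 10, function(x) -x)
#' @export
leapfrog <- function(position, momentum, stepSize, nSteps, gradFn) {
  q <- position; m <- momentum
  g <- gradFn(q)
  if (any(!is.finite(g)))
    return(list(position = q, momentum = m, divergent = TRUE))
  m <- m + 0.5 * stepSize * g
  for (s in seq_len(nSteps)) {
    q <- q + stepSize * m
    g <- gradFn(q)
    if (any(!is.finite(g)) || any(!is.finite(q)))
      return(list(position = q, momentum = m, divergent = TRUE))
    m <- m + stepSize * g * (if (s < nSteps) 1 else 0.5)
  }
  list(position = q, momentum = m, divergent = FALSE)
}

# Geometric annealing schedule: temperature T_t = max(1, T0 * r^t) with r
# chosen so that T reaches 1 at the last burn-in iteration. The
# temperature relaxes the Metropolis test during burn-in (see hmcSample);
# after burn-in T = 1 and the chain targets the exact posterior.
annealTemperature <- function(iter, t0, nBurnin) {
  if (t0 <= 1 || nBurnin == 0L || iter > nBurnin) return(1)
  r <- t0^(-1 / nBurnin)
  max(1, t0 * r^iter)
}

#' Hamiltonian Monte Carlo with partial momentum refresh
#'
#' Metropolis-adjusted HMC on a target split into a likelihood part and a
#' prior part. Each iteration the momentum is partially refreshed,
#' `m <- gamma * m + sqrt(1 - gamma^2) * xi` with `gamma` the momentum
#' persistence and `xi` standard normal; a leapfrog trajectory is
#' proposed; and the Metropolis test accepts or rejects it, negating the
#' persistent momentum on rejection (required for correctness of the
#' persistent-momentum variant). During burn-in an annealing temperature
#' decaying geometrically from `initialTemperature` to 1 relaxes the
#' Metropolis test (acceptance probability `exp(-dH / T)`), letting the
#' early chain cross energy barriers it would otherwise reject; the
#' leapfrog dynamics always follow the exact (untempered) posterior
#' gradient, and once the temperature reaches 1 at the end of burn-in
#' the transition kernel is exact. (Dividing the log-likelihood itself
#' by the temperature is the more common reading of annealed HMC, but on
#' this posterior the flattened early target detaches the weights from
#' the data and strands chains in high-curvature states; see the methods
#' vignette.)
#'
#' @param logLikFn,gradLikFn log-likelihood and its gradient as functions
#'   of the position vector (use the target itself and `logPriorFn = 0`
#'   functions for a plain target).
#' @param logPriorFn,gradPriorFn log-prior and its gradient; pass
#'   `function(q) 0` and `function(q) numeric(length(q))` for an
#'   untempered plain target.
#' @param init initial position vector.
#' @param settings an [HMCSettings-class].
#' @return list with `draws` (matrix, post-burn-in positions by row),
#'   `acceptanceRate`, and `finalPosition`.
#' @seealso [bnnSample()] for the network front end.
#' @examples
#' s <- hmcSettings(stepSize = 0.2, nLeapfrog = 10, nIterations = 200,
#'                  nBurnin = 20, initialTemperature = 10, seed = 1)
#' out <- hmcSample(function(q) -0.5 * sum(q^2), function(q) -q,
#'                  function(q) 0, function(q) numeric(length(q)),
#'                  rnorm(3), s)
#' out$acceptanceRate
#' @export
hmcSample <- function(logLikFn, gradLikFn, logPriorFn, gradPriorFn,
                      init, settings) {
  stopifnot(is(settings, "HMCSettings"))
  set.seed(settings@seed)
  d <- length(init)
  q <- as.numeric(init)
  m <- stats::rnorm(d)
  gamma <- settings@momentumPersistence
  nIter <- settings@nIterations
  nBurn <- settings@nBurnin
  nKeep <- nIter - nBurn
  draws <- matrix(NA_real_, nKeep, d)
  nAccept <- 0L
  rejectStreak <- 0L
  warned <- FALSE

  logPost <- function(x) logLikFn(x) + logPriorFn(x)
  gradPost <- function(x) gradLikFn(x) + gradPriorFn(x)

  for (t in seq_len(nIter)) {
    temp <- annealTemperature(t, settings@initialTemperature, nBurn)

    m <- gamma * m + sqrt(1 - gamma^2) * stats::rnorm(d)
    h0 <- -logPost(q) + 0.5 * sum(m^2)
    prop <- leapfrog(q, m, settings@stepSize, settings@nLeapfrog,
                     gradPost)
    accept <- FALSE
    if (!prop$divergent) {
      h1 <- -logPost(prop$position) + 0.5 * sum(prop$momentum^2)
      if (is.finite(h1) &&
          log(stats::runif(1)) < (h0 - h1) / temp) accept <- TRUE
    }
    if (accept) {
      q <- prop$position
      m <- prop$momentum
      nAccept <- nAccept + 1L
      rejectStreak <- 0L
    } else {
      m <- -m   # momentum flip on rejection keeps detailed balance
      rejectStreak <- rejectStreak + 1L
      if (rejectStreak >= 50L && !warned) {
        warning("50 consecutive HMC rejections; consider a smaller ",
                "step size", call. = FALSE)
        warned <- TRUE
      }
    }
    if (t > nBurn) draws[t - nBurn, ] <- q
  }
  list(draws = draws, acceptanceRate = nAccept / nIter,
       finalPosition = q)
}

#' Sample the BNN posterior for a dataset
#'
#' Front end tying the network model to the sampler: builds the
#' likelihood/prior/gradient closures for the given data, initializes a
#' small-weight [NetworkState-class], and runs [hmcSample()] with the
#' given settings. Responses should be standardized (see
#' [normalizeResponses()]); a warning is issued otherwise, since the
#' unit-variance Gaussian likelihood assumes it.
#'
#' @param genotypes n x p genotype matrix, or a
#'   [DoseResponseExperiment-class] (then `responses` may be omitted and
#'   is standardized automatically).
#' @param responses n x k response matrix.
#' @param nHidden number of hidden units (default 10).
#' @param hyper an [ARDHyper-class].
#' @param settings an [HMCSettings-class].
#' @return a [PosteriorSamples-class].
#' @examples
#' \donttest{
#' d <- simulateDataset(
#'   simulationDesign(nIndividuals = 200, nBackgroundSnps = 8, seed = 5),
#'   geneticModelSpec("additive", theta = 0.3, causalMaf = 0.3))
#' ps <- bnnSample(d, settings = hmcSettings(nIterations = 50L,
#'                                           nBurnin = 10L, seed = 5))
#' ps
#' }
#' @export
bnnSample <- function(genotypes, responses = NULL, nHidden = 10L,
                      hyper = ardHyper(), settings = hmcSettings()) {
  if (is(genotypes, "DoseResponseExperiment")) {
    if (is.null(responses))
      responses <- normalizeResponses(genotypes@responses)
    genotypes <- genotypes@genotypes
  }
  X <- as.matrix(genotypes); Y <- as.matrix(responses)
  if (nrow(X) != nrow(Y))
    stopInvalid("genotypes and responses must have the same rows")
  if (max(abs(colMeans(Y))) > 0.1 ||
      max(abs(apply(Y, 2, stats::sd) - 1)) > 0.1)
    warning("responses do not look standardized; the unit-variance ",
            "likelihood assumes mean 0, variance 1 per dose column",
            call. = FALSE)
  ids <- colnames(X) %||% sprintf("snp%04d", seq_len(ncol(X)))
  tgt <- bnnTarget(X, Y, nHidden, hyper)
  set.seed(deriveSeed(settings@seed, 7L))
  init <- packState(networkState(ncol(X), nHidden, ncol(Y), hyper))
  out <- hmcSample(tgt$logLik, tgt$gradLik, tgt$logPrior, tgt$gradPrior,
                   init, settings)
  new("PosteriorSamples", draws = out$draws,
      shape = as.integer(tgt$shape), markerIds = ids,
      acceptanceRate = out$acceptanceRate, settings = settings)
}
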
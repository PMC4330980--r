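#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Two-locus genetic model specification
#'
#' Describes which genetic architecture generated (or is assumed to have
#' generated) a simulated dose-response dataset: the model kind, the per-SNP
#' effect size theta, the minor allele frequency (MAF) of the two causal
#' loci, the residual noise scale, and the positions of the causal columns
#' in the genotype matrix.
#'
#' The three model kinds share a multiplicative structure around the mean
#' dose-response curve \eqn{\mu_k}:
#' \describe{
#'   \item{additive}{\eqn{y_{ik} = \mu_k (1 + \frac{\theta}{2} S_1 -
#'     \frac{\theta}{2} S_2 + \epsilon)}}
#'   \item{additive_interaction}{adds \eqn{+\frac{\theta}{2} S_1 S_2} inside
#'     the parenthesis}
#'   \item{interaction_only}{\eqn{y_{ik} = \mu_k (1 + \frac{\theta}{2}
#'     S_1 S_2 + \epsilon)}}
#' }
#' where \eqn{S_1, S_2 \in \{0,1,2\}} count minor alleles at the two causal
#' loci and \eqn{\epsilon} is Gaussian noise.
#'
#' @slot modelKind one of `"additive"`, `"additive_interaction"`,
#'   `"interaction_only"`.
#' @slot theta per-SNP effect size in `[0, 1]`; a subject homozygous for the
#'   minor allele at one causal locus deviates by `theta` (100*theta percent)
#'   from the baseline mean.
#' @slot causalMaf minor allele frequency of the two causal loci, in
#'   `(0, 0.5]`.
#' @slot noiseScale scale of the Gaussian noise term (default 0.1).
#' @slot noiseIsSd if `TRUE` (default) `noiseScale` is the standard
#'   deviation; if `FALSE` it is the variance.
#' @slot causalIndices integer pair: genotype-matrix columns of the two
#'   causal loci.
#' @seealso [geneticModelSpec()] for the user-facing constructor,
#'   [simulateDataset()].
#' @export
setClass("GeneticModelSpec",
  representation(
    modelKind = "character",
    theta = "numeric",
    causalMaf = "numeric",
    noiseScale = "numeric",
    noiseIsSd = "logical",
    causalIndices = "integer"
  )
)

setValidity("GeneticModelSpec", function(object) {
  msg <- character()
  if (length(object@modelKind) != 1L ||
      !object@modelKind %in% c("additive", "additive_interaction",
                               "interaction_only"))
    msg <- c(msg, "modelKind must be one of 'additive', 'additive_interaction', 'interaction_only'")
  if (length(object@theta) != 1L || is.na(object@theta) ||
      object@theta < 0 || object@theta > 1)
    msg <- c(msg, "theta (effect size) must lie in [0, 1]")
  if (length(object@causalMaf) != 1L || is.na(object@causalMaf) ||
      object@causalMaf <= 0 || object@causalMaf > 0.5)
    msg <- c(msg, "causalMaf must lie in (0, 0.5]")
  if (length(object@noiseScale) != 1L || is.na(object@noiseScale) ||
      object@noiseScale < 0)
    msg <- c(msg, "noiseScale must be non-negative (0 gives noise-free data)")
  if (length(object@causalIndices) != 2L ||
      anyNA(object@causalIndices) ||
      object@causalIndices[1] == object@causalIndices[2] ||
      any(object@causalIndices < 1L))
    msg <- c(msg, "causalIndices must be two distinct positive indices")
  if (length(msg)) msg else TRUE
})

#' Simulation design for a synthetic dose-response GWAS dataset
#'
#' The non-genetic side of a simulation: sample size, number of background
#' (non-causal) markers, the MAF range background markers are drawn from,
#' the dose grid, and the seed.
#'
#' @slot nIndividuals number of individuals n (>= 1).
#' @slot nBackgroundSnps number of background SNPs (>= 0); total marker
#'   count is `nBackgroundSnps + 2`.
#' @slot backgroundMafRange length-2 numeric, a sub-interval of (0, 0.5];
#'   background MAFs are drawn uniformly from it.
#' @slot doses strictly increasing positive concentrations (the dose grid).
#' @slot hillExponent exponent of the baseline hill-slope mean curve.
#' @slot seed integer RNG seed.
#' @seealso [simulationDesign()], [simulateDataset()]
#' @export
setClass("SimulationDesign",
  representation(
    nIndividuals = "integer",
    nBackgroundSnps = "integer",
    backgroundMafRange = "numeric",
    doses = "numeric",
    hillExponent = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationDesign", function(object) {
  msg <- character()
  if (length(object@nIndividuals) != 1L || object@nIndividuals < 1L)
    msg <- c(msg, "nIndividuals must be >= 1")
  if (length(object@nBackgroundSnps) != 1L || object@nBackgroundSnps < 0L)
    msg <- c(msg, "nBackgroundSnps must be >= 0")
  r <- object@backgroundMafRange
  if (length(r) != 2L || anyNA(r) || r[1] > r[2] || r[1] <= 0 || r[2] > 0.5)
    msg <- c(msg, "backgroundMafRange must be an interval within (0, 0.5]")
  d <- object@doses
  if (length(d) < 1L || anyNA(d) || any(d <= 0) ||
      (length(d) > 1L && any(diff(d) <= 0)))
    msg <- c(msg, "doses must be strictly positive and strictly increasing")
  if (length(object@hillExponent) != 1L || is.na(object@hillExponent))
    msg <- c(msg, "hillExponent must be a single real")
  if (length(msg)) msg else TRUE
})

#' Dose-response experiment container
#'
#' Holds an n x p genotype matrix of minor-allele counts (entries 0/1/2), an
#' n x k matrix of continuous responses at k increasing concentrations, the
#' dose grid, and — for simulated data — the baseline mean curve and the
#' generating [GeneticModelSpec-class] ("truth" metadata).
#'
#' @slot genotypes integer matrix, n individuals x p markers, entries in
#'   {0,1,2}; column names are marker ids.
#' @slot responses numeric matrix, n individuals x k doses.
#' @slot doses numeric length k, strictly increasing positive
#'   concentrations.
#' @slot meanCurve baseline mean response at each dose (length k), or NULL
#'   for imported data.
#' @slot truth the generating [GeneticModelSpec-class], or NULL for
#'   imported data.
#' @seealso [simulateDataset()], [readDataset()], [genotypes()],
#'   [responses()]
#' @export
setClass("DoseResponseExperiment",
  representation(
    genotypes = "matrix",
    responses = "matrix",
    doses = "numeric",
    meanCurve = "numericOrNULL",
    truth = "ANY"
  )
)

setValidity("DoseResponseExperiment", function(object) {
  msg <- character()
  G <- object@genotypes
  Y <- object@responses
  if (!all(G %in% c(0, 1, 2)))
    msg <- c(msg, "genotype entries must be in {0, 1, 2}")
  if (nrow(G) != nrow(Y))
    msg <- c(msg, "genotypes and responses must have the same number of rows")
  if (ncol(Y) != length(object@doses))
    msg <- c(msg, "response column count must equal the dose-grid length")
  if (anyNA(Y) || any(!is.finite(Y)))
    msg <- c(msg, "responses must be finite")
  if (!is.null(object@meanCurve) &&
      length(object@meanCurve) != length(object@doses))
    msg <- c(msg, "meanCurve must have one entry per dose")
  tr <- object@truth
  if (!is.null(tr)) {
    if (!is(tr, "GeneticModelSpec"))
      msg <- c(msg, "truth must be a GeneticModelSpec or NULL")
    else if (any(tr@causalIndices > ncol(G)))
      msg <- c(msg, "truth causalIndices must be valid genotype columns")
  }
  if (length(msg)) msg else TRUE
})

#' ARD prior hyper-parameters
#'
#' Shape/rate pairs of the inverse-gamma hyper-priors in the automatic
#' relevance determination (ARD) hierarchy: one pair for the per-input
#' hidden-layer scales \eqn{\sigma_j^2}, one for the single shared
#' output-weight scale.
#'
#' @slot hiddenShape,hiddenRate inverse-gamma shape/rate for the per-SNP
#'   hidden-weight scales (defaults 3 and 1).
#' @slot outputShape,outputRate inverse-gamma shape/rate for the shared
#'   output-weight scale (defaults 0.1 and 0.1).
#' @seealso [ardHyper()], [logJoint()]
#' @export
setClass("ARDHyper",
  representation(
    hiddenShape = "numeric", hiddenRate = "numeric",
    outputShape = "numeric", outputRate = "numeric"
  )
)

setValidity("ARDHyper", function(object) {
  vals <- c(object@hiddenShape, object@hiddenRate,
            object@outputShape, object@outputRate)
  if (length(vals) != 4L || anyNA(vals) || any(vals <= 0))
    "all ARD hyper-parameters must be positive reals" else TRUE
})

#' Bayesian neural network parameter state
#'
#' All parameters of the one-hidden-layer network: hidden weights and
#' biases, output weights and biases, the per-input ARD scales
#' \eqn{\sigma_j^2}, and the shared output-weight scale.
#'
#' The network maps a genotype row \eqn{x} through \eqn{H} logistic hidden
#' units \eqn{h_j(x) = \mathrm{logit}^{-1}(a_j + x^T w_j)} to \eqn{k}
#' linear outputs \eqn{f_k(x) = \alpha_k + \sum_j h_j(x)\beta_{kj}}.
#'
#' @slot hiddenWeights p x H matrix; column j holds the weights of hidden
#'   unit j, row i the weights fanning out of input SNP i.
#' @slot hiddenBiases length-H hidden biases.
#' @slot outputWeights H x k matrix of output-layer weights.
#' @slot outputBiases length-k output biases.
#' @slot ardScales length-p positive ARD scales \eqn{\sigma_j^2}, one per
#'   input SNP.
#' @slot outputScale single positive shared scale of the output weights.
#' @seealso [networkState()], [forward()], [logJoint()]
#' @export
setClass("NetworkState",
  representation(
    hiddenWeights = "matrix",
    hiddenBiases = "numeric",
    outputWeights = "matrix",
    outputBiases = "numeric",
    ardScales = "numeric",
    outputScale = "numeric"
  )
)

setValidity("NetworkState", function(object) {
  msg <- character()
  p <- nrow(object@hiddenWeights); H <- ncol(object@hiddenWeights)
  k <- ncol(object@outputWeights)
  if (length(object@hiddenBiases) != H)
    msg <- c(msg, "hiddenBiases length must equal the hidden-unit count")
  if (nrow(object@outputWeights) != H)
    msg <- c(msg, "outputWeights must have one row per hidden unit")
  if (length(object@outputBiases) != k)
    msg <- c(msg, "outputBiases length must equal the output count")
  if (length(object@ardScales) != p)
    msg <- c(msg, "ardScales length must equal the input count")
  if (any(!is.finite(object@ardScales)) || any(object@ardScales <= 0))
    msg <- c(msg, "ardScales must be positive and finite")
  if (length(object@outputScale) != 1L ||
      !is.finite(object@outputScale) || object@outputScale <= 0)
    msg <- c(msg, "outputScale must be a single positive real")
  allw <- c(object@hiddenWeights, object@hiddenBiases,
            object@outputWeights, object@outputBiases)
  if (any(!is.finite(allw)))
    msg <- c(msg, "weights and biases must be finite")
  if (length(msg)) msg else TRUE
})

#' Hamiltonian Monte Carlo settings
#'
#' Tuning parameters of the HMC sampler: leapfrog step size and step count,
#' the partial momentum-refresh coefficient (momentum persistence), the
#' initial annealing temperature applied to the likelihood during burn-in,
#' iteration counts and the seed.
#'
#' @slot stepSize positive leapfrog step size (default 0.02).
#' @slot nLeapfrog positive number of leapfrog steps per iteration
#'   (default 20).
#' @slot momentumPersistence gamma in `[0, 1)`: momentum is refreshed as
#'   `p <- gamma * p + sqrt(1 - gamma^2) * xi` each iteration (default
#'   0.75; 0 gives standard full-refresh HMC).
#' @slot initialTemperature initial annealing temperature T0 (default
#'   1000); the log-likelihood is divided by a temperature that decays
#'   geometrically from T0 to 1 over the burn-in, then stays at 1.
#' @slot nIterations total iterations (default 375).
#' @slot nBurnin burn-in iterations discarded from the output (default 25).
#' @slot seed integer RNG seed.
#' @seealso [hmcSettings()], [hmcSample()], [bnnSample()]
#' @export
setClass("HMCSettings",
  representation(
    stepSize = "numeric",
    nLeapfrog = "integer",
    momentumPersistence = "numeric",
    initialTemperature = "numeric",
    nIterations = "integer",
    nBurnin = "integer",
    seed = "integer"
  )
)

setValidity("HMCSettings", function(object) {
  msg <- character()
  if (object@stepSize <= 0) msg <- c(msg, "stepSize must be > 0")
  if (object@nLeapfrog < 1L) msg <- c(msg, "nLeapfrog must be >= 1")
  g <- object@momentumPersistence
  if (is.na(g) || g < 0 || g >= 1)
    msg <- c(msg, "momentumPersistence must lie in [0, 1)")
  if (object@initialTemperature < 1)
    msg <- c(msg, "initialTemperature must be >= 1")
  if (object@nBurnin < 0L) msg <- c(msg, "nBurnin must be >= 0")
  if (object@nBurnin >= object@nIterations)
    msg <- c(msg, "nBurnin must be smaller than nIterations")
  if (length(msg)) msg else TRUE
})

#' Posterior samples from the BNN sampler
#'
#' Post-burn-in draws of the network parameters, stored as a draws x
#' parameters matrix in the unconstrained parameterization (weights,
#' biases, log ARD scales, log output scale), together with the network
#' shape, marker ids, acceptance rate and the settings used.
#'
#' @slot draws numeric matrix, one row per retained iteration, one column
#'   per unconstrained parameter.
#' @slot shape integer triple `(p, H, k)`.
#' @slot markerIds marker labels (length p).
#' @slot acceptanceRate Metropolis acceptance rate over all iterations.
#' @slot settings the [HMCSettings-class] used.
#' @seealso [bnnSample()], [ardSamples()], [scoreSnps()]
#' @export
setClass("PosteriorSamples",
  representation(
    draws = "matrix",
    shape = "integer",
    markerIds = "character",
    acceptanceRate = "numeric",
    settings = "HMCSettings"
  )
)

setValidity("PosteriorSamples", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be three positive integers (p, H, k)")
  if (length(object@markerIds) != object@shape[1])
    msg <- c(msg, "markerIds length must equal the input count")
  if (object@acceptanceRate < 0 || object@acceptanceRate > 1)
    msg <- c(msg, "acceptanceRate must lie in [0, 1]")
  nexp <- object@settings@nIterations - object@settings@nBurnin
  if (nrow(object@draws) != nexp)
    msg <- c(msg, "draws must contain nIterations - nBurnin rows")
  if (length(msg)) msg else TRUE
})

#' MANOVA scan result
#'
#' Per-marker multivariate association results with Bonferroni selection.
#' The `table` slot has one row per marker: the Wilks' lambda (or Pillai
#' trace) statistic, its F approximation with degrees of freedom, the
#' p-value and the selection flag.
#'
#' @slot table data.frame with columns `marker_id`, `statistic`,
#'   `approx_f`, `df1`, `df2`, `p_value`, `selected`.
#' @slot alpha family-wise error level.
#' @slot bonferroniThreshold `alpha / nTested`.
#' @slot nTested number of non-degenerate markers tested.
#' @slot degenerate ids of markers skipped as degenerate (monomorphic or
#'   rank-deficient).
#' @slot statistic `"Wilks"` or `"Pillai"`.
#' @seealso [manovaScan()], [selectedMarkers()]
#' @export
setClass("ManovaScan",
  representation(
    table = "data.frame",
    alpha = "numeric",
    bonferroniThreshold = "numeric",
    nTested = "integer",
    degenerate = "character",
    statistic = "character"
  )
)

setValidity("ManovaScan", function(object) {
  msg <- character()
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  pv <- object@table$p_value
  if (length(pv) && (any(pv < 0, na.rm = TRUE) || any(pv > 1, na.rm = TRUE)))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
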
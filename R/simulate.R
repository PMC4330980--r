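#' Construct a two-locus genetic model specification
#'
#' User-facing constructor for [GeneticModelSpec-class]. See that class for
#' the three model equations.
#'
#' @param modelKind `"additive"`, `"additive_interaction"` or
#'   `"interaction_only"` (prefix matching allowed).
#' @param theta per-SNP effect size in `[0, 1]`.
#' @param causalMaf minor allele frequency of the causal loci, in
#'   `(0, 0.5]`.
#' @param noiseScale Gaussian noise scale (default 0.1).
#' @param noiseIsSd interpret `noiseScale` as the standard deviation
#'   (default `TRUE`) or as the variance (`FALSE`).
#' @param causalIndices genotype columns of the two causal loci
#'   (default 1 and 2).
#' @return a validated [GeneticModelSpec-class].
#' @examples
#' geneticModelSpec("interaction_only", theta = 0.05, causalMaf = 0.4)
#' @export
geneticModelSpec <- function(modelKind = c("additive",
                                           "additive_interaction",
                                           "interaction_only"),
                             theta, causalMaf,
                             noiseScale = 0.1, noiseIsSd = TRUE,
                             causalIndices = c(1L, 2L)) {
  modelKind <- match.arg(modelKind)
  new("GeneticModelSpec", modelKind = modelKind, theta = theta,
      causalMaf = causalMaf, noiseScale = noiseScale,
      noiseIsSd = noiseIsSd, causalIndices = as.integer(causalIndices))
}

#' Default six-point dose grid
#'
#' The concentration grid used throughout the simulation study:
#' \eqn{10^{-4} \cdot \{0.03125, 0.0625, 0.10, 0.25, 0.5, 1.25\}}. On this
#' scale the baseline hill-slope mean curve is nearly flat just below 1;
#' `unitScale = TRUE` drops the \eqn{10^{-4}} factor, giving a curve that
#' falls from ~0.99 to ~0.42 across the grid (see the methods vignette for
#' why both are supported).
#'
#' @param unitScale drop the `1e-4` scale factor (default `FALSE`).
#' @return numeric vector of 6 increasing concentrations.
#' @examples
#' defaultDoseGrid()
#' defaultDoseGrid(unitScale = TRUE)
#' @export
defaultDoseGrid <- function(unitScale = FALSE) {
  g <- c(0.03125, 0.0625, 0.10, 0.25, 0.5, 1.25)
  if (unitScale) g else 1e-4 * g
}

#' Construct a simulation design
#'
#' @param nIndividuals number of individuals (default 2000).
#' @param nBackgroundSnps number of background SNPs (default 998, giving
#'   1000 markers in total with the two causal loci).
#' @param backgroundMafRange interval within (0, 0.5] from which background
#'   MAFs are drawn uniformly (default `c(0.01, 0.5)`).
#' @param doses dose grid (default [defaultDoseGrid()]).
#' @param hillExponent hill exponent of the baseline mean curve
#'   (default -1.5).
#' @param seed integer RNG seed (default 1).
#' @return a validated [SimulationDesign-class].
#' @examples
#' simulationDesign(nIndividuals = 100, nBackgroundSnps = 8, seed = 7)
#' @export
simulationDesign <- function(nIndividuals = 2000L, nBackgroundSnps = 998L,
                             backgroundMafRange = c(0.01, 0.5),
                             doses = defaultDoseGrid(),
                             hillExponent = -1.5, seed = 1L) {
  new("SimulationDesign", nIndividuals = as.integer(nIndividuals),
      nBackgroundSnps = as.integer(nBackgroundSnps),
      backgroundMafRange = as.numeric(backgroundMafRange),
      doses = as.numeric(doses), hillExponent = hillExponent,
      seed = as.integer(seed))
}

#' Hill-slope baseline mean curve
#'
#' Evaluates the baseline mean dose-response
#' \eqn{\mu_k = 1 - 1/(1 + x_k^{e})} at each concentration \eqn{x_k},
#' with hill exponent \eqn{e = -1.5} by default. This is the unit-asymptote
#' special case of the four-parameter hill-slope model with Max = 1,
#' Min = 0 and IC50 = 1.
#'
#' @param doses strictly positive concentrations.
#' @param exponent hill exponent (default -1.5).
#' @return numeric vector of means, each in (0, 1).
#' @examples
#' hillSlopeMean(1)                     # 0.5
#' hillSlopeMean(defaultDoseGrid(unitScale = TRUE))
#' @export
hillSlopeMean <- function(doses, exponent = -1.5) {
  if (!length(doses) || anyNA(doses) || any(doses <= 0))
    stopInvalid("doses must be strictly positive")
  1 - 1 / (1 + doses^exponent)
}

#' Four-parameter hill-slope curve
#'
#' The parametric logistic dose-response model
#' \eqn{f(c) = Max - (Max - Min)/(1 + (c/IC_{50})^{-w})}, with upper and
#' lower asymptotes Max and Min, potency IC50 (the concentration giving
#' half-maximal response) and hill slope w.
#'
#' @param conc strictly positive concentrations.
#' @param max,min upper and lower asymptotes (`max > min`).
#' @param ic50 positive half-maximal concentration.
#' @param hillSlope slope parameter w.
#' @return responses at each concentration.
#' @examples
#' hillSlope(1, max = 1, min = 0, ic50 = 1, hillSlope = 1.5)  # 0.5
#' @export
hillSlope <- function(conc, max = 1, min = 0, ic50 = 1, hillSlope = 1) {
  if (any(conc <= 0)) stopInvalid("concentrations must be positive")
  if (max <= min) stopInvalid("max asymptote must exceed min asymptote")
  if (ic50 <= 0) stopInvalid("ic50 must be positive")
  max - (max - min) / (1 + (conc / ic50)^(-hillSlope))
}

#' Sample one genotype column under Hardy-Weinberg proportions
#'
#' Draws n independent minor-allele counts as Binomial(2, maf), i.e.
#' genotype proportions \eqn{\{(1-q)^2, 2q(1-q), q^2\}} with \eqn{q} the
#' MAF. Loci are simulated independently (no linkage disequilibrium).
#'
#' @param n number of individuals.
#' @param maf minor allele frequency in `[0, 0.5]`.
#' @return integer vector of length n with entries in {0, 1, 2}.
#' @examples
#' set.seed(1); table(sampleGenotypeColumn(1000, 0.5)) / 1000
#' @export
sampleGenotypeColumn <- function(n, maf) {
  if (length(maf) != 1L || is.na(maf) || maf < 0 || maf > 0.5)
    stopInvalid("maf must lie in [0, 0.5]")
  if (n < 1L) stopInvalid("n must be >= 1")
  stats::rbinom(n, 2L, maf)
}

#' Noise-free genetic multiplier of the mean curve
#'
#' The deterministic factor multiplying the baseline mean \eqn{\mu_k} for
#' an individual with `s1` and `s2` minor alleles at the two causal loci:
#' \describe{
#'   \item{additive}{\eqn{1 + \frac{\theta}{2} s_1 - \frac{\theta}{2} s_2}}
#'   \item{additive_interaction}{\eqn{1 + \frac{\theta}{2} s_1 -
#'     \frac{\theta}{2} s_2 + \frac{\theta}{2} s_1 s_2}}
#'   \item{interaction_only}{\eqn{1 + \frac{\theta}{2} s_1 s_2}}
#' }
#'
#' @param spec a [GeneticModelSpec-class].
#' @param s1,s2 minor-allele counts in {0, 1, 2}; vectorized.
#' @return numeric multiplier(s).
#' @examples
#' sp <- geneticModelSpec("additive", theta = 0.02, causalMaf = 0.3)
#' geneticMultiplier(sp, 2, 0)  # 1.02
#' @export
geneticMultiplier <- function(spec, s1, s2) {
  stopifnot(is(spec, "GeneticModelSpec"))
  if (!all(s1 %in% 0:2) || !all(s2 %in% 0:2))
    stopInvalid("s1 and s2 must be minor-allele counts in {0, 1, 2}")
  th2 <- spec@theta / 2
  switch(spec@modelKind,
    additive = 1 + th2 * s1 - th2 * s2,
    additive_interaction = 1 + th2 * s1 - th2 * s2 + th2 * s1 * s2,
    interaction_only = 1 + th2 * s1 * s2)
}

#' Simulate a dose-response GWAS dataset
#'
#' Generates a full synthetic dataset: two causal genotype columns at the
#' model's causal MAF, background columns at MAFs drawn uniformly from the
#' design's range, and responses
#' \deqn{y_{ik} = \mu_k \left( m(s_{1i}, s_{2i}) + \epsilon_{ik} \right)}
#' where \eqn{\mu_k} is the hill-slope mean curve, \eqn{m} is
#' [geneticMultiplier()] and \eqn{\epsilon_{ik}} is independent Gaussian
#' noise per individual and dose (heteroskedastic in the original response
#' units through the \eqn{\mu_k} factor). Fully reproducible from
#' `design@seed`.
#'
#' @param design a [SimulationDesign-class].
#' @param spec a [GeneticModelSpec-class]; its `causalIndices` place the
#'   causal loci among the `nBackgroundSnps + 2` columns.
#' @return a [DoseResponseExperiment-class] carrying truth metadata and
#'   the mean curve.
#' @examples
#' d <- simulateDataset(
#'   simulationDesign(nIndividuals = 50, nBackgroundSnps = 8, seed = 3),
#'   geneticModelSpec("additive", theta = 0.05, causalMaf = 0.3))
#' d
#' @export
simulateDataset <- function(design, spec) {
  stopifnot(is(design, "SimulationDesign"), is(spec, "GeneticModelSpec"))
  p <- design@nBackgroundSnps + 2L
  ci <- spec@causalIndices
  if (any(ci > p))
    stopInvalid("causalIndices exceed the total marker count (",
                p, ")")
  n <- design@nIndividuals
  k <- length(design@doses)
  set.seed(design@seed)
  mu <- hillSlopeMean(design@doses, design@hillExponent)

  bgMaf <- stats::runif(design@nBackgroundSnps,
                        design@backgroundMafRange[1],
                        design@backgroundMafRange[2])
  mafs <- numeric(p)
  mafs[ci] <- spec@causalMaf
  mafs[-ci] <- bgMaf
  G <- vapply(mafs, function(q) sampleGenotypeColumn(n, q), integer(n))
  colnames(G) <- sprintf("snp%04d", seq_len(p))
  colnames(G)[ci] <- c("causal1", "causal2")

  mult <- geneticMultiplier(spec, G[, ci[1]], G[, ci[2]])
  sdNoise <- if (spec@noiseIsSd) spec@noiseScale else sqrt(spec@noiseScale)
  eps <- matrix(stats::rnorm(n * k, 0, sdNoise), n, k)
  Y <- (mult + eps) %*% diag(mu, nrow = k)
  colnames(Y) <- format(design@doses, trim = TRUE, digits = 8)

  new("DoseResponseExperiment", genotypes = G, responses = Y,
      doses = design@doses, meanCurve = mu, truth = spec)
}

#' Standardize responses column-wise
#'
#' Normalizes each dose column to mean 0 and unit sample variance, the
#' preprocessing assumed by the unit-variance Gaussian likelihood of the
#' Bayesian neural network.
#'
#' @param x a [DoseResponseExperiment-class] or a numeric matrix.
#' @return object of the same kind with standardized response columns.
#' @examples
#' round(colMeans(normalizeResponses(matrix(rnorm(40, 5, 3), 10, 4))), 12)
#' @export
normalizeResponses <- function(x) {
  Y <- if (is(x, "DoseResponseExperiment")) x@responses else as.matrix(x)
  sds <- apply(Y, 2, stats::sd)
  if (any(!is.finite(sds)) || any(sds == 0))
    stopInvalid("cannot standardize a constant response column (column ",
                paste(which(sds == 0 | !is.finite(sds)), collapse = ", "),
                ")")
  Ys <- scale(Y)
  attr(Ys, "scaled:center") <- NULL
  attr(Ys, "scaled:scale") <- NULL
  if (is(x, "DoseResponseExperiment")) {
    x@responses <- Ys
    x
  } else Ys
}
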
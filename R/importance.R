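#' Null reference threshold for ARD scales
#'
#' Builds the null-distribution threshold the per-SNP ARD posteriors are
#' compared against. Two constructions:
#' \describe{
#'   \item{pooled}{the `quantile` (default 95th) percentile of the ARD
#'     scale draws pooled across all inputs of the primary run — a cheap
#'     approximation that is valid when causal inputs are sparse;}
#'   \item{permutation}{re-runs the sampler on responses whose rows have
#'     been permuted (breaking any genotype-response association while
#'     keeping marginals) and returns the same pooled percentile from
#'     that null run.}
#' }
#'
#' @param samples a [PosteriorSamples-class] from the primary run.
#' @param mode `"pooled"` (default) or `"permutation"`.
#' @param genotypes,responses the data, required for `"permutation"`
#'   mode; `genotypes` may be a [DoseResponseExperiment-class].
#' @param nHidden,hyper network settings for the permutation re-run
#'   (match the primary run).
#' @param quantile pooled quantile (default 0.95).
#' @return single positive threshold on the sigma^2 scale.
#' @seealso [scoreSnps()]
#' @export
nullReference <- function(samples, mode = c("pooled", "permutation"),
                          genotypes = NULL, responses = NULL,
                          nHidden = NULL, hyper = ardHyper(),
                          quantile = 0.95) {
  mode <- match.arg(mode)
  stopifnot(is(samples, "PosteriorSamples"))
  if (!nrow(samples@draws)) stopInvalid("empty posterior sample")
  if (mode == "pooled")
    return(stats::quantile(ardSamples(samples), quantile, names = FALSE))
  if (is.null(genotypes))
    stopInvalid("permutation mode needs the genotype and response data")
  if (is(genotypes, "DoseResponseExperiment")) {
    if (is.null(responses))
      responses <- normalizeResponses(genotypes@responses)
    genotypes <- genotypes@genotypes
  }
  Y <- as.matrix(responses)
  nHidden <- nHidden %||% samples@shape[2]
  st <- samples@settings
  permSeed <- deriveSeed(st@seed, 104729L)
  set.seed(permSeed)
  Yperm <- Y[sample.int(nrow(Y)), , drop = FALSE]
  nullSettings <- hmcSettings(stepSize = st@stepSize,
                              nLeapfrog = st@nLeapfrog,
                              momentumPersistence = st@momentumPersistence,
                              initialTemperature = st@initialTemperature,
                              nIterations = st@nIterations,
                              nBurnin = st@nBurnin, seed = permSeed)
  nullRun <- bnnSample(genotypes, Yperm, nHidden = nHidden,
                       hyper = hyper, settings = nullSettings)
  stats::quantile(ardSamples(nullRun), quantile, names = FALSE)
}

#' Posterior probabilities of SNP involvement
#'
#' Converts ARD-scale posteriors into per-SNP posterior probabilities of
#' involvement: the probability for SNP j is the fraction of post-burn-in
#' draws with \eqn{\sigma_j^2} above the null reference threshold, and a
#' SNP is called causal when that probability exceeds the cut-off
#' (default 0.4).
#'
#' @param samples a [PosteriorSamples-class].
#' @param threshold positive null reference threshold (see
#'   [nullReference()]).
#' @param cutoff selection cut-off on the posterior probability, in
#'   (0, 1]; default 0.4.
#' @return data.frame with one row per marker: `marker_id`,
#'   `posterior_probability`, `ard_median`, `ard_q05`, `ard_q95`,
#'   `selected`.
#' @export
scoreSnps <- function(samples, threshold, cutoff = 0.4) {
  stopifnot(is(samples, "PosteriorSamples"))
  if (!nrow(samples@draws)) stopInvalid("empty posterior sample")
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0)
    stopInvalid("threshold must be a single positive real")
  if (cutoff <= 0 || cutoff > 1)
    stopInvalid("cutoff must lie in (0, 1]")
  s2 <- ardSamples(samples)
  prob <- colMeans(s2 > threshold)
  qs <- apply(s2, 2, stats::quantile, probs = c(0.05, 0.5, 0.95),
              names = FALSE)
  data.frame(marker_id = samples@markerIds,
             posterior_probability = unname(prob),
             ard_median = qs[2, ], ard_q05 = qs[1, ], ard_q95 = qs[3, ],
             selected = unname(prob > cutoff),
             stringsAsFactors = FALSE, row.names = NULL)
}
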
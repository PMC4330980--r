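#' Genotype matrix of an experiment
#'
#' @param x a [DoseResponseExperiment-class].
#' @return integer matrix of minor-allele counts (n individuals x p
#'   markers).
#' @examples
#' d <- simulateDataset(
#'   simulationDesign(nIndividuals = 20, nBackgroundSnps = 3, seed = 1),
#'   geneticModelSpec("additive", theta = 0.05, causalMaf = 0.3))
#' dim(genotypes(d))
#' @export
setMethod("genotypes", "DoseResponseExperiment", function(x) x@genotypes)

#' Response matrix of an experiment
#'
#' @param x a [DoseResponseExperiment-class].
#' @return numeric matrix of responses (n individuals x k doses).
#' @export
setMethod("responses", "DoseResponseExperiment", function(x) x@responses)

#' Dose grid of an experiment
#'
#' @param x a [DoseResponseExperiment-class].
#' @return numeric vector of k strictly increasing concentrations.
#' @export
setMethod("doses", "DoseResponseExperiment", function(x) x@doses)

#' Generating model ("truth") of a simulated experiment
#'
#' @param x a [DoseResponseExperiment-class].
#' @return the generating [GeneticModelSpec-class], or NULL for imported
#'   data.
#' @export
setMethod("truthSpec", "DoseResponseExperiment", function(x) x@truth)

#' Baseline mean dose-response curve of a simulated experiment
#'
#' @param x a [DoseResponseExperiment-class].
#' @return numeric vector of length k, or NULL for imported data.
#' @export
setMethod("meanCurve", "DoseResponseExperiment", function(x) x@meanCurve)

#' Marker identifiers
#'
#' @param x a [DoseResponseExperiment-class] or [PosteriorSamples-class].
#' @return character vector of marker labels.
#' @export
setMethod("markerIds", "DoseResponseExperiment",
          function(x) colnames(x@genotypes))

#' @rdname markerIds
#' @export
setMethod("markerIds", "PosteriorSamples", function(x) x@markerIds)

#' Posterior draws of the ARD scales
#'
#' Extracts the per-SNP ARD scale draws \eqn{\sigma_j^2} from a sampler
#' run, back-transformed from the log scale used during sampling.
#'
#' @param x a [PosteriorSamples-class].
#' @return numeric matrix, draws x p, columns named by marker id.
#' @seealso [scoreSnps()], [nullReference()]
#' @export
setMethod("ardSamples", "PosteriorSamples", function(x) {
  idx <- paramIndex(x@shape[1], x@shape[2], x@shape[3])
  s2 <- exp(x@draws[, idx$logSigma2, drop = FALSE])
  colnames(s2) <- x@markerIds
  s2
})

#' Metropolis acceptance rate of a sampler run
#'
#' @param x a [PosteriorSamples-class].
#' @return acceptance rate in `[0, 1]` over all iterations.
#' @export
setMethod("acceptanceRate", "PosteriorSamples", function(x) x@acceptanceRate)

#' Per-marker result table of a MANOVA scan
#'
#' @param x a [ManovaScan-class].
#' @return data.frame with columns `marker_id`, `statistic`, `approx_f`,
#'   `df1`, `df2`, `p_value`, `selected`.
#' @export
setMethod("scanTable", "ManovaScan", function(x) x@table)

#' Markers selected by a scan
#'
#' @param x a [ManovaScan-class].
#' @return character vector of marker ids passing the Bonferroni
#'   threshold.
#' @export
setMethod("selectedMarkers", "ManovaScan",
          function(x) x@table$marker_id[x@table$selected])

setMethod("show", "DoseResponseExperiment", function(object) {
  cat("DoseResponseExperiment\n",
      "  ", nrow(object@genotypes), " individuals, ",
      ncol(object@genotypes), " markers, ",
      length(object@doses), " doses\n", sep = "")
  if (!is.null(object@truth)) {
    tr <- object@truth
    cat("  truth: ", tr@modelKind, " model, theta = ", tr@theta,
        ", causal MAF = ", tr@causalMaf,
        ", causal columns = ", paste(tr@causalIndices, collapse = ", "),
        "\n", sep = "")
  }
})

setMethod("show", "GeneticModelSpec", function(object) {
  cat("GeneticModelSpec: ", object@modelKind,
      ", theta = ", object@theta,
      ", causal MAF = ", object@causalMaf,
      ", noise ", if (object@noiseIsSd) "sd" else "variance",
      " = ", object@noiseScale, "\n", sep = "")
})

setMethod("show", "NetworkState", function(object) {
  cat("NetworkState: ", nrow(object@hiddenWeights), " inputs -> ",
      ncol(object@hiddenWeights), " hidden -> ",
      ncol(object@outputWeights), " outputs\n", sep = "")
})

setMethod("show", "PosteriorSamples", function(object) {
  cat("PosteriorSamples: ", nrow(object@draws), " draws, network ",
      object@shape[1], " -> ", object@shape[2], " -> ", object@shape[3],
      ", acceptance rate ", round(object@acceptanceRate, 3), "\n", sep = "")
})

setMethod("show", "ManovaScan", function(object) {
  cat("ManovaScan (", object@statistic, "): ", object@nTested,
      " markers tested, alpha = ", object@alpha,
      ", Bonferroni threshold = ",
      format(object@bonferroniThreshold, digits = 4),
      ", ", sum(object@table$selected), " selected\n", sep = "")
  if (length(object@degenerate))
    cat("  degenerate markers skipped: ", length(object@degenerate), "\n",
        sep = "")
})
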
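#' Detection outcome of one method on one simulated dataset
#'
#' Runs a method's selection procedure (MANOVA Bonferroni set, or BNN
#' posterior-probability set at the 0.4 cut-off) and intersects the
#' selected markers with the dataset's true causal columns. A causal
#' locus counts as detected when its column is in the selected set;
#' accompanying background false positives do not disqualify the
#' detection.
#'
#' @param dataset a simulated [DoseResponseExperiment-class] with truth
#'   metadata.
#' @param method `"manova"` or `"bnn"`.
#' @param config named list of method settings. For `"manova"`: `alpha`
#'   (default 0.05). For `"bnn"`: `nHidden`, `hyper`, `settings`,
#'   `cutoff`, `nullMode`, `nullQuantile` (defaults as in [bnnSample()],
#'   [nullReference()] and [scoreSnps()]).
#' @return logical vector `c(both = ..., atLeastOne = ...)`.
#' @export
detectCausal <- function(dataset, method = c("manova", "bnn"),
                         config = list()) {
  method <- match.arg(method)
  stopifnot(is(dataset, "DoseResponseExperiment"))
  tr <- truthSpec(dataset)
  if (is.null(tr)) stopInvalid("dataset carries no truth metadata")
  causal <- markerIds(dataset)[tr@causalIndices]
  sel <- if (method == "manova") {
    sc <- manovaScan(genotypes(dataset),
                     normalizeResponses(responses(dataset)),
                     alpha = config$alpha %||% 0.05)
    selectedMarkers(sc)
  } else {
    settings <- config$settings %||% hmcSettings()
    ps <- bnnSample(genotypes(dataset),
                    normalizeResponses(responses(dataset)),
                    nHidden = config$nHidden %||% 10L,
                    hyper = config$hyper %||% ardHyper(),
                    settings = settings)
    thr <- nullReference(ps, mode = config$nullMode %||% "pooled",
                         genotypes = genotypes(dataset),
                         responses = normalizeResponses(
                           responses(dataset)),
                         quantile = config$nullQuantile %||% 0.95)
    imp <- scoreSnps(ps, thr, cutoff = config$cutoff %||% 0.4)
    imp$marker_id[imp$selected]
  }
  hits <- causal %in% sel
  c(both = all(hits), atLeastOne = any(hits))
}

#' Power sweep over effect size and MAF
#'
#' Replicate-level experiment harness: for every combination of `theta`
#' and `maf`, simulates `nReplicates` datasets under the given model and
#' design, runs each requested method, and estimates the power to detect
#' both causal loci and at least one. Replicate seeds are derived
#' deterministically from `baseSeed` per cell, so results for one cell
#' are unchanged by removing other cells from the sweep.
#'
#' @param thetas,mafs non-empty numeric grids.
#' @param modelKind the generating architecture.
#' @param nReplicates replicate datasets per cell.
#' @param design a [SimulationDesign-class] (its seed slot is overridden
#'   per replicate).
#' @param methods character subset of `c("manova", "bnn")`.
#' @param baseSeed integer master seed.
#' @param methodConfig named list of per-method config lists, e.g.
#'   `list(manova = list(alpha = 0.05), bnn = list(...))`.
#' @param noiseScale,noiseIsSd noise convention forwarded to the model
#'   spec.
#' @param out optional path: when given, the table is also written as
#'   TSV.
#' @return data.frame with one row per (model, method, theta, maf):
#'   `model`, `method`, `theta`, `maf`, `n_reps`, `power_both`,
#'   `power_at_least_one`.
#' @examples
#' \donttest{
#' runPowerSweep(thetas = 0.05, mafs = 0.3, nReplicates = 2,
#'               design = simulationDesign(nIndividuals = 500,
#'                                         nBackgroundSnps = 48),
#'               methods = "manova", baseSeed = 1)
#' }
#' @export
runPowerSweep <- function(thetas, mafs,
                          modelKind = c("additive",
                                        "additive_interaction",
                                        "interaction_only"),
                          nReplicates = 20L,
                          design = simulationDesign(),
                          methods = "manova", baseSeed = 1L,
                          methodConfig = list(),
                          noiseScale = 0.1, noiseIsSd = TRUE,
                          out = NULL) {
  modelKind <- match.arg(modelKind)
  stopifnot(length(thetas) >= 1L, length(mafs) >= 1L, nReplicates >= 1L)
  methods <- match.arg(methods, c("manova", "bnn"), several.ok = TRUE)
  grid <- expand.grid(theta = thetas, maf = mafs,
                      KEEP.OUT.ATTRS = FALSE)
  cells <- vector("list", nrow(grid) * length(methods))
  ci <- 0L
  for (g in seq_len(nrow(grid))) {
    th <- grid$theta[g]; q <- grid$maf[g]
    # cell index derived from the parameter values, not the grid
    # position, so cells are independent of the rest of the sweep
    cellKey <- c(round(th * 1e6), round(q * 1e6),
                 match(modelKind, c("additive", "additive_interaction",
                                    "interaction_only")))
    det <- list()
    for (m in methods) det[[m]] <- matrix(NA, nReplicates, 2)
    for (r in seq_len(nReplicates)) {
      d <- design
      d@seed <- deriveSeed(baseSeed, cellKey[1], cellKey[2],
                           cellKey[3], r)
      spec <- geneticModelSpec(modelKind, theta = th, causalMaf = q,
                               noiseScale = noiseScale,
                               noiseIsSd = noiseIsSd)
      dataset <- simulateDataset(d, spec)
      for (m in methods) {
        cfg <- methodConfig[[m]] %||% list()
        if (m == "bnn") {
          st <- cfg$settings %||% hmcSettings()
          st@seed <- deriveSeed(baseSeed, cellKey[1], cellKey[2],
                                cellKey[3], r, 2L)
          cfg$settings <- st
        }
        res <- tryCatch(detectCausal(dataset, m, cfg),
                        error = function(e) {
                          warning("replicate ", r, " (", m,
                                  ") failed: ", conditionMessage(e),
                                  call. = FALSE)
                          c(both = NA, atLeastOne = NA)
                        })
        det[[m]][r, ] <- res
      }
    }
    for (m in methods) {
      ok <- !is.na(det[[m]][, 1])
      ci <- ci + 1L
      if (!any(ok)) {
        warning("no successful replicates for theta=", th, " maf=", q,
                " method=", m, call. = FALSE)
        pb <- NA_real_; p1 <- NA_real_
      } else {
        pb <- mean(det[[m]][ok, 1])
        p1 <- mean(det[[m]][ok, 2])
      }
      cells[[ci]] <- data.frame(model = modelKind, method = m,
                                theta = th, maf = q,
                                n_reps = sum(ok), power_both = pb,
                                power_at_least_one = p1,
                                stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, cells)
  rownames(res) <- NULL
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  res
}

#' Plot power curves from a sweep table
#'
#' Figure-style display of [runPowerSweep()] output: power against MAF,
#' one panel per effect size, solid lines for power to detect both loci
#' and dashed for at least one, colored by method.
#'
#' @param sweep data.frame from [runPowerSweep()].
#' @return a ggplot object (requires the `ggplot2` package).
#' @export
plotPowerCurves <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopInvalid("plotting requires the 'ggplot2' package")
  long <- rbind(
    data.frame(sweep[c("method", "theta", "maf")],
               power = sweep$power_both, target = "both"),
    data.frame(sweep[c("method", "theta", "maf")],
               power = sweep$power_at_least_one,
               target = "at least one"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = maf, y = power, colour = method,
                               linetype = target)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~theta, labeller = ggplot2::label_both) +
    ggplot2::scale_linetype_manual(values = c(both = "solid",
                                              `at least one` = "dashed")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "minor allele frequency", y = "power")
}
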
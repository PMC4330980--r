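#' Multivariate association test of one marker
#'
#' Fits the multivariate linear model regressing the k dose responses
#' jointly on the additively coded genotype (0/1/2 minor-allele count)
#' plus an intercept and optional numeric covariates, by least squares,
#' and tests the genotype coefficient vector with Wilks' lambda and its
#' Rao F approximation. For a single-degree-of-freedom hypothesis the F
#' transform is exact and the four classical multivariate statistics give
#' the same p-value; the Pillai trace is available as an alternative
#' statistic label.
#'
#' @param genotype numeric vector of minor-allele counts in {0, 1, 2}.
#' @param responses numeric matrix (n x k) of dose responses.
#' @param covariates optional numeric matrix of additional columns to
#'   adjust for (default none; the intercept is always included).
#' @param statistic `"Wilks"` (default) or `"Pillai"`.
#' @param markerId label carried into the result.
#' @return one-row data.frame with columns `marker_id`, `statistic`,
#'   `approx_f`, `df1`, `df2`, `p_value`.
#' @examples
#' set.seed(1)
#' g <- rbinom(200, 2, 0.3)
#' Y <- cbind(g + rnorm(200), rnorm(200))
#' fitSingleSnp(g, Y)
#' @export
fitSingleSnp <- function(genotype, responses, covariates = NULL,
                         statistic = c("Wilks", "Pillai"),
                         markerId = "marker") {
  statistic <- match.arg(statistic)
  Y <- as.matrix(responses)
  n <- nrow(Y); k <- ncol(Y)
  if (length(genotype) != n)
    stopInvalid("genotype length must match the number of individuals")
  nNuis <- 1L + if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= k + nNuis + 1L)
    stopInvalid("too few individuals for a ", k, "-response test")
  if (stats::var(genotype) == 0)
    stop(degenerateMarkerError(markerId, "monomorphic in sample"))

  # project out intercept (and covariates) from both g and Y
  if (is.null(covariates)) {
    gc <- genotype - mean(genotype)
    Yc <- sweep(Y, 2, colMeans(Y))
    dfe <- n - 2L
  } else {
    Z <- cbind(1, covariates)
    qz <- qr(Z)
    if (qz$rank < ncol(Z))
      stopInvalid("covariate matrix is rank deficient")
    gc <- stats::resid(stats::lm.fit(Z, genotype))
    Yc <- stats::resid(stats::lm.fit(Z, Y))
    dfe <- n - qz$rank - 1L
  }
  Sxx <- sum(gc^2)
  if (Sxx < .Machine$double.eps * n)
    stop(degenerateMarkerError(markerId,
                               "collinear with covariates"))
  hvec <- crossprod(Yc, gc) / sqrt(Sxx)      # k x 1; H = h h'
  E <- crossprod(Yc) - tcrossprod(hvec)
  Eh <- tryCatch(solve(E, hvec), error = function(e) NULL)
  if (is.null(Eh))
    stop(degenerateMarkerError(markerId, "singular residual matrix"))
  t2 <- drop(crossprod(hvec, Eh))            # Hotelling-type quantity
  lambda <- 1 / (1 + t2)                     # Wilks' lambda
  df1 <- k
  df2 <- dfe - k + 1L
  Fstat <- t2 * df2 / k
  pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  statVal <- if (statistic == "Wilks") lambda else 1 - lambda
  data.frame(marker_id = markerId, statistic = statVal,
             approx_f = Fstat, df1 = df1, df2 = df2, p_value = pval,
             stringsAsFactors = FALSE)
}

degenerateMarkerError <- function(markerId, why) {
  structure(class = c("drbnnDegenerateMarker", "error", "condition"),
            list(message = paste0("degenerate marker ", markerId, ": ",
                                  why),
                 call = NULL, markerId = markerId))
}

#' Genome-wide MANOVA scan with Bonferroni selection
#'
#' Applies [fitSingleSnp()] to every marker and selects those with
#' p-value below `alpha / p_tested`. Degenerate markers (monomorphic or
#' rank-deficient) are skipped with a warning and excluded from both
#' testing and selection.
#'
#' @param genotypes n x p matrix of minor-allele counts, or a
#'   [DoseResponseExperiment-class] (in which case `responses` may be
#'   omitted).
#' @param responses n x k response matrix; standardized internally is NOT
#'   applied — pass what you want tested.
#' @param alpha family-wise error level in (0, 1), default 0.05.
#' @param covariates optional numeric covariate matrix.
#' @param statistic `"Wilks"` (default) or `"Pillai"`.
#' @return a [ManovaScan-class].
#' @examples
#' d <- simulateDataset(
#'   simulationDesign(nIndividuals = 300, nBackgroundSnps = 18, seed = 2),
#'   geneticModelSpec("additive", theta = 0.4, causalMaf = 0.3))
#' manovaScan(d)
#' @export
manovaScan <- function(genotypes, responses = NULL, alpha = 0.05,
                       covariates = NULL,
                       statistic = c("Wilks", "Pillai")) {
  statistic <- match.arg(statistic)
  if (is(genotypes, "DoseResponseExperiment")) {
    if (is.null(responses)) responses <- genotypes@responses
    genotypes <- genotypes@genotypes
  }
  G <- as.matrix(genotypes)
  if (!ncol(G)) stopInvalid("empty genotype matrix")
  if (alpha <= 0 || alpha >= 1) stopInvalid("alpha must lie in (0, 1)")
  ids <- colnames(G) %||% sprintf("snp%04d", seq_len(ncol(G)))
  Y <- as.matrix(responses)

  # shared centering across markers (intercept-only fast path)
  rows <- vector("list", ncol(G))
  degen <- character()
  for (j in seq_len(ncol(G))) {
    res <- tryCatch(
      fitSingleSnp(G[, j], Y, covariates = covariates,
                   statistic = statistic, markerId = ids[j]),
      drbnnDegenerateMarker = function(e) e)
    if (inherits(res, "drbnnDegenerateMarker")) {
      degen <- c(degen, ids[j])
    } else {
      rows[[j]] <- res
    }
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(tab))
    stopInvalid("no testable markers (all degenerate)")
  if (length(degen))
    warning(length(degen), " degenerate marker(s) skipped: ",
            paste(utils::head(degen, 5), collapse = ", "),
            if (length(degen) > 5) ", ...", call. = FALSE)
  nTested <- nrow(tab)
  thr <- alpha / nTested
  tab$selected <- tab$p_value < thr
  rownames(tab) <- NULL
  new("ManovaScan", table = tab, alpha = alpha,
      bonferroniThreshold = thr, nTested = as.integer(nTested),
      degenerate = degen, statistic = statistic)
}
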
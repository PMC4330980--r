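#' Joint genotype frequency table under Hardy-Weinberg independence
#'
#' The 3 x 3 table `p[x+1, y+1]` = proportion of individuals with x minor
#' alleles at locus S1 and y at locus S2, for two independent loci each in
#' Hardy-Weinberg proportions.
#'
#' @param maf1,maf2 minor allele frequencies in `[0, 0.5]`.
#' @return 3 x 3 numeric matrix summing to 1, dimnames 0:2 x 0:2.
#' @examples
#' hweIndependentFreqs(0.5, 0.5)["0", "1"]  # 0.25 * 0.5
#' @export
hweIndependentFreqs <- function(maf1, maf2) {
  for (q in c(maf1, maf2))
    if (length(q) != 1L || is.na(q) || q < 0 || q > 0.5)
      stopInvalid("MAFs must lie in [0, 0.5]")
  hw <- function(q) stats::dbinom(0:2, 2, q)
  tab <- outer(hw(maf1), hw(maf2))
  dimnames(tab) <- list(S1 = 0:2, S2 = 0:2)
  tab
}

validateFreqTable <- function(freqs) {
  f <- as.matrix(freqs)
  if (!all(dim(f) == c(3L, 3L)))
    stopInvalid("frequency table must be 3 x 3")
  if (anyNA(f) || any(f < 0))
    stopInvalid("frequency table entries must be non-negative")
  if (abs(sum(f) - 1) > 1e-12)
    stopInvalid("frequency table must sum to 1 (got ", sum(f), ")")
  f
}

# E[y | S1 = s1, S2 = s2] for the three architectures, in the
# beta-parameterized (no baseline) form used by the marginal analysis
modelExpectation <- function(model, betas, s1, s2) {
  b1 <- betas[1]; b2 <- betas[2]; b3 <- betas[3]
  switch(model,
    additive = b1 * s1 + b2 * s2,
    additive_interaction = b1 * s1 + b2 * s2 + b3 * s1 * s2,
    interaction_only = b3 * s1 * s2,
    stopInvalid("unknown model kind: ", model))
}

#' Closed-form marginal effect at one S2 level
#'
#' The marginal (S1-averaged) expected trait value at a given S2 level,
#' for each two-locus architecture, from the closed forms obtained by
#' summing \eqn{E[y \mid S_1 = i, S_2 = s]} over \eqn{i \in \{0,1,2\}}:
#' with joint weights \eqn{p_{is}} as-printed (`weighting = "as_printed"`,
#' the default, e.g. for the additive model at S2 = 1,
#' \eqn{\beta_1 (p_{11} + 2 p_{21}) + \beta_2 (p_{01} + p_{11} +
#' p_{21})}), or normalized by the column mass for a textbook conditional
#' expectation (`weighting = "conditional"`). The relation between the
#' models' magnitudes is the same under either weighting, since both
#' marginal effects at a level share the column-mass factor.
#'
#' @param model `"additive"`, `"additive_interaction"` or
#'   `"interaction_only"`.
#' @param betas numeric length 3: effects \eqn{\beta_1, \beta_2} of the
#'   S1 and S2 genotypes and the interaction effect \eqn{\beta_3}
#'   (ignored where a model lacks the term).
#' @param freqs 3 x 3 joint genotype frequency table (see
#'   [hweIndependentFreqs()]).
#' @param s2Level S2 minor-allele count, 0, 1 or 2.
#' @param weighting `"as_printed"` (joint weights) or `"conditional"`.
#' @return single real marginal effect.
#' @examples
#' f <- hweIndependentFreqs(0.2, 0.2)
#' marginalEffect("additive", c(0.02, -0.02, 0.02), f, 1)  # -0.00384
#' @export
marginalEffect <- function(model = c("additive", "additive_interaction",
                                     "interaction_only"),
                           betas, freqs, s2Level,
                           weighting = c("as_printed", "conditional")) {
  model <- match.arg(model)
  weighting <- match.arg(weighting)
  f <- validateFreqTable(freqs)
  if (!s2Level %in% 0:2) stopInvalid("s2Level must be 0, 1 or 2")
  stopifnot(length(betas) == 3L, all(is.finite(betas)))
  b1 <- betas[1]; b2 <- betas[2]; b3 <- betas[3]
  s <- s2Level
  col <- f[, s + 1L]                         # p_{0s}, p_{1s}, p_{2s}
  colMass <- sum(col)
  # closed forms: sum_i E[y|S1=i, S2=s] p_{is}
  val <- switch(model,
    additive = b1 * (col[2] + 2 * col[3]) + b2 * s * colMass,
    additive_interaction = b1 * (col[2] + 2 * col[3]) +
      b2 * s * colMass + b3 * s * (col[2] + 2 * col[3]),
    interaction_only = b3 * s * (col[2] + 2 * col[3]))
  if (weighting == "conditional") {
    if (colMass <= 0)
      stopInvalid("conditional weighting on a zero-mass S2 column")
    val <- val / colMass
  }
  unname(val)
}

#' Brute-force marginal effect by enumeration
#'
#' Independent oracle for [marginalEffect()]: directly enumerates
#' \eqn{S_1 \in \{0,1,2\}} and forms the weighted sum of an arbitrary
#' conditional-mean function. Used in the test suite to verify the closed
#' forms, and available for custom architectures.
#'
#' @param modelFn function `(s1, s2) -> E[y]`.
#' @param freqs 3 x 3 joint genotype frequency table.
#' @param s2Level S2 minor-allele count, 0, 1 or 2.
#' @param weighting `"as_printed"` or `"conditional"`.
#' @return single real marginal effect.
#' @examples
#' f <- hweIndependentFreqs(0.2, 0.2)
#' bruteForceMarginal(function(s1, s2) 0.02 * s1 - 0.02 * s2, f, 1)
#' @export
bruteForceMarginal <- function(modelFn, freqs, s2Level,
                               weighting = c("as_printed",
                                             "conditional")) {
  weighting <- match.arg(weighting)
  f <- validateFreqTable(freqs)
  if (!s2Level %in% 0:2) stopInvalid("s2Level must be 0, 1 or 2")
  w <- f[, s2Level + 1L]
  vals <- vapply(0:2, function(s1) modelFn(s1, s2Level), numeric(1))
  out <- sum(vals * w)
  if (weighting == "conditional") {
    if (sum(w) <= 0)
      stopInvalid("conditional weighting on a zero-mass S2 column")
    out <- out / sum(w)
  }
  out
}

relationOf <- function(a, b, tol = 1e-12) {
  # compares |a| against |b| with an absolute-magnitude tolerance
  if (abs(abs(a) - abs(b)) <= tol * max(1, abs(a), abs(b))) "eq"
  else if (abs(a) < abs(b)) "lt" else "gt"
}

#' Marginal-effect table for the simulation effect sizes
#'
#' Reproduces the marginal-effect comparison across architectures at the
#' effect sizes used in the simulations (\eqn{\beta_1 = \beta_3 =
#' \theta/2}, \eqn{\beta_2 = -\theta/2}): for each S2 level it computes
#' \eqn{\mu_A}, \eqn{\mu_{AI}} and \eqn{\mu_I} and reports relation
#' columns comparing magnitudes, computed from the actual values:
#' `relation_ai_vs_a` is `eq` at S2 = 0 (the interaction contributes
#' nothing there) and, in the attenuation regime (Hardy-Weinberg tables
#' with MAF(S1) below 1/3), `lt` at S2 = 1, 2 — the interaction term
#' shrinks the S2 marginal effect, which is why single-locus scans lose
#' power on S2 under the interaction model. Outside that regime the
#' comparison can flip, so the column reports what the numbers say
#' (`eq`, `lt` or `gt`) rather than a fixed symbol. `relation_i_vs_a`
#' compares the purely interactive model's marginal (0 at S2 = 0, but
#' generally nonzero elsewhere — the reason marginal-effect methods
#' retain power on a purely epistatic architecture) against the additive
#' one.
#'
#' @param theta effect size (> 0).
#' @param freqs 3 x 3 joint genotype frequency table.
#' @param weighting `"as_printed"` or `"conditional"`; the relation
#'   columns are invariant to this choice (both marginals at a level
#'   share the column-mass factor).
#' @return data.frame with columns `s2_level`, `mu_additive`,
#'   `mu_additive_interaction`, `mu_interaction_only`,
#'   `relation_ai_vs_a`, `relation_i_vs_a`.
#' @examples
#' buildMarginalTables(0.04, hweIndependentFreqs(0.2, 0.2))
#' @export
buildMarginalTables <- function(theta, freqs,
                                weighting = c("as_printed",
                                              "conditional")) {
  weighting <- match.arg(weighting)
  if (theta <= 0) stopInvalid("theta must be > 0")
  f <- validateFreqTable(freqs)
  betas <- c(theta / 2, -theta / 2, theta / 2)
  rows <- lapply(0:2, function(s) {
    muA <- marginalEffect("additive", betas, f, s, weighting)
    muAI <- marginalEffect("additive_interaction", betas, f, s,
                           weighting)
    muI <- marginalEffect("interaction_only", betas, f, s, weighting)
    data.frame(s2_level = s, mu_additive = muA,
               mu_additive_interaction = muAI,
               mu_interaction_only = muI,
               relation_ai_vs_a = relationOf(muAI, muA),
               relation_i_vs_a = relationOf(muI, muA),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
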
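test_that("hill-slope mean curve evaluates correctly on all grids", {
  # unit concentration: 1 to any power is 1, so mu = 1 - 1/2
  expect_equal(hillSlopeMean(1), 0.5)
  # as-printed grid (1e-4 scale): curve is nearly flat just below 1
  expect_true(all(abs(hillSlopeMean(defaultDoseGrid()) - 1) < 1e-3))
  # unit-scale grid: sloping curve; endpoints frozen from direct
  # evaluation of 1 - 1/(1 + x^-1.5)
  mu <- hillSlopeMean(defaultDoseGrid(unitScale = TRUE))
  expect_equal(mu[1], 1 - 1 / (1 + 0.03125^(-1.5)), tolerance = 1e-12)
  expect_equal(round(mu[1], 4), 0.9945)
  expect_equal(mu[6], 1 - 1 / (1 + 1.25^(-1.5)), tolerance = 1e-12)
  expect_equal(round(mu[6], 4), 0.4171)
  expect_true(all(mu > 0 & mu < 1))
  expect_error(hillSlopeMean(c(0.1, -1)), "positive")
  # four-parameter form agrees at the unit-asymptote special case
  expect_equal(hillSlope(0.25, max = 1, min = 0, ic50 = 1,
                         hillSlope = 1.5),
               hillSlopeMean(0.25), tolerance = 1e-12)
})

test_that("genotype sampling follows Hardy-Weinberg proportions", {
  set.seed(101)
  expect_true(all(sampleGenotypeColumn(500, 0) == 0))
  n <- 1e5
  g <- sampleGenotypeColumn(n, 0.5)
  props <- tabulate(g + 1L, 3L) / n
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / n)
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 3 * se))
  g2 <- sampleGenotypeColumn(n, 0.2)
  seMean <- sqrt(2 * 0.2 * 0.8 / n)
  expect_lt(abs(mean(g2) - 0.4), 3 * seMean)
  expect_true(all(g2 %in% 0:2))
  expect_error(sampleGenotypeColumn(10, 0.6), "maf")
  expect_error(sampleGenotypeColumn(10, -0.1), "maf")
})

test_that("genetic multiplier matches the three model equations", {
  add <- geneticModelSpec("additive", theta = 0.02, causalMaf = 0.3)
  expect_equal(geneticMultiplier(add, 2, 0), 1.02)
  expect_equal(geneticMultiplier(add, 0, 2), 0.98)
  ai <- geneticModelSpec("additive_interaction", theta = 0.04,
                         causalMaf = 0.3)
  expect_equal(geneticMultiplier(ai, 1, 1), 1.02)
  io <- geneticModelSpec("interaction_only", theta = 0.7,
                         causalMaf = 0.3)
  expect_equal(geneticMultiplier(io, 0, 2), 1)
  expect_equal(geneticMultiplier(io, 2, 2), 1 + 0.35 * 4)
  # invariants across models: neutral at the double-major genotype and
  # at zero effect size; interaction gap is exactly (theta/2) s1 s2
  for (kind in c("additive", "additive_interaction",
                 "interaction_only")) {
    sp <- geneticModelSpec(kind, theta = 0.05, causalMaf = 0.2)
    sp0 <- geneticModelSpec(kind, theta = 0, causalMaf = 0.2)
    for (s1 in 0:2) for (s2 in 0:2) {
      if (s1 == 0 && s2 == 0)
        expect_identical(geneticMultiplier(sp, 0, 0), 1)
      expect_identical(geneticMultiplier(sp0, s1, s2), 1)
    }
  }
  addV <- geneticModelSpec("additive", theta = 0.05, causalMaf = 0.2)
  aiV <- geneticModelSpec("additive_interaction", theta = 0.05,
                          causalMaf = 0.2)
  for (s1 in 0:2) for (s2 in 0:2)
    expect_equal(geneticMultiplier(aiV, s1, s2) -
                   geneticMultiplier(addV, s1, s2),
                 0.025 * s1 * s2, tolerance = 1e-15)
  expect_error(geneticMultiplier(addV, 3, 0), "minor-allele")
})

test_that("simulated datasets are reproducible with exact group means", {
  des <- simulationDesign(nIndividuals = 400, nBackgroundSnps = 8,
                          seed = 42)
  spec <- geneticModelSpec("additive", theta = 0.05, causalMaf = 0.3)
  d1 <- simulateDataset(des, spec)
  d2 <- simulateDataset(des, spec)
  expect_identical(genotypes(d1), genotypes(d2))
  expect_identical(responses(d1), responses(d2))
  expect_true(all(genotypes(d1) %in% 0:2))
  expect_identical(markerIds(d1)[1:2], c("causal1", "causal2"))

  # noise-free: group means equal mu_k * multiplier exactly
  spec0 <- geneticModelSpec("additive_interaction", theta = 0.06,
                            causalMaf = 0.4, noiseScale = 0)
  d0 <- simulateDataset(des, spec0)
  G <- genotypes(d0); Y <- responses(d0); mu <- meanCurve(d0)
  for (s1 in 0:1) for (s2 in 0:1) {
    rows <- which(G[, 1] == s1 & G[, 2] == s2)
    if (!length(rows)) next
    expect_equal(colMeans(Y[rows, , drop = FALSE]),
                 unname(mu * geneticMultiplier(spec0, s1, s2)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  # noisy case: (2,0) group mean near 1.05 * mu_k within 3 SE
  big <- simulateDataset(
    simulationDesign(nIndividuals = 2000, nBackgroundSnps = 3,
                     seed = 7), spec)
  Gb <- genotypes(big); Yb <- responses(big)
  rows <- which(Gb[, 1] == 2 & Gb[, 2] == 0)
  muB <- meanCurve(big)
  se <- 0.1 * muB / sqrt(length(rows))
  expect_true(all(abs(colMeans(Yb[rows, , drop = FALSE]) -
                        1.05 * muB) < 3 * se))
})

test_that("response normalization standardizes each dose column", {
  Y <- matrix(rnorm(60, 5, 3), 20, 3)
  Z <- normalizeResponses(Y)
  expect_true(all(abs(colMeans(Z)) < 1e-12))
  expect_equal(unname(apply(Z, 2, var)), rep(1, 3), tolerance = 1e-12)
  expect_equal(normalizeResponses(Z), Z, tolerance = 1e-12)
  Y[, 2] <- 4
  expect_error(normalizeResponses(Y), "constant")
})

test_that("dataset round-trips through the TSV format", {
  d <- tinyDataset(seed = 9, n = 10, bg = 3)
  stem <- file.path(tempdir(), "rt")
  writeDataset(d, stem)
  back <- readDataset(stem)
  expect_identical(genotypes(back), genotypes(d))
  expect_equal(responses(back), responses(d), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(doses(back), doses(d), tolerance = 1e-12)
  tr <- truthSpec(back)
  expect_identical(tr@modelKind, "additive")
  expect_equal(tr@theta, 0.3)
  expect_identical(tr@causalIndices, truthSpec(d)@causalIndices)

  # domain violations are parse errors naming a line
  gfile <- paste0(stem, ".geno.tsv")
  lines <- readLines(gfile)
  lines[3] <- sub("^[0-9]", "3", lines[3])
  writeLines(lines, gfile)
  expect_error(readDataset(stem), "line")

  writeDataset(d, stem)
  rfile <- paste0(stem, ".resp.tsv")
  lines <- readLines(rfile)
  lines[4] <- sub("^[-0-9.e]+", "abc", lines[4])
  writeLines(lines, rfile)
  expect_error(readDataset(stem), "non-numeric")
})

test_that("VCF import converts GT fields to minor-allele counts", {
  vcf <- file.path(tempdir(), "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
          "INFO", "FORMAT", "A", "B", "C", "D", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "0/1", sep = "\t"),
    # ALT is the major allele here: counts must flip to the REF allele
    paste("1", "200", ".", "C", "T", ".", "PASS", ".", "GT",
          "1/1", "1/1", "0/1", "1/1", sep = "\t")), vcf)
  G <- readGenotypesVCF(vcf)
  expect_identical(dim(G), c(4L, 2L))
  expect_identical(unname(G[, "rs1"]), c(0L, 1L, 2L, 1L))
  expect_identical(unname(G[, "1_200"]), c(0L, 0L, 1L, 0L))

  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
          "INFO", "FORMAT", "A", "B", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "./.", sep = "\t")), vcf)
  expect_error(readGenotypesVCF(vcf), "missing")
})
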
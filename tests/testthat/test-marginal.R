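test_that("Hardy-Weinberg independent tables are correct products", {
  f <- hweIndependentFreqs(0.5, 0.5)
  expect_equal(f["0", "1"], 0.25 * 0.5)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  # boundary MAF puts all mass on the zero-copy margin
  f0 <- hweIndependentFreqs(0, 0.3)
  expect_equal(unname(rowSums(f0)), c(1, 0, 0), tolerance = 1e-15)
  for (rep in 1:20) {
    q <- runif(2, 0, 0.5)
    expect_equal(sum(hweIndependentFreqs(q[1], q[2])), 1,
                 tolerance = 1e-12)
  }
  expect_error(hweIndependentFreqs(0.6, 0.2), "MAF")
})

test_that("closed forms equal the enumeration oracle everywhere", {
  set.seed(81)
  for (rep in 1:100) {
    f <- randomFreqTable()
    b <- rnorm(3)
    for (m in c("additive", "additive_interaction",
                "interaction_only")) {
      fn <- function(s1, s2) drbnn:::modelExpectation(m, b, s1, s2)
      for (s in 0:2) for (w in c("as_printed", "conditional")) {
        expect_equal(marginalEffect(m, b, f, s, w),
                     bruteForceMarginal(fn, f, s, w),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("worked marginal effects at theta 0.04, MAF 0.2 are exact", {
  f <- hweIndependentFreqs(0.2, 0.2)
  b <- c(0.02, -0.02, 0.02)
  # additive: -(theta/2)(p01 - p21) with p01 = 0.2048, p21 = 0.0128
  expect_equal(marginalEffect("additive", b, f, 1), -0.00384,
               tolerance = 1e-12)
  # with the interaction term the S2 marginal is attenuated; value
  # frozen from the enumeration oracle
  muAI <- bruteForceMarginal(
    function(s1, s2) 0.02 * s1 - 0.02 * s2 + 0.02 * s1 * s2, f, 1)
  expect_equal(muAI, -0.00128, tolerance = 1e-12)
  expect_equal(marginalEffect("additive_interaction", b, f, 1), muAI,
               tolerance = 1e-14)
  expect_lt(abs(muAI), abs(-0.00384))
  # purely interactive model has no marginal at S2 = 0, for any freqs
  set.seed(82)
  for (rep in 1:10)
    expect_equal(marginalEffect("interaction_only", rnorm(3),
                                randomFreqTable(), 0), 0,
                 tolerance = 1e-15)
})

test_that("oracle degenerate and linear behaviour", {
  f <- hweIndependentFreqs(0.3, 0.25)
  expect_equal(bruteForceMarginal(function(s1, s2) 0, f, 1), 0)
  # constant conditional mean integrates to c * column mass (or c)
  cm <- sum(f[, 2])
  expect_equal(bruteForceMarginal(function(s1, s2) 3, f, 1), 3 * cm,
               tolerance = 1e-14)
  expect_equal(bruteForceMarginal(function(s1, s2) 3, f, 1,
                                  "conditional"), 3, tolerance = 1e-14)
  # linearity in the effect vector
  set.seed(83)
  b1 <- rnorm(3); b2 <- rnorm(3); a <- 0.7
  for (m in c("additive", "additive_interaction", "interaction_only"))
    expect_equal(marginalEffect(m, a * b1 + b2, f, 2),
                 a * marginalEffect(m, b1, f, 2) +
                   marginalEffect(m, b2, f, 2), tolerance = 1e-12)
  # the two weightings differ exactly by the column mass
  for (s in 0:2)
    expect_equal(marginalEffect("additive", b1, f, s),
                 marginalEffect("additive", b1, f, s, "conditional") *
                   sum(f[, s + 1]), tolerance = 1e-13)
  # zero-mass column: conditional weighting is degenerate
  f0 <- hweIndependentFreqs(0.3, 0)
  expect_error(marginalEffect("additive", b1, f0, 2, "conditional"),
               "zero-mass")
})

test_that("marginal tables show attenuation in the low-MAF regime", {
  tab <- buildMarginalTables(0.04, hweIndependentFreqs(0.2, 0.2))
  expect_identical(tab$s2_level, 0:2)
  # S2 = 0: interaction contributes nothing, both models coincide at
  # (theta/2)(p10 + 2 p20)
  f <- hweIndependentFreqs(0.2, 0.2)
  expect_equal(tab$mu_additive[1],
               0.02 * (f["1", "0"] + 2 * f["2", "0"]),
               tolerance = 1e-14)
  expect_identical(tab$relation_ai_vs_a[1], "eq")
  expect_equal(tab$mu_interaction_only[1], 0)
  expect_identical(tab$relation_i_vs_a[1], "lt")
  # attenuation holds under HWE whenever MAF(S1) < 1/3; the purely
  # interactive model has a nonzero marginal at S2 > 0 wherever the
  # relevant cells have mass
  set.seed(84)
  for (rep in 1:200) {
    q1 <- runif(1, 0.01, 1 / 3 - 0.01); q2 <- runif(1, 0.01, 0.5)
    tt <- buildMarginalTables(runif(1, 0.01, 1),
                              hweIndependentFreqs(q1, q2))
    expect_identical(tt$relation_ai_vs_a, c("eq", "lt", "lt"))
    expect_true(all(abs(tt$mu_interaction_only[2:3]) > 0))
  }
  # ... and can fail beyond it: at MAF(S1) = 0.45 the S2 = 1 relation
  # flips, matching the power loss observed at high MAF
  tHigh <- buildMarginalTables(0.04, hweIndependentFreqs(0.45, 0.2))
  expect_identical(tHigh$relation_ai_vs_a[2], "gt")
  # relation columns are invariant to the weighting convention
  t1 <- buildMarginalTables(0.04, f, "as_printed")
  t2 <- buildMarginalTables(0.04, f, "conditional")
  expect_identical(t1$relation_ai_vs_a, t2$relation_ai_vs_a)
  expect_identical(t1$relation_i_vs_a, t2$relation_i_vs_a)
})

test_that("frequency-table validation rejects malformed input", {
  expect_error(marginalEffect("additive", c(1, 1, 1),
                              matrix(1, 2, 2), 1), "3 x 3")
  bad <- matrix(1 / 9, 3, 3); bad[1, 1] <- 0.5
  expect_error(marginalEffect("additive", c(1, 1, 1), bad, 1), "sum")
  expect_error(marginalEffect("additive", c(1, 1, 1),
                              randomFreqTable(), 3), "s2Level")
})
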
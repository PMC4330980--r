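test_that("hidden activations match a scalar-loop oracle", {
  set.seed(21)
  st <- networkState(6, 4, 3)
  # zero parameters: logistic(0) = 1/2 everywhere
  z <- st
  z@hiddenWeights[] <- 0; z@hiddenBiases[] <- 0
  expect_equal(hiddenActivation(z, c(0, 1, 2, 0, 1, 2)), rep(0.5, 4))
  # large bias saturates to 1
  z@hiddenBiases[] <- 50
  expect_equal(hiddenActivation(z, rep(0, 6)), rep(1, 4),
               tolerance = 1e-15)
  for (rep in 1:5) {
    x <- sample(0:2, 6, replace = TRUE)
    st2 <- networkState(6, 4, 3, initSd = 0.8)
    expect_equal(forward(st2, x), slowForward(st2, x),
                 tolerance = 1e-12)
    expect_true(all(hiddenActivation(st2, x) > 0 &
                      hiddenActivation(st2, x) < 1))
  }
  expect_error(hiddenActivation(st, c(0, 1)), "match")
})

test_that("forward map handles boundary parameterizations", {
  st <- networkState(3, 2, 4)
  st@outputWeights[] <- 0
  st@outputBiases <- c(1, 2, 3, 4)
  expect_equal(forward(st, c(0, 1, 2)), c(1, 2, 3, 4))
  # one hidden unit pinned at 1/2, output weight 2, bias 0 -> output 1
  st1 <- networkState(3, 1, 1)
  st1@hiddenWeights[] <- 0; st1@hiddenBiases[] <- 0
  st1@outputWeights[] <- 2; st1@outputBiases[] <- 0
  expect_equal(forward(st1, c(2, 1, 0)), 1)
})

test_that("forward is invariant under hidden-unit permutation", {
  set.seed(22)
  st <- networkState(5, 4, 3, initSd = 0.7)
  perm <- c(3, 1, 4, 2)
  stP <- st
  stP@hiddenWeights <- st@hiddenWeights[, perm]
  stP@hiddenBiases <- st@hiddenBiases[perm]
  stP@outputWeights <- st@outputWeights[perm, ]
  x <- c(0, 2, 1, 0, 2)
  expect_equal(forward(st, x), forward(stP, x), tolerance = 1e-14)
})

test_that("log joint density matches a slow accumulation oracle", {
  set.seed(23)
  n <- 15; p <- 4; H <- 3; k <- 2
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  Y <- matrix(rnorm(n * k), n, k)
  for (rep in 1:3) {
    st <- networkState(p, H, k, initSd = 0.6)
    st@ardScales <- rexp(p) + 0.1
    st@outputScale <- rexp(1) + 0.1
    expect_equal(logJoint(st, X, Y), slowLogJoint(st, X, Y),
                 tolerance = 1e-10)
  }
  # a perfect fit contributes zero likelihood; residual scaling checks
  st <- networkState(p, H, k)
  Yfit <- forward(st, X)
  expect_equal(logJoint(st, X, Yfit) -
                 drbnn:::logPriorState(st, ardHyper()), 0,
               tolerance = 1e-10)
  # doubling one unit residual changes the likelihood term by -1.5
  Y1 <- Yfit; Y1[1, 1] <- Y1[1, 1] + 1
  Y2 <- Yfit; Y2[1, 1] <- Y2[1, 1] + 2
  expect_equal(logJoint(st, X, Y2) - logJoint(st, X, Y1), -1.5,
               tolerance = 1e-10)
  bad <- st; bad@ardScales[1] <- -1
  expect_error(validObject(bad), "positive")
})

test_that("analytic gradient agrees with central finite differences", {
  set.seed(24)
  n <- 20; p <- 5; H <- 3; k <- 2
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  Y <- matrix(rnorm(n * k), n, k)
  tgt <- drbnn:::bnnTarget(X, Y, H)
  for (rep in 1:3) {
    th <- rnorm(tgt$index$total, 0, 0.5)
    ana <- tgt$gradLik(th) + tgt$gradPrior(th)
    num <- fdGrad(function(t) tgt$logLik(t) + tgt$logPrior(t), th)
    expect_lt(max(abs(ana - num) / pmax(1, abs(num))), 1e-5)
  }
  # gradLogJoint exposes the same gradient in NetworkState shape
  st <- networkState(p, H, k, initSd = 0.5)
  g <- gradLogJoint(st, X, Y)
  flat <- c(as.vector(g$hiddenWeights), g$hiddenBiases,
            as.vector(g$outputWeights), g$outputBiases,
            g$logArdScales, g$logOutputScale)
  num <- fdGrad(function(t) {
    tgt$logLik(t) + tgt$logPrior(t)
  }, drbnn:::packState(st))
  expect_lt(max(abs(flat - num) / pmax(1, abs(num))), 1e-5)
})

test_that("gradient vanishes at an optimizer-found mode", {
  set.seed(25)
  n <- 25; p <- 3; H <- 2; k <- 2
  X <- matrix(rbinom(n * p, 2, 0.4), n, p)
  Y <- matrix(rnorm(n * k, 0, 0.5), n, k)
  tgt <- drbnn:::bnnTarget(X, Y, H)
  f <- function(t) -(tgt$logLik(t) + tgt$logPrior(t))
  gr <- function(t) -(tgt$gradLik(t) + tgt$gradPrior(t))
  opt <- optim(rnorm(tgt$index$total, 0, 0.1), f, gr,
               method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  expect_lt(sqrt(sum(gr(opt$par)^2)), 1e-4)
})

test_that("small hidden weights collapse the network to a linear map", {
  set.seed(26)
  p <- 6; H <- 5; k <- 3
  affineError <- function(wScale) {
    st <- networkState(p, H, k, initSd = 1)
    st@hiddenWeights <- matrix(rnorm(p * H), p, H) * wScale
    # affine reference: intercept f(0) plus per-coordinate unit steps
    f0 <- forward(st, rep(0, p))
    J <- vapply(seq_len(p), function(j) {
      e <- rep(0, p); e[j] <- 1
      forward(st, e) - f0
    }, numeric(k))
    xs <- matrix(sample(0:2, 40 * p, replace = TRUE), 40, p)
    errs <- vapply(seq_len(nrow(xs)), function(i) {
      max(abs(forward(st, xs[i, ]) - (f0 + drop(J %*% xs[i, ]))))
    }, numeric(1))
    max(errs)
  }
  # residual curvature is O(||w||^2): tiny at scale 1e-3, and growing
  # roughly quadratically with the weight scale
  errSmall <- affineError(1e-3)
  errBig <- affineError(1e-2)
  expect_lt(errSmall, 1e-4)
  expect_gt(errBig / errSmall, 20)
  expect_lt(errBig / errSmall, 500)
})
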
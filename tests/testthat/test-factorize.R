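test_that("the same seed reproduces a factorization bit-for-bit", {
  A <- simulateLowRank(30, 12, k = 2, noiseSd = 0.2, seed = 1)$A
  f1 <- nmfFactorize(A, 2, seed = 42, maxEpochs = 300)
  f2 <- nmfFactorize(A, 2, seed = 42, maxEpochs = 300)
  expect_identical(basisMatrix(f1), basisMatrix(f2))
  expect_identical(coefMatrix(f1), coefMatrix(f2))
  expect_identical(lossTrace(f1), lossTrace(f2))
})

test_that("factorize leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(nmfFactorize(simulateLowRank(10, 8, 2, seed = 2)$A, 2,
                         seed = 1, maxEpochs = 100))
  expect_identical(runif(1), before)
})

test_that("an exact low-rank target is recovered to numerical precision", {
  set.seed(3)
  W <- matrix(runif(300), 100, 3)
  H <- matrix(runif(60), 3, 20)
  f <- nmfFactorize(W %*% H, 3, seed = 11, maxEpochs = 10000,
                    relTol = 1e-300)
  expect_lt(tail(lossTrace(f), 1), 1e-6)
})

test_that("epoch accounting: one outer alternation = nInner epochs", {
  A <- simulateLowRank(20, 10, 2, seed = 5)$A
  f <- nmfFactorize(A, 2, nInner = 7, maxEpochs = 35, relTol = 1e-300)
  expect_equal(epochsRun(f), 35L)
  expect_equal(epochTrace(f), seq(7, 35, by = 7))
  expect_equal(length(lossTrace(f)), length(objectiveTrace(f)))
})

test_that("a fully masked W is returned untouched and H solves the NNLS", {
  set.seed(6)
  Wtrue <- matrix(runif(40, 0.1, 1), 10, 4)
  Htrue <- matrix(runif(20, 0.1, 2), 4, 5)
  A <- Wtrue %*% Htrue
  f <- nmfFactorize(A, 4, maskW = matrix(TRUE, 10, 4), initW = Wtrue,
                    seed = 7, maxEpochs = 3000, relTol = 1e-300)
  expect_identical(basisMatrix(f), Wtrue)
  V <- crossprod(Wtrue)
  U <- -crossprod(Wtrue, A)
  for (j in 1:5) {
    expect_equal(coefMatrix(f)[, j], nnqp_oracle(V, U[, j]),
                 tolerance = 1e-6)
  }
})

test_that("mask-fixed entries keep their stamped values exactly", {
  A <- simulateLowRank(15, 8, 2, noiseSd = 0.1, seed = 8)$A
  maskW <- matrix(FALSE, 15, 3)
  maskW[, 1] <- TRUE
  profile <- matrix(runif(45), 15, 3)
  f <- nmfFactorize(A, 3, maskW = maskW, initW = profile, seed = 9,
                    maxEpochs = 200)
  expect_identical(basisMatrix(f)[, 1], profile[, 1])
  # without an init matrix, fixed entries are stamped to zero
  f0 <- suppressWarnings(
    nmfFactorize(A, 3, maskH = rbind(TRUE, FALSE, FALSE), seed = 9,
                 maxEpochs = 200))
  expect_identical(coefMatrix(f0)[1, ], rep(0, 8))
})

test_that("multiplicative runs warn when an initialization contains zeros", {
  A <- simulateLowRank(10, 6, 2, seed = 10)$A
  expect_warning(
    nmfFactorize(A, 2, method = "lee", maskW = cbind(TRUE, FALSE),
                 seed = 3, maxEpochs = 50),
    "zero")
})

test_that("a 30%-missing exact low-rank matrix is recovered", {
  sim <- simulateLowRank(100, 40, k = 3, noiseSd = 0, missingFrac = 0.3,
                         seed = 13)
  f <- nmfFactorize(sim$A, 3, seed = 3, maxEpochs = 5000, relTol = 1e-300)
  expect_lt(tail(lossTrace(f), 1), 1e-4)
})

test_that("unobserved values of A never influence the result", {
  sim <- simulateLowRank(40, 20, k = 2, noiseSd = 0.5, missingFrac = 0.2,
                         seed = 17)
  A1 <- as.matrix(sim$A)
  A2 <- sim$A@values
  A2[sim$deleted] <- 1e6 * runif(sum(sim$deleted))  # scramble hidden cells
  tm2 <- new("TargetMatrix", values = A2, observed = !sim$deleted)
  f1 <- nmfFactorize(A1, 2, seed = 4, maxEpochs = 400)
  f2 <- nmfFactorize(tm2, 2, seed = 4, maxEpochs = 400)
  expect_identical(basisMatrix(f1), basisMatrix(f2))
  expect_identical(coefMatrix(f1), coefMatrix(f2))
})

test_that("over-parameterized ranks and bad weights are flagged", {
  A <- simulateLowRank(6, 4, 2, seed = 20)$A
  expect_warning(nmfFactorize(A, 5, seed = 1, maxEpochs = 50),
                 "overparameterized")
  expect_error(nmfFactorize(A, 2, beta = c(0.1, 0.5, 0)), "ridge > angle")
  expect_error(nmfFactorize(A, 2, relTol = 0), "relTol")
})

test_that("normalizeBasis preserves the reconstruction", {
  f <- nmfFactorize(simulateLowRank(12, 9, 2, seed = 21)$A, 2, seed = 2,
                    maxEpochs = 100)
  g <- normalizeBasis(f)
  expect_equal(colSums(basisMatrix(g)), rep(1, 2), tolerance = 1e-12)
  expect_equal(reconstruct(g), reconstruct(f), tolerance = 1e-12)
})
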
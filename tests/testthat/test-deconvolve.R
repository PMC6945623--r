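test_that("pure-normal samples get near-zero purity", {
  sim <- simulateMixture(n = 80, m = 10, L = 2, purityRange = c(0, 0),
                         seed = 61)
  dec <- deconvolve(sim$A, sim$W0, kUnknown = 1, seed = 62,
                    maxEpochs = 5000, relTol = 1e-10)
  expect_true(all(purity(dec) < 0.05))
})

test_that("samples with no known-profile content get near-one purity", {
  set.seed(63)
  n <- 80
  # cancer support disjoint from the known profiles' support
  Wc <- matrix(0, n, 1)
  Wc[1:40, 1] <- runif(40, 0.2, 1)
  W0 <- matrix(0, n, 2)
  W0[41:80, ] <- runif(80, 0.2, 1)
  A <- Wc %*% matrix(runif(10, 1, 5), 1, 10)
  dec <- deconvolve(A, W0, kUnknown = 1, seed = 64, maxEpochs = 5000,
                    relTol = 1e-10)
  expect_true(all(purity(dec) > 0.95))
})

test_that("mixture fractions are recovered within 0.05 and rank-correlate", {
  for (s in c(71, 75, 78)) {
    sim <- simulateMixture(n = 200, m = 30, L = 2, kUnknown = 1,
                           purityRange = c(0.1, 0.9), seed = s)
    dec <- deconvolve(sim$A, sim$W0, kUnknown = 1, seed = s + 100,
                      maxEpochs = 20000, relTol = 1e-12)
    expect_lt(max(abs(purity(dec) - sim$purity)), 0.05)
    expect_gt(cor(purity(dec), sim$purity, method = "spearman"), 0.9)
    expect_true(all(purity(dec) >= 0 & purity(dec) <= 1))
  }
})

test_that("the known-profile block of the stacked basis is bit-identical", {
  sim <- simulateMixture(n = 60, m = 8, L = 3, seed = 81)
  dec <- deconvolve(sim$A, sim$W0, kUnknown = 2, seed = 82,
                    maxEpochs = 500)
  stacked <- basisMatrix(dec@fit)
  expect_identical(stacked[, 3:5], sim$W0)
  expect_equal(dim(dec@W), c(60L, 2L))
  expect_equal(dim(dec@H1), c(3L, 8L))
})

test_that("markerMask encodes pathway and marker designs", {
  # one pathway over rows 1:2 of 4, single column: rows 3,4 fixed to zero
  m1 <- markerMask(list(1:2), n = 4, K = 1)
  expect_identical(m1, matrix(c(FALSE, FALSE, TRUE, TRUE), 4, 1))
  # extra columns beyond the sets are fully free
  m2 <- markerMask(list(1:2, 3:4), n = 5, K = 4)
  expect_true(all(!m2[, 3:4]))
  expect_true(all(m2[3:5, 1]))
  # marker mode: column l forbidden on the *other* sets' rows
  m3 <- markerMask(list(1:2, 3:4), n = 5, K = 2, exclusive = TRUE)
  expect_identical(which(m3[, 1]), 3:4L)
  expect_identical(which(m3[, 2]), 1:2L)
  expect_false(any(m3[5, ]))  # row in no set stays free everywhere
  expect_error(markerMask(list(integer(0)), n = 4), "empty")
  expect_error(markerMask(list(1:9), n = 4), "outside")
})

test_that("a pathway mask confines basis support to its gene set", {
  sim <- simulateLowRank(30, 12, 2, noiseSd = 0.2, seed = 83)
  mask <- markerMask(list(1:10), n = 30, K = 3)
  f <- suppressWarnings(nmfFactorize(sim$A, 3, maskW = mask, seed = 84,
                                     maxEpochs = 500))
  expect_true(all(basisMatrix(f)[11:30, 1] == 0))
  expect_true(any(basisMatrix(f)[, 2] > 0))
})

test_that("sharedProfileMask zeroes cross-dataset specific blocks", {
  mask <- sharedProfileMask(c(3, 2), kShared = 1, kSpecific = 1)
  expect_equal(dim(mask), c(3L, 5L))
  expect_true(all(!mask[1, ]))              # shared row free everywhere
  expect_identical(mask[2, ], c(rep(FALSE, 3), rep(TRUE, 2)))
  expect_identical(mask[3, ], c(rep(TRUE, 3), rep(FALSE, 2)))
  # degenerate single-dataset case: nothing is masked
  expect_false(any(sharedProfileMask(4, kShared = 1, kSpecific = 0)))
})

test_that("a planted shared profile is recovered across two datasets", {
  set.seed(11)
  n <- 120
  Wsh <- matrix(runif(n), n, 1)
  W1 <- matrix(runif(n), n, 1)
  W2 <- matrix(runif(n), n, 1)
  m1 <- 20; m2 <- 25
  A1 <- cbind(Wsh, W1) %*% matrix(runif(2 * m1, 0, 5), 2, m1)
  A2 <- cbind(Wsh, W2) %*% matrix(runif(2 * m2, 0, 5), 2, m2)
  mask <- sharedProfileMask(c(m1, m2), kShared = 1, kSpecific = 1)
  fit <- suppressWarnings(
    nmfFactorize(cbind(A1, A2), k = 3, maskH = mask, seed = 5,
                 maxEpochs = 10000, relTol = 1e-10))
  expect_gt(cor(basisMatrix(fit)[, 1], Wsh), 0.9)
})
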
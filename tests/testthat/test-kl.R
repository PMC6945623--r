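test_that("KL coordinate terms match direct evaluation", {
  # single row, w = 2, h = 1, a = 4: b = 2 - 4*2/2 = -2, a = 4*(2/2)^2 = 4
  terms <- klCoordinateTerms(matrix(4, 1, 1), matrix(2, 1, 1),
                             matrix(1, 1, 1), 1, 1)
  expect_equal(terms$b, -2)
  expect_equal(terms$a, 4)

  # an observed zero contributes w to the gradient, nothing to curvature
  terms0 <- klCoordinateTerms(matrix(0, 1, 1), matrix(2, 1, 1),
                              matrix(1, 1, 1), 1, 1)
  expect_equal(terms0$b, 2)
  expect_equal(terms0$a, 0)

  # at a perfect strictly-positive fit the gradient vanishes
  set.seed(5)
  W <- matrix(runif(8, 0.1, 1), 4, 2)
  H <- matrix(runif(6, 0.1, 1), 2, 3)
  A <- W %*% H
  for (kk in 1:2) for (j in 1:3) {
    t1 <- klCoordinateTerms(A, W, H, kk, j)
    expect_equal(t1$b, 0, tolerance = 1e-10)
    expect_equal(t1$a, sum(W[, kk]^2 / A[, j]), tolerance = 1e-8)
  }

  # missing rows are excluded from the sums
  Am <- matrix(c(4, NA, 1), 3, 1)
  Wm <- matrix(c(2, 5, 1), 3, 1)
  Hm <- matrix(1, 1, 1)
  tm <- klCoordinateTerms(Am, Wm, Hm, 1, 1)
  expect_equal(tm$b, (2 - 4 * 2 / 2) + (1 - 1 * 1 / 1))
  expect_equal(tm$a, 4 * 1 + 1 * 1)
})

test_that("the clamped Newton coordinate update behaves as derived", {
  # a stationary point is a fixed point
  expect_equal(klCoordinateUpdate(1.3, a = 2, b = 0), 1.3)
  # plug-in: (4*1 + 2)/4 = 1.5
  expect_equal(klCoordinateUpdate(1, a = 4, b = -2), 1.5)
  # negative Newton step clamps at zero
  expect_equal(klCoordinateUpdate(0, a = 1, b = 5), 0)
  # penalties shift and shrink the step
  expect_equal(klCoordinateUpdate(1, a = 4, b = -2, cross = 2,
                                  beta = c(1, 0.5, 0.25)),
               (4 - (-2) - 0.5 * 2 - 0.25) / 5)
})

test_that("KL coordinate sweeps do not increase the true objective", {
  set.seed(21)
  for (s in 1:5) {
    W <- matrix(runif(24, 0.05, 1), 8, 3)
    H <- matrix(runif(12, 0.05, 1), 3, 4)
    A <- matrix(runif(32, 0.1, 3), 8, 4)
    prev <- kl_objective(A, W, H)
    for (sweep in 1:15) {
      H <- nmfkit:::c_update_factor(A, W, H, c(0, 0, 0),
                                    matrix(integer(0), 0, 0),
                                    matrix(integer(0), 0, 0),
                                    1L, 1e-16, 3L)
      cur <- kl_objective(A, W, H)
      expect_lte(cur, prev + 1e-10)
      prev <- cur
    }
  }
})

test_that("KL fixed points satisfy the KKT conditions", {
  set.seed(31)
  W <- matrix(runif(30, 0.05, 1), 10, 3)
  H <- matrix(runif(15, 0.05, 1), 3, 5)
  A <- matrix(runif(50, 0.2, 3), 10, 5)
  for (sweep in 1:400) {
    H <- nmfkit:::c_update_factor(A, W, H, c(0, 0, 0),
                                  matrix(integer(0), 0, 0),
                                  matrix(integer(0), 0, 0),
                                  1L, 1e-16, 3L)
  }
  for (kk in 1:3) for (j in 1:5) {
    b <- klCoordinateTerms(A, W, H, kk, j)$b
    if (H[kk, j] > 1e-10) {
      expect_equal(b, 0, tolerance = 1e-5)
    } else {
      expect_gte(b, -1e-6)
    }
  }
})
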
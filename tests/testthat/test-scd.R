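test_that("buildSystem forms the penalized Gram system", {
  A <- matrix(c(3, 5), 2, 1)
  W <- diag(2)
  sys <- buildSystem(A, W, beta = c(0, 0, 0))
  expect_false(sys$perColumn)
  expect_equal(sys$V, diag(2))
  expect_equal(sys$U, matrix(c(-3, -5), 2, 1))

  sys3 <- buildSystem(A, W, beta = c(0, 0, 1))
  expect_equal(sys3$U, matrix(c(-2, -4), 2, 1))

  # missing row restricts the cross-products to observed rows
  Am <- matrix(c(4, NA), 2, 1)
  Wm <- matrix(c(1, 2), 2, 1)
  b <- c(0.5, 0, 0.25)
  sysm <- buildSystem(Am, Wm, beta = b)
  expect_true(sysm$perColumn)
  expect_equal(sysm$V[[1]], matrix(1 + 0.5, 1, 1))
  expect_equal(sysm$U, matrix(-4 + 0.25, 1, 1))
})

test_that("buildSystem enforces the diagonal-positivity weight constraint", {
  A <- matrix(1, 2, 2)
  W <- matrix(runif(4), 2, 2)
  expect_error(buildSystem(A, W, beta = c(0.1, 0.5, 0)), "ridge > angle")
  expect_silent(buildSystem(A, W, beta = c(0.5, 0.1, 0)))
  expect_silent(buildSystem(A, W, beta = c(0, 0, 0.3)))
})

test_that("scdSolve handles interior and clamped optima", {
  res <- scdSolve(diag(2), matrix(c(-3, -5), 2, 1))
  expect_equal(res$H, matrix(c(3, 5), 2, 1))
  # gradient points out of the feasible region: clamp at zero
  expect_equal(scdSolve(diag(1), matrix(2, 1, 1))$H, matrix(0, 1, 1))
})

test_that("scdSolve rejects a non-positive diagonal and asymmetry", {
  expect_error(scdSolve(matrix(c(0, 0, 0, 1), 2, 2),
                        matrix(0, 2, 1)), "diagonal")
  expect_error(scdSolve(matrix(c(1, 2, 0, 1), 2, 2),
                        matrix(0, 2, 1)), "symmetric")
})

test_that("converged SCD solutions match the active-set oracle", {
  for (s in 1:30) {
    k <- sample(2:4, 1)
    inst <- rand_nnqp(k, m = 3, seed = s)
    H <- scdSolve(inst$V, inst$U, nInner = 2000)$H
    for (j in 1:3) {
      expect_equal(H[, j], nnqp_oracle(inst$V, inst$U[, j]),
                   tolerance = 1e-8)
    }
    expect_true(all(H >= 0))
  }
})

test_that("each SCD sweep does not increase the quadratic objective", {
  qobj <- function(V, U, H)
    sum(vapply(seq_len(ncol(U)), function(j)
      0.5 * sum(H[, j] * (V %*% H[, j])) + sum(U[, j] * H[, j]), 0))
  for (s in 1:5) {
    inst <- rand_nnqp(4, m = 5, seed = 100 + s)
    H <- matrix(0, 4, 5)
    prev <- qobj(inst$V, inst$U, H)
    for (sweep in 1:20) {
      H <- scdSolve(inst$V, inst$U, H0 = H, nInner = 1)$H
      cur <- qobj(inst$V, inst$U, H)
      expect_lte(cur, prev + 1e-12)
      prev <- cur
    }
  }
})

test_that("a converged solution is a fixed point of further sweeps", {
  inst <- rand_nnqp(4, m = 4, seed = 77)
  H <- scdSolve(inst$V, inst$U, nInner = 2000)$H
  H2 <- scdSolve(inst$V, inst$U, H0 = H, nInner = 1)$H
  expect_equal(H2, H, tolerance = 1e-12)
})

test_that("warm starts and per-column systems agree with the direct solve", {
  set.seed(8)
  A <- matrix(runif(30, 0, 2), 6, 5)
  A[cbind(c(1, 3, 5), c(2, 4, 1))] <- NA
  W <- matrix(runif(18), 6, 3)
  sys <- buildSystem(A, W, beta = c(0.2, 0.1, 0.05))
  H <- scdSolve(sys, nInner = 2000)$H
  # column-wise oracle on each per-column system
  for (j in 1:5) {
    expect_equal(H[, j], nnqp_oracle(sys$V[[j]], sys$U[, j]),
                 tolerance = 1e-8)
  }
})
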
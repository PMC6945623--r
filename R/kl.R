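#' Coordinate-wise terms of the sequential quadratic KL solver
#'
#' For the KL-divergence loss the coefficient subproblem is solved by a
#' Newton-like scheme: for coordinate `(kbar, j)` of `H`, the first and
#' second partial derivatives of the (unpenalized) KL loss are
#' `b = sum_l (w_{l,kbar} - a_{lj} w_{l,kbar} / (WH)_{lj})` and
#' `a = sum_l a_{lj} (w_{l,kbar} / (WH)_{lj})^2`, with the sums running only
#' over observed rows `l` of column `j` and `(WH)_{lj}` guarded below by
#' `eps`.
#'
#' @param A a [TargetMatrix-class] or numeric matrix (`NA` = unobserved).
#' @param W,H current factors.
#' @param kbar coordinate (row of `H`) index.
#' @param j column index.
#' @param eps denominator guard.
#' @return list with elements `b` (gradient) and `a` (curvature).
#' @seealso [klCoordinateUpdate()]
#' @export
klCoordinateTerms <- function(A, W, H, kbar, j, eps = 1e-16) {
  A <- .tm_relaxed(A)
  W <- as.matrix(W)
  H <- as.matrix(H)
  I <- which(A@observed[, j])
  w <- W[I, kbar]
  a <- A@values[I, j]
  wh <- (W[I, , drop = FALSE] %*% H[, j])[, 1] + eps
  r <- w / wh
  list(b = sum(w - a * r), a = sum(a * r^2))
}

#' Clamped quadratic coordinate update for the KL loss
#'
#' Minimizes the second-order Taylor model of the penalized KL loss in one
#' coordinate of `H`, subject to non-negativity:
#' `h_new = max(0, (a h_old - b - b2 * cross - b3) / (a + b1))`, where
#' `cross` is the current column sum of `H` excluding the updated
#' coordinate and `beta = (b1, b2, b3)` are the penalty weights.  The
#' denominator is replaced by `eps` when `a + b1` is not positive.
#'
#' @param hOld current coordinate value.
#' @param a,b curvature and gradient from [klCoordinateTerms()].
#' @param cross sum of the other coordinates in the same column.
#' @param beta numeric length-3 penalty weights.
#' @param eps denominator guard.
#' @return The updated non-negative coordinate value.
#' @export
klCoordinateUpdate <- function(hOld, a, b, cross = 0,
                               beta = c(0, 0, 0), eps = 1e-16) {
  den <- a + beta[1]
  if (den <= 0) den <- eps
  max(0, (a * hOld - b - beta[2] * cross - beta[3]) / den)
}
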
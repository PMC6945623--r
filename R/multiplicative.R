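#' Generalized multiplicative updates for the coefficient matrix
#'
#' One (or `nInner`) regularized multiplicative update(s) of `H` in
#' `A ~ W H`, the generalization of the classic multiplicative NMF rules to
#' the unified ridge/angle/L1 penalties:
#'
#' * `leeUpdateMse()` — square loss:
#'   `h <- h * (W'A) / ([W'W + b1 I + b2 (E - I)] H + b3 E)`.
#' * `leeUpdateKl()` — KL loss:
#'   `h <- h * sum_l(w_{l,kbar} a_{lj} / (WH)_{lj}) /
#'   (sum_l w_{l,kbar} + (b1 - b2) h + b2 colsum(h) + b3)`.
#'
#' With all `beta = 0` these are exactly the original multiplicative
#' algorithms.  With missing entries the cross-products `W'W` and `W'A` are
#' restricted per column to the observed rows, just as in the
#' coordinate-descent solver.  Denominators are guarded by `eps`.
#'
#' Multiplicative updates preserve zeros: an entry initialized at zero stays
#' zero for ever, which is why the driver warns on zero entries in a
#' multiplicative initialization.
#'
#' @param A a [TargetMatrix-class] or numeric matrix (`NA` = unobserved).
#' @param W non-negative n x k basis (held fixed).
#' @param H strictly positive k x m coefficients to update.
#' @param beta numeric length-3 penalty weights `(ridge, angle, L1)`.
#' @param nInner number of successive updates to apply.
#' @param fixed optional logical k x m pattern of entries to hold fixed.
#' @param eps denominator guard.
#' @return The updated k x m coefficient matrix.
#' @examples
#' A <- matrix(4, 1, 1); W <- matrix(1, 1, 1); H <- matrix(1, 1, 1)
#' leeUpdateMse(A, W, H)  # 1 * 4 / 1 = 4
#' @name multiplicativeUpdates
NULL

.lee_update <- function(A, W, H, beta, nInner, fixed, eps, method) {
  A <- .tm_relaxed(A)
  W <- as.matrix(W)
  H <- as.matrix(H)
  if (any(W < 0) || any(H < 0))
    stop("factor matrices must be non-negative", call. = FALSE)
  if (any(H == 0))
    warning("zero entries in H remain zero under multiplicative updates")
  kern <- .tm_for_kernel(A)
  fx <- if (is.null(fixed)) matrix(integer(0), 0, 0) else
    matrix(as.integer(fixed), nrow(H), ncol(H))
  c_update_factor(kern$values, W, H, as.numeric(beta), kern$obs, fx,
                  as.integer(nInner), eps, method)
}

#' @rdname multiplicativeUpdates
#' @export
leeUpdateMse <- function(A, W, H, beta = c(0, 0, 0), nInner = 1L,
                         fixed = NULL, eps = 1e-16) {
  .lee_update(A, W, H, beta, nInner, fixed, eps, method = 2L)
}

#' @rdname multiplicativeUpdates
#' @export
leeUpdateKl <- function(A, W, H, beta = c(0, 0, 0), nInner = 1L,
                        fixed = NULL, eps = 1e-16) {
  .lee_update(A, W, H, beta, nInner, fixed, eps, method = 4L)
}
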
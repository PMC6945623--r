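#' Penalty functionals for regularized NMF
#'
#' The three penalty terms shared by all solvers, applied to a factor matrix
#' `X`:
#'
#' * `penaltyL2(X)` — ridge penalty, half the squared Frobenius norm
#'   `1/2 ||X||_F^2`; controls magnitudes and stabilizes the solvers.
#' * `penaltyAngle(X)` — sum over column pairs `i < j` of the inner product
#'   of columns `i` and `j`; penalizing it maximizes independence (the angle)
#'   between columns.  Equals `1/2 tr(X (E - I) X')` where `E` is the
#'   all-ones matrix.
#' * `penaltyL1(X)` — LASSO-like matrix-wise sparsity penalty, the sum of
#'   absolute entries.
#'
#' The identity `penaltyL2(X) + penaltyAngle(X) = 1/2 tr(X E X')` (half the
#' sum of squared row sums) links these to the column-wise sparsity penalty
#' of sparse NMF.
#'
#' In the factorization objective the weights `alpha = (a1, a2, a3)` apply
#' these penalties to `W` and `beta = (b1, b2, b3)` to the *transpose* of
#' `H` (so the angle penalty acts on rows of `H`).
#'
#' @param X numeric matrix with finite entries.
#' @return A single non-negative number.
#' @examples
#' X <- matrix(c(1, 3, 2, 4), 2, 2)
#' penaltyL2(X)     # 15
#' penaltyAngle(X)  # columns' inner product: 1*2 + 3*4 = 14
#' penaltyL1(X)     # 10
#' @name penalties
NULL

.check_finite <- function(X, what = "X") {
  if (!all(is.finite(X)))
    stop(what, " must contain only finite values", call. = FALSE)
}

#' @rdname penalties
#' @export
penaltyL2 <- function(X) {
  X <- as.matrix(X)
  .check_finite(X)
  0.5 * sum(X * X)
}

#' @rdname penalties
#' @export
penaltyAngle <- function(X) {
  X <- as.matrix(X)
  .check_finite(X)
  if (ncol(X) < 2L) return(0)
  S <- crossprod(X)
  sum(S[upper.tri(S)])
}

#' @rdname penalties
#' @export
penaltyL1 <- function(X) {
  X <- as.matrix(X)
  .check_finite(X)
  sum(abs(X))
}

# Total penalty J_W(W) + J_H(H): alpha acts on W, beta on t(H).
.total_penalty <- function(W, H, alpha, beta) {
  p <- 0
  if (alpha[1] > 0) p <- p + alpha[1] * penaltyL2(W)
  if (alpha[2] > 0) p <- p + alpha[2] * penaltyAngle(W)
  if (alpha[3] > 0) p <- p + alpha[3] * penaltyL1(W)
  if (beta[1] > 0) p <- p + beta[1] * penaltyL2(H)
  if (beta[2] > 0) p <- p + beta[2] * penaltyAngle(t(H))
  if (beta[3] > 0) p <- p + beta[3] * penaltyL1(H)
  p
}

#' Loss between a target matrix and a reconstruction
#'
#' Evaluates the factorization loss over *observed* entries only.  Two
#' conventions are exposed:
#'
#' * `convention = "mean"` — the reporting convention: the mean per observed
#'   entry of `(a - ahat)^2` (no 1/2 factor) for `loss = "mse"`, or of the
#'   KL divergence term `a log(a / ahat) - a + ahat` for `loss = "mkl"`.
#' * `convention = "objective"` — the internal optimization objective: the
#'   *sum* over observed entries, with the 1/2 factor under MSE.
#'
#' Under KL, `0 * log(0 / ahat)` is defined as 0 and reconstruction values
#' are floored at `eps` before taking logs.
#'
#' @param A a [TargetMatrix-class] or numeric matrix (`NA` = unobserved).
#' @param W,H non-negative factor matrices (n x k and k x m).
#' @param loss `"mse"` (square error) or `"mkl"` (mean KL divergence, the
#'   deviance of a Poisson model).
#' @param convention `"mean"` or `"objective"`, see above.
#' @param eps positive guard added to KL denominators.
#' @return A single non-negative number.
#' @examples
#' A <- matrix(2, 1, 1)
#' W <- matrix(1, 1, 1); H <- matrix(1, 1, 1)
#' nmfLoss(A, W, H, "mse", convention = "objective")  # 0.5
#' nmfLoss(A, W, H, "mkl")                            # 2*log(2) - 1
#' @export
nmfLoss <- function(A, W, H, loss = c("mse", "mkl"),
                    convention = c("mean", "objective"), eps = 1e-16) {
  loss <- match.arg(loss)
  convention <- match.arg(convention)
  A <- .tm_relaxed(A)
  if (nrow(W) != nrow(A@values) || ncol(H) != ncol(A@values) ||
      ncol(W) != nrow(H))
    stop("shapes of A, W and H do not conform", call. = FALSE)
  if (any(W < 0) || any(H < 0))
    stop("factor matrices must be non-negative", call. = FALSE)
  obs <- A@observed
  a <- A@values[obs]
  yhat <- (W %*% H)[obs]
  if (loss == "mse") {
    terms <- (a - yhat)^2
    if (convention == "mean") return(mean(terms))
    return(0.5 * sum(terms))
  }
  y <- pmax(yhat, eps)
  terms <- ifelse(a > 0, a * log(a / y), 0) - a + yhat
  if (convention == "mean") mean(terms) else sum(terms)
}

# Penalized objective used for the monotonicity trace.
.objective <- function(A, W, H, loss, alpha, beta, eps = 1e-16) {
  nmfLoss(A, W, H, loss, convention = "objective", eps = eps) +
    .total_penalty(W, H, alpha, beta)
}
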
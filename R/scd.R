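#' Build the penalized quadratic system of a non-negative least-squares step
#'
#' For the subproblem "solve H given W" under square loss, the penalized
#' objective is `tr(1/2 H' V H + H' U) + const` with
#' `V = W' W + b1 I + b2 (E - I)` and `U = -W' A + b3 E`, where
#' `beta = (b1, b2, b3)` are the ridge, angle and L1 penalty weights.
#'
#' With missing entries the cross-products are restricted per column `j` to
#' its observed rows `I_j`, so `V` depends on `j` and one system is returned
#' per column.
#'
#' @param A a [TargetMatrix-class] or numeric matrix (`NA` = unobserved).
#' @param W non-negative n x k basis.
#' @param beta numeric length-3 penalty weights for the factor being solved.
#' @return A list with elements `U` (k x m), `perColumn` (logical), and
#'   either `V` (k x k, fully observed) or `V` as a list of k x k matrices,
#'   one per column.
#' @seealso [scdSolve()]
#' @export
buildSystem <- function(A, W, beta = c(0, 0, 0)) {
  A <- .tm_relaxed(A)
  W <- as.matrix(W)
  .check_finite(W, "W")
  if (any(W < 0)) stop("W must be non-negative", call. = FALSE)
  if (nrow(W) != nrow(A@values))
    stop("W must have as many rows as A", call. = FALSE)
  .check_beta_scd(beta)
  k <- ncol(W)
  m <- ncol(A@values)
  reg <- matrix(beta[2], k, k)
  diag(reg) <- beta[1]
  if (all(A@observed)) {
    V <- crossprod(W) + reg
    U <- -crossprod(W, A@values) + beta[3]
    return(list(V = V, U = U, perColumn = FALSE))
  }
  Vs <- vector("list", m)
  U <- matrix(0, k, m)
  for (j in seq_len(m)) {
    I <- which(A@observed[, j])
    if (length(I) == 0L)
      stop("column ", j, " has no observed entries", call. = FALSE)
    WI <- W[I, , drop = FALSE]
    Vs[[j]] <- crossprod(WI) + reg
    U[, j] <- -crossprod(WI, A@values[I, j]) + beta[3]
  }
  list(V = Vs, U = U, perColumn = TRUE)
}

.check_beta_scd <- function(beta, what = "beta") {
  if (length(beta) != 3L || any(!is.finite(beta)) || any(beta < 0))
    stop(what, " must be three non-negative finite weights", call. = FALSE)
  if (beta[2] > 0 && beta[1] <= beta[2])
    stop(what, ": the angle weight requires ridge > angle (", what,
         "[1] > ", what, "[2]) to keep the quadratic diagonal positive",
         call. = FALSE)
  invisible(beta)
}

#' Sequential coordinate-wise descent for a penalized NNLS system
#'
#' Minimizes `1/2 h' V h + u' h` over `h >= 0` for every column of `U`
#' independently, by cyclic exact coordinate minimization with clamping at
#' zero: `h <- max(0, h - (V h + u)_kbar / v_kbar,kbar)`, keeping a running
#' gradient that is updated incrementally whenever a coordinate changes.
#' Columns are independent; coordinates are swept in fixed ascending order.
#'
#' @param V symmetric k x k matrix with strictly positive diagonal (Gram
#'   plus penalties), or the list returned by [buildSystem()].
#' @param U k x m matrix of linear terms (one column per NNLS problem);
#'   ignored when `V` is a `buildSystem()` result.
#' @param H0 optional non-negative warm-start (k x m); defaults to zero, the
#'   cold start for which the running gradient is simply `U`.
#' @param nInner maximum number of full coordinate sweeps; a sweep that
#'   changes no coordinate terminates early.
#' @return list with `H` (the non-negative solution) and `sweeps` (sweeps
#'   actually run, maximum over columns).
#' @examples
#' V <- diag(2); U <- matrix(c(-3, -5), 2, 1)
#' scdSolve(V, U)$H  # c(3, 5): unconstrained optimum is feasible
#' @export
scdSolve <- function(V, U = NULL, H0 = NULL, nInner = 500L) {
  if (is.list(V) && !is.null(V$perColumn)) {
    sys <- V
    if (!sys$perColumn) return(scdSolve(sys$V, sys$U, H0, nInner))
    m <- ncol(sys$U)
    k <- nrow(sys$U)
    H <- if (is.null(H0)) matrix(0, k, m) else as.matrix(H0)
    sweeps <- 0L
    for (j in seq_len(m)) {
      res <- scdSolve(sys$V[[j]], sys$U[, j, drop = FALSE],
                      H[, j, drop = FALSE], nInner)
      H[, j] <- res$H
      sweeps <- max(sweeps, res$sweeps)
    }
    return(list(H = H, sweeps = sweeps))
  }
  V <- as.matrix(V)
  U <- as.matrix(U)
  if (nrow(V) != ncol(V) || nrow(U) != nrow(V))
    stop("V must be k x k and U k x m", call. = FALSE)
  if (max(abs(V - t(V))) > 1e-8 * max(1, max(abs(V))))
    stop("V must be symmetric", call. = FALSE)
  if (any(diag(V) <= 0))
    stop("V must have a strictly positive diagonal", call. = FALSE)
  if (is.null(H0)) H0 <- matrix(0, nrow(U), ncol(U))
  H0 <- as.matrix(H0)
  if (any(H0 < 0)) stop("H0 must be non-negative", call. = FALSE)
  res <- c_scd_quad(V, U, H0, as.integer(nInner), 1e-16)
  list(H = res$H, sweeps = res$sweeps)
}
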
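#' Missing-value imputation by NMF reconstruction
#'
#' Factorizes the incomplete matrix using only its observed entries and
#' fills each missing entry with the corresponding entry of the
#' reconstruction `W %*% H`.  Because the matrix is assumed (approximately)
#' low-rank, the observed entries are redundant for the factorization and
#' the reconstruction is a reasonable prediction at unobserved positions.
#'
#' Every complete entry informs every imputed one through the shared
#' factors, unlike feature-by-feature imputers.  The procedure assumes the
#' entries are missing completely at random (MCAR); when missingness is
#' correlated with the underlying value, imputations may be biased.
#'
#' @param A a [TargetMatrix-class] or numeric matrix with `NA` for missing
#'   entries.
#' @param k factorization rank.
#' @param ... further arguments passed to [nmfFactorize()] (method, loss,
#'   penalties, `seed`, ...).  The default loss is `"mse"`.
#' @return A list with `completed` (numeric matrix: observed entries passed
#'   through bit-exactly, missing entries replaced by the non-negative
#'   reconstruction) and `fit` (the underlying [NmfFit-class]).
#' @examples
#' set.seed(7)
#' A <- matrix(runif(30), 10, 3) %*% matrix(runif(12, 0, 10), 3, 4)
#' Amiss <- A; Amiss[sample(length(A), 5)] <- NA
#' out <- nmfImpute(Amiss, k = 3, seed = 1)
#' max(abs(out$completed[is.na(Amiss)] - A[is.na(Amiss)]))
#' @seealso [selectRank()] for choosing `k`.
#' @export
nmfImpute <- function(A, k, ...) {
  A <- targetMatrix(A)
  miss <- !A@observed
  if (!any(miss)) {
    warning("no missing entries; returning the input unchanged")
    return(list(completed = A@values, fit = NULL))
  }
  fit <- nmfFactorize(A, k, ...)
  completed <- A@values
  completed[miss] <- (fit@W %*% fit@H)[miss]
  list(completed = completed, fit = fit)
}
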
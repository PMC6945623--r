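#' Tumour-content deconvolution by profile-guided NMF
#'
#' Solves `A ~ W H + W0 H1` where `W0` is a *known* non-negative profile
#' matrix (e.g. healthy expression profiles) and `W` holds `kUnknown`
#' unknown (e.g. cancer) profiles.  Internally this is a single masked
#' factorization over the horizontally stacked basis `[W | W0]`: the `W0`
#' block is fixed via the masking mechanism of [nmfFactorize()] and only
#' `W`, `H` and `H1` are estimated — no special-case solver code.
#'
#' The per-sample content of the unknown component ("tumour purity") is
#' estimated as the fraction of the reconstruction it accounts for:
#' `r_j = sum_i (W H)_ij / sum_i (W H + W0 H1)_ij`, which lies in `[0, 1]`
#' and is invariant to the joint scale of the factors.  Samples whose
#' reconstruction is identically zero get `NA`.
#'
#' By default a small angle penalty is placed on the stacked basis, which
#' discourages the unknown profiles from duplicating the known ones —
#' independence between columns is exactly what the angle penalty
#' maximizes, and is desirable for content deconvolution.
#'
#' @param A a [TargetMatrix-class] or numeric matrix (features x samples).
#' @param W0 known non-negative profile matrix (features x L), rows aligned
#'   with `A`.
#' @param kUnknown number of unknown profile columns (default 1).
#' @param alpha penalty weights for the stacked basis; the default
#'   `c(2 * a2, a2, 0)` with a small `a2` applies the angle penalty (the
#'   ridge must dominate it for the coordinate-descent solver).
#' @param ... further arguments passed to [nmfFactorize()].
#' @return An [NmfDeconvolution-class] with the unknown profiles `W`, their
#'   loadings `H`, the known-profile loadings `H1` and the per-sample
#'   `purity`.
#' @examples
#' sim <- simulateMixture(n = 60, m = 12, L = 2, seed = 4)
#' dec <- deconvolve(sim$A, sim$W0, kUnknown = 1, seed = 5)
#' round(purity(dec), 2)
#' @export
deconvolve <- function(A, W0, kUnknown = 1L, alpha = NULL, ...) {
  A <- targetMatrix(A)
  W0 <- as.matrix(W0)
  if (nrow(W0) != nrow(A@values))
    stop("W0 must have one row per feature of A", call. = FALSE)
  if (any(W0 < 0) || any(!is.finite(W0)))
    stop("W0 must be finite and non-negative", call. = FALSE)
  kUnknown <- as.integer(kUnknown)
  if (kUnknown < 1L) stop("kUnknown must be >= 1", call. = FALSE)
  n <- nrow(A@values)
  L <- ncol(W0)
  K <- kUnknown + L
  if (is.null(alpha)) {
    a2 <- 1e-6 * mean(A@values[A@observed])
    alpha <- c(2 * a2, a2, 0)
  }
  maskW <- cbind(matrix(FALSE, n, kUnknown), matrix(TRUE, n, L))
  dots <- list(...)
  seed <- dots$seed
  initFree <- .with_seed(seed, function()
    matrix(stats::runif(n * kUnknown), n, kUnknown))
  dots$seed <- if (is.null(seed)) NULL else seed + 1L
  fit <- do.call(nmfFactorize,
                 c(list(A = A, k = K, alpha = alpha,
                        maskW = maskW, initW = cbind(initFree, W0)),
                   dots))
  W <- fit@W[, seq_len(kUnknown), drop = FALSE]
  H <- fit@H[seq_len(kUnknown), , drop = FALSE]
  H1 <- fit@H[kUnknown + seq_len(L), , drop = FALSE]
  num <- colSums(W %*% H)
  den <- num + colSums(W0 %*% H1)
  r <- ifelse(den > 0, num / den, NA_real_)
  new("NmfDeconvolution", fit = fit, W = W, H = H, H1 = H1, purity = r)
}

#' @describeIn deconvolve per-sample purity estimates.
#' @param object an `NmfDeconvolution`.
#' @export
setGeneric("purity", function(object) standardGeneric("purity"))

#' @rdname deconvolve
#' @export
setMethod("purity", "NmfDeconvolution", function(object) object@purity)

setMethod("show", "NmfDeconvolution", function(object) {
  cat(sprintf("NmfDeconvolution: %d unknown + %d known profiles, %d samples\n",
              ncol(object@W), nrow(object@H1), ncol(object@H)))
  ok <- object@purity[!is.na(object@purity)]
  cat(sprintf("  purity: median %.3f, range [%.3f, %.3f]\n",
              stats::median(ok), min(ok), max(ok)))
})

#' Build a basis mask from gene sets
#'
#' Constructs the `maskW` pattern for a pathway- or marker-guided
#' factorization with `K` basis columns, the first `L = length(geneSets)`
#' of which are tied to the given sets of feature (row) indices:
#'
#' * `exclusive = FALSE` (pathway mode): column `l` may load only on the
#'   features in set `l`; entries outside `S_l` are fixed to zero.
#' * `exclusive = TRUE` (marker mode): column `l` is forbidden from loading
#'   on the *other* sets' marker features (`w_il` fixed to zero for `i` in
#'   the union of `S_q`, `q != l`), appropriate when each set marks one
#'   cell type or tissue.
#'
#' Columns `L+1, ..., K` are left fully free to absorb unknown pathways or
#' cell types.
#'
#' @param geneSets list of integer vectors of 1-based row indices.
#' @param n number of rows (features).
#' @param K total number of basis columns, `K >= length(geneSets)`.
#' @param exclusive marker-gene mode, see above.
#' @return Logical `n x K` matrix; `TRUE` entries are fixed (to zero) when
#'   passed as `maskW` to [nmfFactorize()].
#' @examples
#' markerMask(list(1:2), n = 4, K = 1)
#' @export
markerMask <- function(geneSets, n, K = length(geneSets),
                       exclusive = FALSE) {
  L <- length(geneSets)
  if (L == 0L) stop("at least one gene set is required", call. = FALSE)
  if (K < L) stop("K must be >= the number of gene sets", call. = FALSE)
  for (l in seq_len(L)) {
    s <- geneSets[[l]]
    if (length(s) == 0L) stop("gene set ", l, " is empty", call. = FALSE)
    if (any(s < 1L | s > n)) stop("gene set ", l, " has indices outside ",
                                  "1..", n, call. = FALSE)
  }
  mask <- matrix(FALSE, n, K)
  for (l in seq_len(L)) {
    if (exclusive) {
      others <- unique(unlist(geneSets[-l]))
      mask[others, l] <- TRUE
    } else {
      mask[setdiff(seq_len(n), geneSets[[l]]), l] <- TRUE
    }
  }
  mask
}

#' Build a coefficient mask for multi-dataset shared-profile factorization
#'
#' For a meta-analysis of several datasets concatenated column-wise into
#' one target matrix, this builds the `maskH` pattern that lets
#' `kShared` basis columns load on every sample while each dataset's
#' `kSpecific` columns may load only on that dataset's samples — the
#' dataset-specific blocks of the coefficient matrix are fixed to zero
#' elsewhere.  Shared columns then capture profiles common to all
#' datasets; specific columns capture dataset-private ones.
#'
#' @param mPerDataset integer vector, number of samples (columns) per
#'   dataset, in concatenation order.
#' @param kShared number of shared basis columns.
#' @param kSpecific integer vector (recycled) of dataset-specific column
#'   counts.
#' @return Logical `K x m` matrix (`K = kShared + sum(kSpecific)`,
#'   `m = sum(mPerDataset)`); `TRUE` entries are fixed to zero when passed
#'   as `maskH` to [nmfFactorize()].  Row order: shared columns first, then
#'   each dataset's specific columns in order.
#' @examples
#' sharedProfileMask(c(3, 2), kShared = 1, kSpecific = 1)
#' @export
sharedProfileMask <- function(mPerDataset, kShared = 1L, kSpecific = 1L) {
  nd <- length(mPerDataset)
  if (nd < 1L) stop("need at least one dataset", call. = FALSE)
  kSpecific <- rep_len(as.integer(kSpecific), nd)
  m <- sum(mPerDataset)
  K <- kShared + sum(kSpecific)
  mask <- matrix(FALSE, K, m)
  colEnd <- cumsum(mPerDataset)
  colStart <- colEnd - mPerDataset + 1L
  row <- kShared
  for (d in seq_len(nd)) {
    if (kSpecific[d] > 0L) {
      rows <- row + seq_len(kSpecific[d])
      ownCols <- seq.int(colStart[d], colEnd[d])
      mask[rows, setdiff(seq_len(m), ownCols)] <- TRUE
      row <- row + kSpecific[d]
    }
  }
  mask
}
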
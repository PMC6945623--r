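#' Simulate the rank-selection benchmark matrix
#'
#' Generates the reference simulation for rank selection: a rank-3 product
#' of uniform factors plus standard-normal noise, clipped at zero.  Entries
#' of `W` (400 x 3) are iid uniform(0, 1) and entries of `H` (3 x 50) iid
#' uniform(0, 10); `A = max(WH + N(0, 1), 0)`, fully observed.  Because the
#' per-entry signal mean (about 7.5) dominates the unit noise, clipping is
#' rare.
#'
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return list with `A` (a fully observed [TargetMatrix-class]), and the
#'   ground-truth `W` and `H`.
#' @seealso [selectRank()]
#' @export
simulateRankData <- function(seed = NULL) {
  .with_seed(seed, function() {
    W <- matrix(stats::runif(400 * 3), 400, 3)
    H <- matrix(stats::runif(3 * 50, 0, 10), 3, 50)
    A <- pmax(W %*% H + matrix(stats::rnorm(400 * 50), 400, 50), 0)
    list(A = targetMatrix(A), W = W, H = H)
  })
}

#' Simulate a noisy low-rank non-negative matrix with MCAR missingness
#'
#' Generalizes the rank-selection design to arbitrary shape: `W` is n x k
#' uniform(0, `wMax`), `H` is k x m uniform(0, `hMax`),
#' `A = max(WH + N(0, noiseSd), 0)`, and a fraction `missingFrac` of
#' entries is deleted completely at random (patterns emptying a row or
#' column are redrawn).
#'
#' @param n,m,k matrix dimensions and true rank.
#' @param noiseSd standard deviation of the additive Gaussian noise
#'   (default 1, the reference design).
#' @param missingFrac fraction of entries deleted, in `[0, 0.5]`.
#' @param wMax,hMax upper bounds of the uniform factor entries (defaults 1
#'   and 10, the reference design).
#' @param seed integer seed.
#' @return list with `A` (a [TargetMatrix-class]), the truth `W`, `H`, the
#'   noise-free clean observed matrix `clean = pmax(WH, 0)` and the logical
#'   `deleted` pattern.
#' @export
simulateLowRank <- function(n, m, k, noiseSd = 1, missingFrac = 0,
                            wMax = 1, hMax = 10, seed = NULL) {
  if (missingFrac < 0 || missingFrac > 0.5)
    stop("missingFrac must be in [0, 0.5]", call. = FALSE)
  .with_seed(seed, function() {
    W <- matrix(stats::runif(n * k, 0, wMax), n, k)
    H <- matrix(stats::runif(k * m, 0, hMax), k, m)
    signal <- W %*% H
    A <- signal
    if (noiseSd > 0)
      A <- A + matrix(stats::rnorm(n * m, 0, noiseSd), n, m)
    A <- pmax(A, 0)
    deleted <- matrix(FALSE, n, m)
    if (missingFrac > 0) {
      nDel <- floor(missingFrac * n * m)
      if (nDel >= 1L) {
        ok <- FALSE
        for (try in 1:50) {
          deleted[] <- FALSE
          deleted[sample(n * m, nDel)] <- TRUE
          if (all(rowSums(!deleted) > 0L) && all(colSums(!deleted) > 0L)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("missingFrac infeasible for this matrix size",
                      call. = FALSE)
      }
    }
    tm <- new("TargetMatrix", values = A, observed = !deleted)
    list(A = tm, W = W, H = H, clean = signal, deleted = deleted)
  })
}

#' Simulate expression mixtures with known content fractions
#'
#' Builds mixture samples `A = Wc Hc + W0 H1` for deconvolution tests:
#' `W0` (n x L) holds known "healthy" profiles and `Wc` (n x kUnknown)
#' unknown "cancer" profiles, both uniform(0, 1).  Per sample `j` a purity
#' `p_j` is drawn uniformly from `purityRange` and the loading columns are
#' scaled so the cancer component contributes exactly the fraction `p_j`
#' of the sample's total reconstruction mass — the recorded purity equals
#' the generative mixing weight by construction.
#'
#' @param n,m number of features and samples.
#' @param L number of known profiles.
#' @param kUnknown number of unknown profiles.
#' @param purityRange length-2 numeric within `[0, 1]`.
#' @param totalMass expected column total of `A` (sets the overall scale).
#' @param noiseSd optional Gaussian noise (clipped at zero), default 0.
#' @param seed integer seed.
#' @return list with `A` (a [TargetMatrix-class]), `W0`, `purity`, and the
#'   truth `Wc`, `Hc`, `H1`.
#' @seealso [deconvolve()]
#' @export
simulateMixture <- function(n, m, L = 2L, kUnknown = 1L,
                            purityRange = c(0.1, 0.9), totalMass = n,
                            noiseSd = 0, seed = NULL) {
  if (any(purityRange < 0) || any(purityRange > 1))
    stop("purityRange must lie within [0, 1]", call. = FALSE)
  .with_seed(seed, function() {
    W0 <- matrix(stats::runif(n * L), n, L)
    Wc <- matrix(stats::runif(n * kUnknown), n, kUnknown)
    p <- stats::runif(m, purityRange[1], purityRange[2])
    Hc <- matrix(stats::runif(kUnknown * m), kUnknown, m)
    H1 <- matrix(stats::runif(L * m), L, m)
    sc <- colSums(Wc %*% Hc)
    s0 <- colSums(W0 %*% H1)
    Hc <- Hc * rep(p * totalMass / sc, each = kUnknown)
    H1 <- H1 * rep((1 - p) * totalMass / s0, each = L)
    A <- Wc %*% Hc + W0 %*% H1
    if (noiseSd > 0)
      A <- pmax(A + matrix(stats::rnorm(n * m, 0, noiseSd), n, m), 0)
    list(A = targetMatrix(A), W0 = W0, purity = p,
         Wc = Wc, Hc = Hc, H1 = H1)
  })
}
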
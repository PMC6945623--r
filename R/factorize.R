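#' Regularized non-negative matrix factorization
#'
#' Factorizes a non-negative target matrix `A` (possibly with missing
#' entries) as `A ~ W H` with `W, H >= 0`, minimizing the observed-entry
#' loss plus the ridge/angle/L1 penalties, by alternately solving for `H`
#' (with `W` fixed) and for `W` (with `H` fixed, via transposition — one
#' solver path serves both factors).
#'
#' Two solver families are available:
#'
#' * `method = "scd"` — sequential coordinate-wise descent.  Under square
#'   loss each coordinate subproblem is an exact clamped quadratic
#'   minimization with an incrementally maintained gradient; under KL loss
#'   a clamped Newton step on a second-order Taylor model is used.  A
#'   Newton-like second-order scheme, it typically converges in far fewer
#'   epochs than the multiplicative rules.
#' * `method = "lee"` — the classic multiplicative updates, generalized to
#'   the unified penalties.
#'
#' Missing entries (unobserved positions of `A`) are handled by dropping
#' their loss terms: per column, cross-products are restricted to the
#' observed rows.  Unobserved values never influence any output.
#'
#' One *epoch* is a complete scan over all entries of `W` and `H`; each
#' outer alternation runs `nInner` solver sweeps per factor and thus counts
#' as `nInner` epochs.  Square-loss solvers benefit from `nInner > 1`
#' (the expensive cross-products are reused across sweeps); KL solvers do
#' not (the reconstruction must be refreshed every sweep), hence the
#' defaults of 50 and 1.
#'
#' Convergence is declared when the relative change of the mean
#' observed-entry loss between consecutive outer alternations,
#' `|l_prev - l| / max(l_prev, eps)`, falls below `relTol`, or when
#' `maxEpochs` is exhausted.  Successive alternations warm-start each
#' factor at its previous value.
#'
#' The factorization is defined up to a joint rescaling/permutation of the
#' factors; no normalization is applied by default (see
#' [normalizeBasis()]).
#'
#' @param A a [TargetMatrix-class] or numeric matrix; `NA` entries are
#'   treated as unobserved.
#' @param k factorization rank (number of basis columns).
#' @param method `"scd"` (coordinate descent) or `"lee"` (multiplicative).
#' @param loss `"mse"` (square error) or `"mkl"` (KL divergence).
#' @param alpha numeric length 3, penalty weights `(ridge, angle, L1)`
#'   applied to `W` (its columns for the angle term).
#' @param beta same, applied to `t(H)` (the angle term acts on rows of
#'   `H`).  For `method = "scd"` each weight triple must satisfy
#'   `ridge > angle` or `angle = 0`, which keeps the quadratic diagonal
#'   strictly positive.
#' @param nInner solver sweeps per factor per outer alternation; default 50
#'   under square loss, 1 under KL.
#' @param maxEpochs total epoch budget.
#' @param relTol relative-change convergence tolerance (> 0).
#' @param seed integer; seeds the uniform(0,1) default initialization.  The
#'   caller's RNG state is left untouched.  `NULL` draws from the current
#'   RNG stream.
#' @param maskW,maskH optional logical patterns (n x k and k x m); `TRUE`
#'   entries are *fixed* for the whole run at their initial values (from
#'   `initW`/`initH`, or 0 if none given) — hard regularization used for
#'   guided factorization.
#' @param initW,initH optional non-negative starting values overriding the
#'   random initialization.
#' @param eps small positive guard for denominators and KL logs.
#' @param verbose if positive, print the mean loss each outer alternation.
#' @return An [NmfFit-class] object.
#' @examples
#' set.seed(1)
#' A <- matrix(runif(20 * 6), 20, 6) %*% matrix(runif(6 * 10), 6, 10)
#' fit <- nmfFactorize(A, k = 6, seed = 42)
#' tail(lossTrace(fit), 1)  # ~0: exact low-rank target is recovered
#' @seealso [nmfImpute()], [selectRank()], [deconvolve()]
#' @export
nmfFactorize <- function(A, k, method = c("scd", "lee"),
                         loss = c("mse", "mkl"),
                         alpha = c(0, 0, 0), beta = c(0, 0, 0),
                         nInner = NULL, maxEpochs = 2000L, relTol = 1e-4,
                         seed = NULL, maskW = NULL, maskH = NULL,
                         initW = NULL, initH = NULL,
                         eps = 1e-16, verbose = 0L) {
  method <- match.arg(method)
  loss <- match.arg(loss)
  A <- targetMatrix(A)
  n <- nrow(A@values)
  m <- ncol(A@values)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > min(n, m))
    warning("k exceeds min(dim(A)); the factorization is overparameterized")
  if (!is.numeric(relTol) || relTol <= 0)
    stop("relTol must be positive", call. = FALSE)
  if (is.null(nInner)) nInner <- if (loss == "mse") 50L else 1L
  nInner <- as.integer(nInner)
  if (nInner < 1L) stop("nInner must be >= 1", call. = FALSE)
  if (method == "scd") {
    .check_beta_scd(alpha, "alpha")
    .check_beta_scd(beta, "beta")
  }

  ini <- .nmf_init(n, m, k, seed, initW, initH, maskW, maskH, method)
  W <- ini$W
  H <- ini$H

  kern <- .tm_for_kernel(A)
  At <- t(kern$values)
  obsT <- if (kern$missing) t(kern$obs) else kern$obs
  fxH <- if (is.null(maskH)) matrix(integer(0), 0, 0) else
    matrix(as.integer(maskH), k, m)
  fxWt <- if (is.null(maskW)) matrix(integer(0), 0, 0) else
    t(matrix(as.integer(maskW), n, k))
  mcode <- switch(paste(method, loss),
                  "scd mse" = 1L, "lee mse" = 2L,
                  "scd mkl" = 3L, "lee mkl" = 4L)

  nOuterMax <- max(1L, as.integer(ceiling(maxEpochs / nInner)))
  lossTr <- objTr <- epochTr <- numeric(nOuterMax)
  obsPat <- A@observed
  aObs <- A@values[obsPat]
  prev <- NA_real_
  relChange <- NA_real_
  converged <- FALSE
  it <- 0L
  while (it < nOuterMax) {
    it <- it + 1L
    H <- c_update_factor(kern$values, W, H, beta, kern$obs, fxH,
                         nInner, eps, mcode)
    W <- t(c_update_factor(At, t(H), t(W), alpha, obsT, fxWt,
                           nInner, eps, mcode))
    yhat <- (W %*% H)[obsPat]
    if (loss == "mse") {
      sq <- (aObs - yhat)^2
      ml <- mean(sq)
      obj <- 0.5 * sum(sq)
    } else {
      y <- pmax(yhat, eps)
      terms <- ifelse(aObs > 0, aObs * log(aObs / y), 0) - aObs + yhat
      ml <- mean(terms)
      obj <- sum(terms)
    }
    obj <- obj + .total_penalty(W, H, alpha, beta)
    lossTr[it] <- ml
    objTr[it] <- obj
    epochTr[it] <- it * nInner
    if (verbose > 0)
      message(sprintf("epoch %6d  mean %s %.8g", it * nInner,
                      toupper(loss), ml))
    if (!is.na(prev)) {
      relChange <- abs(prev - ml) / max(prev, eps)
      if (relChange < relTol) {
        converged <- TRUE
        break
      }
    }
    prev <- ml
  }

  new("NmfFit", W = W, H = H,
      lossTrace = lossTr[seq_len(it)],
      objectiveTrace = objTr[seq_len(it)],
      epochTrace = epochTr[seq_len(it)],
      epochsRun = it * nInner,
      converged = converged,
      finalRelChange = relChange,
      config = list(k = k, method = method, loss = loss,
                    alpha = as.numeric(alpha), beta = as.numeric(beta),
                    nInner = nInner, maxEpochs = as.integer(maxEpochs),
                    relTol = relTol,
                    seed = if (is.null(seed)) NA_integer_ else
                      as.integer(seed),
                    eps = eps))
}

# Default initialization: iid uniform(0, 1) entries for both factors, with
# user-supplied matrices overriding and mask-fixed entries stamped last
# (to the user initial value, or 0 when none was given).
.nmf_init <- function(n, m, k, seed, initW, initH, maskW, maskH, method) {
  drawn <- .with_seed(seed, function()
    list(W = matrix(stats::runif(n * k), n, k),
         H = matrix(stats::runif(k * m), k, m)))
  W <- drawn$W
  H <- drawn$H
  if (!is.null(initW)) {
    initW <- as.matrix(initW)
    if (!identical(dim(initW), c(n, k)))
      stop("initW must be ", n, " x ", k, call. = FALSE)
    if (any(initW < 0) || any(!is.finite(initW)))
      stop("initW must be finite and non-negative", call. = FALSE)
    W <- initW
  }
  if (!is.null(initH)) {
    initH <- as.matrix(initH)
    if (!identical(dim(initH), c(k, m)))
      stop("initH must be ", k, " x ", m, call. = FALSE)
    if (any(initH < 0) || any(!is.finite(initH)))
      stop("initH must be finite and non-negative", call. = FALSE)
    H <- initH
  }
  if (!is.null(maskW)) {
    maskW <- matrix(as.logical(maskW), n, k)
    W[maskW] <- if (is.null(initW)) 0 else initW[maskW]
  }
  if (!is.null(maskH)) {
    maskH <- matrix(as.logical(maskH), k, m)
    H[maskH] <- if (is.null(initH)) 0 else initH[maskH]
  }
  if (method == "lee" && (any(W == 0) || any(H == 0)))
    warning("multiplicative updates keep zero-initialized entries at zero")
  list(W = W, H = H)
}

#' @describeIn nmfFactorize basis matrix `W` of a fit.
#' @param object an `NmfFit`.
#' @export
setGeneric("basisMatrix", function(object) standardGeneric("basisMatrix"))

#' @rdname nmfFactorize
#' @export
setMethod("basisMatrix", "NmfFit", function(object) object@W)

#' @describeIn nmfFactorize coefficient matrix `H` of a fit.
#' @export
setGeneric("coefMatrix", function(object) standardGeneric("coefMatrix"))

#' @rdname nmfFactorize
#' @export
setMethod("coefMatrix", "NmfFit", function(object) object@H)

#' @describeIn nmfFactorize mean observed-entry loss after each outer
#'   alternation (no 1/2 factor under MSE).
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))

#' @rdname nmfFactorize
#' @export
setMethod("lossTrace", "NmfFit", function(object) object@lossTrace)

#' @describeIn nmfFactorize penalized objective after each outer
#'   alternation.
#' @export
setGeneric("objectiveTrace", function(object)
  standardGeneric("objectiveTrace"))

#' @rdname nmfFactorize
#' @export
setMethod("objectiveTrace", "NmfFit", function(object)
  object@objectiveTrace)

#' @describeIn nmfFactorize cumulative epochs at each trace point.
#' @export
setGeneric("epochTrace", function(object) standardGeneric("epochTrace"))

#' @rdname nmfFactorize
#' @export
setMethod("epochTrace", "NmfFit", function(object) object@epochTrace)

#' @describeIn nmfFactorize total epochs consumed by the run.
#' @export
setGeneric("epochsRun", function(object) standardGeneric("epochsRun"))

#' @rdname nmfFactorize
#' @export
setMethod("epochsRun", "NmfFit", function(object) object@epochsRun)

#' @describeIn nmfFactorize whether the tolerance was reached in budget.
#' @export
setGeneric("hasConverged", function(object) standardGeneric("hasConverged"))

#' @rdname nmfFactorize
#' @export
setMethod("hasConverged", "NmfFit", function(object) object@converged)

#' @describeIn nmfFactorize the reconstruction `W %*% H`.
#' @export
setGeneric("reconstruct", function(object) standardGeneric("reconstruct"))

#' @rdname nmfFactorize
#' @export
setMethod("reconstruct", "NmfFit", function(object) object@W %*% object@H)

setMethod("show", "NmfFit", function(object) {
  cfg <- object@config
  cat(sprintf("NmfFit: %d x %d ~ (%d x %d) (%d x %d)\n",
              nrow(object@W), ncol(object@H),
              nrow(object@W), ncol(object@W),
              nrow(object@H), ncol(object@H)))
  cat(sprintf("  method %s, loss %s, nInner %d\n",
              toupper(cfg$method), toupper(cfg$loss), cfg$nInner))
  cat(sprintf("  epochs run: %d, converged: %s (rel. change %.3g)\n",
              object@epochsRun, object@converged, object@finalRelChange))
  cat(sprintf("  final mean %s: %.6g\n", toupper(cfg$loss),
              utils::tail(object@lossTrace, 1)))
})

#' Normalize a fit so basis columns sum to one
#'
#' Rescales each column of `W` to unit sum and multiplies the matching row
#' of `H` by the removed factor, leaving the reconstruction `W %*% H`
#' unchanged.  The factorization has an inherent scale indeterminacy; this
#' optional post-processing fixes one convention.  Columns of `W` that sum
#' to zero are left untouched.
#'
#' @param object an [NmfFit-class].
#' @return A new `NmfFit` with rescaled factors.
#' @export
setGeneric("normalizeBasis", function(object)
  standardGeneric("normalizeBasis"))

#' @rdname normalizeBasis
#' @export
setMethod("normalizeBasis", "NmfFit", function(object) {
  s <- colSums(object@W)
  s[s == 0] <- 1
  object@W <- sweep(object@W, 2, s, "/")
  object@H <- object@H * s
  object
})
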
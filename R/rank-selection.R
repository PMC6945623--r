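#' Choose the factorization rank by holdout imputation
#'
#' The rank `k` is the single critical hyperparameter of NMF.  This selects
#' it by a training/validation split over matrix *entries*: some fraction
#' of the observed entries is deleted at random, the deleted entries are
#' imputed by NMF at each candidate rank, and the rank minimizing the error
#' between imputed and held-back values is chosen.  Only the correct rank
#' should both capture the signal (unlike too-small ranks) and avoid
#' fitting noise (unlike too-large ranks), so the held-out error is
#' typically U-shaped in `k` while the training error decreases
#' monotonically.
#'
#' Each of `nRuns` runs draws an independent deletion pattern, uniform
#' without replacement over the observed entries of `A`.  Patterns that
#' would empty a row or column are redrawn (bounded retries).  The selected
#' rank minimizes the *mean* held-out MSE across runs; ties break toward
#' the smaller rank for parsimony.  Per-run argmins are also reported.
#'
#' @param A a [TargetMatrix-class] or numeric matrix (`NA` = unobserved).
#' @param kGrid integer vector of candidate ranks (default `1:6`).
#' @param holdoutFrac fraction of observed entries to delete per run, in
#'   `(0, 0.5]`; default 0.3.
#' @param nRuns number of independent deletion patterns (default 5).
#' @param seed integer master seed; the deletion patterns and all
#'   factorization initializations derive from it.
#' @param ... further arguments passed to [nmfFactorize()] (loss defaults
#'   to `"mse"`).
#' @return A [RankSurvey-class] object.
#' @examples
#' sim <- simulateLowRank(60, 20, k = 2, noiseSd = 0.1, seed = 3)
#' rs <- selectRank(sim$A, kGrid = 1:4, nRuns = 2, seed = 9,
#'                  maxEpochs = 500)
#' selectedRank(rs)
#' @export
selectRank <- function(A, kGrid = 1:6, holdoutFrac = 0.3, nRuns = 5L,
                       seed = NULL, ...) {
  A <- targetMatrix(A)
  kGrid <- sort(unique(as.integer(kGrid)))
  if (any(kGrid < 1L)) stop("ranks must be >= 1", call. = FALSE)
  if (holdoutFrac <= 0 || holdoutFrac > 0.5)
    stop("holdoutFrac must be in (0, 0.5]", call. = FALSE)
  nRuns <- as.integer(nRuns)
  .with_seed(seed, function() {
    nk <- length(kGrid)
    mse <- mkl <- train <- matrix(NA_real_, nRuns, nk,
                                  dimnames = list(NULL, paste0("k", kGrid)))
    for (r in seq_len(nRuns)) {
      del <- .draw_holdout(A, holdoutFrac)
      Atrain <- new("TargetMatrix", values = A@values,
                    observed = A@observed & !del)
      heldTruth <- A@values[del]
      for (ik in seq_along(kGrid)) {
        fit <- nmfFactorize(Atrain, kGrid[ik], ...)
        rec <- fit@W %*% fit@H
        imput <- rec[del]
        mse[r, ik] <- mean((heldTruth - imput)^2)
        y <- pmax(imput, 1e-16)
        mkl[r, ik] <- mean(ifelse(heldTruth > 0,
                                  heldTruth * log(heldTruth / y), 0) -
                           heldTruth + imput)
        tr <- Atrain@observed
        train[r, ik] <- mean((A@values[tr] - rec[tr])^2)
      }
    }
    meanErr <- colMeans(mse)
    new("RankSurvey", kGrid = kGrid, mseErrors = mse, mklErrors = mkl,
        trainErrors = train,
        perRunBest = kGrid[apply(mse, 1, which.min)],
        kSelected = kGrid[which.min(meanErr)],
        nRuns = nRuns, holdoutFrac = holdoutFrac,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
}

# Uniform MCAR deletion over observed entries, redrawn (up to 50 times)
# if it would leave a row or column with no observed entry.
.draw_holdout <- function(A, frac) {
  obsIdx <- which(A@observed)
  nDel <- floor(frac * length(obsIdx))
  if (nDel < 1L) stop("holdout fraction deletes no entries", call. = FALSE)
  for (try in 1:50) {
    del <- matrix(FALSE, nrow(A@values), ncol(A@values))
    del[sample(obsIdx, nDel)] <- TRUE
    remaining <- A@observed & !del
    if (all(rowSums(remaining) > 0L) && all(colSums(remaining) > 0L))
      return(del)
  }
  stop("could not draw a deletion pattern keeping every row and column ",
       "partly observed", call. = FALSE)
}

#' @describeIn selectRank the selected rank.
#' @param object a `RankSurvey`.
#' @export
setGeneric("selectedRank", function(object) standardGeneric("selectedRank"))

#' @rdname selectRank
#' @export
setMethod("selectedRank", "RankSurvey", function(object) object@kSelected)

#' @describeIn selectRank held-out error surface (`nRuns` x ranks), metric
#'   `"mse"`, `"mkl"` or `"train"`.
#' @param metric which error matrix to return.
#' @export
setGeneric("errorSurface", function(object, metric = "mse")
  standardGeneric("errorSurface"))

#' @rdname selectRank
#' @export
setMethod("errorSurface", "RankSurvey", function(object, metric = "mse") {
  switch(match.arg(metric, c("mse", "mkl", "train")),
         mse = object@mseErrors, mkl = object@mklErrors,
         train = object@trainErrors)
})

setMethod("show", "RankSurvey", function(object) {
  cat(sprintf("RankSurvey over k = {%s}, %d runs, %.0f%% holdout\n",
              paste(object@kGrid, collapse = ", "), object@nRuns,
              100 * object@holdoutFrac))
  cat("  mean held-out MSE by k:\n")
  print(signif(colMeans(object@mseErrors), 4))
  cat(sprintf("  per-run argmin: %s\n",
              paste(object@perRunBest, collapse = ", ")))
  cat(sprintf("  selected k: %d\n", object@kSelected))
})
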
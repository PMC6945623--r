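#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib nmfkit, .registration = TRUE
NULL

#' Non-negative target matrix with an explicit observed-entry pattern
#'
#' `TargetMatrix` wraps a features-by-samples non-negative matrix together
#' with a logical pattern marking which entries are observed (present and
#' trusted).  All solvers in the package only ever read observed entries;
#' unobserved ones carry no information and may hold `NA` or arbitrary
#' values.
#'
#' Every observed entry must be finite and non-negative, and every row and
#' every column must contain at least one observed entry — reconstruction of
#' a fully-missing row or column is unreliable and such inputs are rejected
#' at construction time.
#'
#' @slot values numeric matrix (n features x m samples).
#' @slot observed logical matrix of the same shape; `TRUE` marks an observed
#'   entry.
#'
#' @seealso [targetMatrix()], [nmfFactorize()]
#' @export
setClass("TargetMatrix",
  representation(values = "matrix", observed = "matrix"))

setValidity("TargetMatrix", function(object) {
  v <- object@values
  o <- object@observed
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (!is.logical(o)) return("observed must be a logical matrix")
  if (!identical(dim(v), dim(o)))
    return("values and observed must have identical dimensions")
  if (any(is.na(o))) return("observed pattern must not contain NA")
  vo <- v[o]
  if (any(!is.finite(vo)))
    return("all observed values must be finite")
  if (any(vo < 0))
    return("all observed values must be non-negative")
  TRUE
})

#' Result of a non-negative matrix factorization
#'
#' Holds the factor pair `A ~ W H`, the per-outer-iteration loss and
#' penalized-objective traces, epoch accounting and the convergence state.
#' One *epoch* is a complete scan over all entries of both `W` and `H`; an
#' outer alternation that runs `nInner` solver sweeps per factor therefore
#' advances the epoch counter by `nInner`.
#'
#' @slot W numeric matrix, n x k non-negative basis ("metagene" profiles).
#' @slot H numeric matrix, k x m non-negative coefficients (sample loadings).
#' @slot lossTrace numeric; mean unpenalized loss per observed entry after
#'   each outer alternation (MSE without the 1/2 factor, or mean KL).
#' @slot objectiveTrace numeric; the full penalized objective (sum of
#'   per-entry losses with the internal 1/2 convention for MSE, plus all
#'   penalty terms) after each outer alternation.
#' @slot epochTrace numeric; cumulative epochs at each trace point.
#' @slot epochsRun integer; total epochs consumed.
#' @slot converged logical; whether the relative-change criterion was met
#'   before the epoch budget ran out.
#' @slot finalRelChange numeric; last relative change of the mean loss.
#' @slot config list; all settings of the run (k, method, loss, alpha, beta,
#'   nInner, maxEpochs, relTol, seed, eps).
#'
#' @seealso [nmfFactorize()], [basisMatrix()], [coefMatrix()]
#' @export
setClass("NmfFit",
  representation(W = "matrix", H = "matrix",
                 lossTrace = "numeric", objectiveTrace = "numeric",
                 epochTrace = "numeric",
                 epochsRun = "integer", converged = "logical",
                 finalRelChange = "numeric", config = "list"))

setValidity("NmfFit", function(object) {
  if (ncol(object@W) != nrow(object@H))
    return("W and H have incompatible inner dimensions")
  if (any(object@W < 0) || any(object@H < 0))
    return("factors must be non-negative")
  TRUE
})

#' Result of holdout-imputation rank selection
#'
#' For each of `nRuns` random deletion patterns and each candidate rank,
#' records the reconstruction error on the deleted (held-out) entries and on
#' the retained (training) entries.  The selected rank minimizes the mean
#' held-out MSE across runs, with ties broken toward the smaller rank.
#'
#' @slot kGrid integer vector of candidate ranks.
#' @slot mseErrors numeric matrix (nRuns x length(kGrid)); held-out mean
#'   square error, computed only on deleted entries.
#' @slot mklErrors numeric matrix; held-out mean KL divergence.
#' @slot trainErrors numeric matrix; mean square error on retained entries.
#' @slot perRunBest integer; argmin rank of each run's held-out MSE.
#' @slot kSelected integer; rank minimizing the mean held-out MSE.
#' @slot nRuns integer.
#' @slot holdoutFrac numeric; fraction of observed entries deleted per run.
#' @slot seed integer or NA.
#'
#' @seealso [selectRank()]
#' @export
setClass("RankSurvey",
  representation(kGrid = "integer", mseErrors = "matrix",
                 mklErrors = "matrix", trainErrors = "matrix",
                 perRunBest = "integer", kSelected = "integer",
                 nRuns = "integer", holdoutFrac = "numeric",
                 seed = "integer"))

#' Result of profile-guided deconvolution
#'
#' @slot fit the underlying [NmfFit-class] over the stacked basis
#'   `[W | W0]`.
#' @slot W numeric matrix; the estimated unknown (e.g. cancer) profiles.
#' @slot H numeric matrix; loadings of the unknown profiles.
#' @slot H1 numeric matrix; loadings of the known profiles `W0`.
#' @slot purity numeric vector; per-sample fraction of the reconstruction
#'   attributable to the unknown component, in `[0, 1]` (NA where the
#'   reconstruction of a sample is identically zero).
#'
#' @seealso [deconvolve()]
#' @export
setClass("NmfDeconvolution",
  representation(fit = "NmfFit", W = "matrix", H = "matrix",
                 H1 = "matrix", purity = "numeric"))
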
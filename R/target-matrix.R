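#' Construct a TargetMatrix
#'
#' Builds a [TargetMatrix-class] from a numeric matrix.  `NA`/`NaN` entries
#' are treated as unobserved unless an explicit `observed` pattern is given.
#'
#' @param x numeric matrix (features x samples), entries non-negative where
#'   observed.
#' @param observed optional logical matrix of the same shape; defaults to
#'   `!is.na(x)`.
#'
#' @return A [TargetMatrix-class] object.
#' @examples
#' A <- matrix(c(1, 2, NA, 4), 2, 2)
#' tm <- targetMatrix(A)
#' nObserved(tm)
#' @export
targetMatrix <- function(x, observed = NULL) {
  if (is(x, "TargetMatrix")) return(x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(observed)) observed <- !is.na(x)
  observed <- as.matrix(observed)
  if (!is.logical(observed)) storage.mode(observed) <- "logical"
  tm <- new("TargetMatrix", values = x, observed = observed)
  if (any(rowSums(observed) == 0L))
    stop("every row must contain at least one observed entry; ",
         "reconstruction of fully-missing rows is unreliable",
         call. = FALSE)
  if (any(colSums(observed) == 0L))
    stop("every column must contain at least one observed entry; ",
         "reconstruction of fully-missing columns is unreliable",
         call. = FALSE)
  tm
}

# Relaxed coercion for low-level per-column operations, which may legally
# see blocks whose rows are entirely missing; only the per-entry invariants
# are enforced.
.tm_relaxed <- function(x) {
  if (is(x, "TargetMatrix")) return(x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  new("TargetMatrix", values = x, observed = !is.na(x))
}

#' @describeIn targetMatrix logical observed-entry pattern.
#' @param object,... a `TargetMatrix`.
#' @export
setGeneric("observedPattern", function(object, ...)
  standardGeneric("observedPattern"))

#' @rdname targetMatrix
#' @export
setMethod("observedPattern", "TargetMatrix", function(object, ...)
  object@observed)

#' @describeIn targetMatrix number of observed entries.
#' @export
setGeneric("nObserved", function(object, ...) standardGeneric("nObserved"))

#' @rdname targetMatrix
#' @export
setMethod("nObserved", "TargetMatrix", function(object, ...)
  sum(object@observed))

#' Coerce a TargetMatrix back to a base matrix
#'
#' Unobserved entries are returned as `NA`.
#'
#' @param x a [TargetMatrix-class].
#' @param ... ignored.
#' @return numeric matrix with `NA` at unobserved positions.
#' @export
setMethod("as.matrix", "TargetMatrix", function(x, ...) {
  v <- x@values
  v[!x@observed] <- NA_real_
  v
})

#' @export
setMethod("dim", "TargetMatrix", function(x) dim(x@values))

setMethod("show", "TargetMatrix", function(object) {
  d <- dim(object@values)
  no <- sum(object@observed)
  cat(sprintf("TargetMatrix: %d features x %d samples\n", d[1], d[2]))
  cat(sprintf("  observed entries: %d / %d (%.1f%%)\n",
              no, prod(d), 100 * no / prod(d)))
  vo <- object@values[object@observed]
  cat(sprintf("  value range: [%g, %g]\n", min(vo), max(vo)))
})

# Internal: values with unobserved entries zeroed (safe to hand to kernels
# that must never read unobserved positions) plus the pattern, or an empty
# pattern when fully observed.
.tm_for_kernel <- function(tm) {
  v <- tm@values
  miss <- !tm@observed
  if (any(miss)) {
    v[miss] <- 0
    obs <- matrix(as.integer(tm@observed), nrow(v), ncol(v))
  } else {
    obs <- matrix(integer(0), 0, 0)
  }
  list(values = v, obs = obs, missing = any(miss))
}
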
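# Run fn() under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, fn) {
  if (is.null(seed) || is.na(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Match estimated factor columns to reference columns
#'
#' NMF is invariant to jointly permuting columns of `W` and rows of `H`;
#' comparing an estimate to a ground truth therefore needs an assignment
#' step.  This finds, over all permutations (exhaustively, so it is meant
#' for small `k`), the column assignment maximizing the total Pearson
#' correlation between matched columns.
#'
#' @param West estimated matrix (n x k).
#' @param Wref reference matrix (n x k), same shape.
#' @return list with `perm` (index vector such that `West[, perm]` matches
#'   `Wref` column-for-column) and `correlations` (per matched pair).
#' @export
matchColumns <- function(West, Wref) {
  West <- as.matrix(West)
  Wref <- as.matrix(Wref)
  k <- ncol(Wref)
  if (ncol(West) != k) stop("column counts differ", call. = FALSE)
  if (k > 8L) stop("exhaustive matching supports k <= 8", call. = FALSE)
  C <- suppressWarnings(stats::cor(West, Wref))
  C[!is.finite(C)] <- -1
  perms <- .permutations(k)
  best <- NULL
  bestv <- -Inf
  for (p in perms) {
    v <- sum(C[cbind(p, seq_len(k))])
    if (v > bestv) {
      bestv <- v
      best <- p
    }
  }
  list(perm = best, correlations = C[cbind(best, seq_len(k))])
}

.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- .permutations(k - 1L)
  out <- vector("list", k * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in 0:(k - 1L)) {
      i <- i + 1L
      out[[i]] <- append(p, k, after = pos)
    }
  }
  out
}
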
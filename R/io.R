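#' Read a target matrix from a delimited or MatrixMarket file
#'
#' Reads CSV/TSV (with optional row and column labels; the first column is
#' used as row names when non-numeric) or MatrixMarket (`.mtx`) files into
#' a [TargetMatrix-class].  In delimited files, empty cells and any cell
#' matching `missingMarkers` become unobserved entries.  A MatrixMarket
#' file is taken as fully observed unless a companion delimited 0/1 file is
#' given via `observedFile`.
#'
#' Files are 1-based and label-oriented; any negative value is rejected
#' with its row/column coordinates, since the factorization requires
#' non-negative data.
#'
#' @param path file to read.
#' @param format `"auto"` (from the extension), `"csv"`, `"tsv"` or
#'   `"mtx"`.
#' @param missingMarkers character values marking unobserved entries.
#' @param observedFile optional delimited 0/1 pattern for `"mtx"` input.
#' @return A [TargetMatrix-class].
#' @seealso [writeTargetMatrix()]
#' @export
readTargetMatrix <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                             missingMarkers = c("NA", "NaN", ""),
                             observedFile = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx",
                     tsv = , txt = , tab = "tsv",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format=", call. = FALSE))
  }
  if (format == "mtx") {
    M <- as.matrix(Matrix::readMM(path))
    obs <- NULL
    if (!is.null(observedFile)) {
      obs <- as.matrix(utils::read.table(observedFile))
      obs <- matrix(as.logical(obs), nrow(M), ncol(M))
    }
    .check_nonneg_cells(M)
    return(targetMatrix(M, observed = obs))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          na.strings = missingMarkers,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) > 1L && !is.numeric(df[[1L]])) {
    rn <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
    M <- as.matrix(df)
    rownames(M) <- rn
  } else {
    M <- as.matrix(df)
  }
  if (!is.numeric(M))
    stop("non-numeric cells in ", path, call. = FALSE)
  .check_nonneg_cells(M)
  targetMatrix(M)
}

.check_nonneg_cells <- function(M) {
  bad <- which(!is.na(M) & M < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("negative value at row ", bad[1, 1], ", column ", bad[1, 2],
         ": the target matrix must be non-negative", call. = FALSE)
  invisible(M)
}

#' Write a target matrix to a delimited file
#'
#' Unobserved entries are written as `NA`; [readTargetMatrix()] of the
#' result restores both values and the observed pattern losslessly.
#'
#' @param tm a [TargetMatrix-class] or numeric matrix.
#' @param path output file; the extension selects CSV or TSV.
#' @return `path`, invisibly.
#' @export
writeTargetMatrix <- function(tm, path) {
  tm <- targetMatrix(tm)
  M <- as.matrix(tm)
  if (is.null(colnames(M))) colnames(M) <- paste0("s", seq_len(ncol(M)))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- as.data.frame(M)
  if (!is.null(rownames(M)) &&
      !identical(rownames(M), as.character(seq_len(nrow(M))))) {
    df <- cbind(feature = rownames(M), df)
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Write a factorization result to a directory
#'
#' Writes `W.tsv`, `H.tsv`, the loss/objective traces (`trace.tsv`) and a
#' JSON run manifest (`manifest.json`) holding every configuration field —
#' rank, algorithm, loss, penalty weights, inner sweeps, epoch budget,
#' tolerance, seed — plus the epochs run, convergence flag and final
#' losses.  Re-running [nmfFactorize()] with the manifest settings on the
#' same data reproduces `W` and `H` bit-for-bit.
#'
#' @param fit an [NmfFit-class].
#' @param dir output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
writeFit <- function(fit, dir) {
  stopifnot(is(fit, "NmfFit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pW <- file.path(dir, "W.tsv")
  pH <- file.path(dir, "H.tsv")
  pT <- file.path(dir, "trace.tsv")
  pM <- file.path(dir, "manifest.json")
  utils::write.table(fit@W, pW, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  utils::write.table(fit@H, pH, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  utils::write.table(
    data.frame(epoch = fit@epochTrace, meanLoss = fit@lossTrace,
               objective = fit@objectiveTrace),
    pT, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(fit@config,
                list(epochsRun = fit@epochsRun,
                     converged = fit@converged,
                     finalRelChange = fit@finalRelChange,
                     finalMeanLoss = utils::tail(fit@lossTrace, 1)))
  jsonlite::write_json(manifest, pM, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(W = pW, H = pH, trace = pT, manifest = pM))
}
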
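#' Construct a SimilarityMatrix
#'
#' @param values square numeric matrix; dimnames supply feature identifiers
#'   unless \code{featureIds} is given.
#' @param featureIds optional character vector of feature identifiers.
#' @param source provenance tag, one of \code{GO_BP, GO_MF, PPI_NG, PPI_JA,
#'   PPI_FS, PPI_SC, PE, SP, MI, CUSTOM}.
#' @param validate set to \code{FALSE} to skip invariant checking (used
#'   internally when the invariants are guaranteed by construction).
#' @return A \linkS4class{SimilarityMatrix}.
#' @export
SimilarityMatrix <- function(values, featureIds = rownames(values),
                             source = "CUSTOM", validate = TRUE) {
  values <- as.matrix(values)
  if (is.null(featureIds))
    featureIds <- sprintf("F%04d", seq_len(nrow(values)))
  dimnames(values) <- list(featureIds, featureIds)
  obj <- new("SimilarityMatrix", values = values, source = source)
  if (validate) validObject(obj)
  obj
}

#' @describeIn SimilarityMatrix feature identifiers.
#' @param x a \code{SimilarityMatrix}.
#' @export
setMethod("featureIds", "SimilarityMatrix", function(x) rownames(x@values))

#' Similarity values and provenance
#'
#' @param x a \linkS4class{SimilarityMatrix}.
#' @return \code{similarityValues}: the numeric matrix;
#'   \code{similaritySource}: the provenance tag.
#' @export
similarityValues <- function(x) x@values

#' @rdname similarityValues
#' @export
similaritySource <- function(x) x@source

#' Check the similarity-matrix invariants
#'
#' A valid similarity matrix is square, symmetric within \code{tol}, has
#' all entries in \eqn{[0,1]} and an exactly unit diagonal. Each violated
#' invariant is reported with the first offending entry.
#'
#' @param S a \linkS4class{SimilarityMatrix} or a plain numeric matrix.
#' @param tol symmetry tolerance.
#' @return Character vector of violation descriptions; empty when valid.
#' @examples
#' validateSimilarity(diag(5))                       # character(0)
#' m <- diag(2); m[1, 2] <- 0.4; m[2, 1] <- 0.6
#' validateSimilarity(m)                             # asymmetry at (1,2)
#' @export
validateSimilarity <- function(S, tol = 1e-10) {
  v <- if (is(S, "SimilarityMatrix")) S@values else as.matrix(S)
  if (nrow(v) != ncol(v)) stop("similarity matrix must be square")
  msgs <- character(0)
  asym <- abs(v - t(v))
  if (any(asym > tol)) {
    ij <- sort(which(asym > tol, arr.ind = TRUE)[1L, ])  # report as (i,j), i<j
    msgs <- c(msgs, sprintf("asymmetry at (%d,%d): %g vs %g",
                            ij[1L], ij[2L], v[ij[1L], ij[2L]],
                            v[ij[2L], ij[1L]]))
  }
  oob <- v < -tol | v > 1 + tol
  if (any(oob)) {
    ij <- which(oob, arr.ind = TRUE)[1L, ]
    msgs <- c(msgs, sprintf("entry (%d,%d) = %g outside [0,1]",
                            ij[1L], ij[2L], v[ij[1L], ij[2L]]))
  }
  d <- diag(v)
  if (any(d != 1)) {
    i <- which(d != 1)[1L]
    msgs <- c(msgs, sprintf("diagonal != 1 at (%d,%d): %g", i, i, d[i]))
  }
  msgs
}

#' Read / write a similarity matrix as headered TSV
#'
#' The on-disk format is a dense tab-delimited table with feature
#' identifiers as both row and column labels; the provenance tag is stored
#' in a \code{# source:} comment on the first line.
#'
#' @param path file path.
#' @return \code{readSimilarity}: a \linkS4class{SimilarityMatrix}.
#' @export
readSimilarity <- function(path) {
  first <- readLines(path, n = 1L)
  source <- "CUSTOM"
  skip <- 0L
  if (startsWith(first, "# source:")) {
    source <- trimws(sub("# source:", "", first, fixed = TRUE))
    skip <- 1L
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                           skip = skip, check.names = FALSE)
  SimilarityMatrix(as.matrix(tab), source = source)
}

#' @rdname readSimilarity
#' @param S a \linkS4class{SimilarityMatrix}.
#' @export
writeSimilarity <- function(S, path) {
  stopifnot(is(S, "SimilarityMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# source: %s", S@source), con)
  df <- data.frame(feature_id = featureIds(S), S@values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("show", "SimilarityMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v)]
  cat(sprintf("SimilarityMatrix [%s]: %d features, off-diagonal mean %.3f\n",
              object@source, nrow(v),
              if (length(off)) mean(off) else NA_real_))
})
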
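#' Construct a RankedList
#'
#' @param features character vector of feature identifiers ordered from most
#'   (position 1) to least important.
#' @return A \linkS4class{RankedList}.
#' @export
RankedList <- function(features) new("RankedList", features = as.character(features))

#' @describeIn RankedList the ordered feature identifiers.
#' @param x a \code{RankedList}.
#' @export
setMethod("featureIds", "RankedList", function(x) x@features)

#' Rank function of a ranked list
#'
#' @param x a \linkS4class{RankedList}.
#' @return Named integer vector: \code{ranks(x)[f]} is the 1-based position
#'   \eqn{\tau(f)} of feature \code{f} (1 = most important).
#' @export
ranks <- function(x) {
  stopifnot(is(x, "RankedList"))
  stats::setNames(seq_along(x@features), x@features)
}

#' Top of a ranked list
#'
#' @param x a \linkS4class{RankedList}.
#' @param k number of leading features.
#' @return Character vector of the first \code{k} feature identifiers.
#' @export
topFeatures <- function(x, k) utils::head(x@features, k)

#' Read / write ranked lists as two-column TSV (rank, feature_id)
#'
#' @param path file path.
#' @return \code{readRankedList}: a \linkS4class{RankedList}.
#' @export
readRankedList <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  RankedList(tab$feature_id[order(tab$rank)])
}

#' @rdname readRankedList
#' @param x a \linkS4class{RankedList}.
#' @export
writeRankedList <- function(x, path) {
  stopifnot(is(x, "RankedList"))
  utils::write.table(
    data.frame(rank = seq_along(x@features), feature_id = x@features),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("show", "RankedList", function(object) {
  cat(sprintf("RankedList of %d features; top: %s\n",
              length(object@features),
              paste(utils::head(object@features, 5L), collapse = ", ")))
})
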
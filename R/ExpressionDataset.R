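#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, samples in rows and features in columns
#'   (the orientation used throughout the method: each row is one subject's
#'   expression vector).
#' @param labels numeric/integer vector of length \code{nrow(values)} with
#'   values in \{-1, +1\}, or a vector of two class strings which are mapped
#'   to -1/+1 (see [readExpression()] for the mapping convention).
#' @param sampleIds,featureIds identifier vectors; default to the dimnames
#'   of \code{values}.
#' @return A validated \linkS4class{ExpressionDataset}.
#' @examples
#' x <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("f", 1:4)))
#' d <- ExpressionDataset(x, c(-1, 1, 1))
#' exprValues(d)[1:2, 1:2]
#' @export
ExpressionDataset <- function(values, labels,
                              sampleIds = rownames(values),
                              featureIds = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sampleIds)) sampleIds <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(featureIds)) featureIds <- sprintf("F%04d", seq_len(ncol(values)))
  if (length(labels) != nrow(values))
    stop("one label per sample (row) is required")
  labels <- .coerceLabels(labels, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = t(values)),
    colData = S4Vectors::DataFrame(label = labels, row.names = sampleIds))
  rownames(se) <- featureIds
  new("ExpressionDataset", se)
}

# Map labels onto -1/+1. Numeric labels must already be -1/+1; two class
# strings are mapped by lexicographic order (first -> -1), and the mapping
# is announced so a sign flip of W can never pass silently.
.coerceLabels <- function(labels, sampleIds, mapping = NULL) {
  if (anyNA(labels)) {
    bad <- sampleIds[is.na(labels)]
    stop(sprintf("missing label for sample(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  if (is.numeric(labels)) {
    if (!all(labels %in% c(-1, 1)))
      stop("numeric labels must be coded -1/+1", call. = FALSE)
    return(as.numeric(labels))
  }
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    stop(sprintf("expected exactly two classes, found: %s",
                 paste(lev, collapse = ", ")), call. = FALSE)
  if (is.null(mapping)) {
    mapping <- c(-1, 1)
    names(mapping) <- lev
    .msg("mapping class '%s' -> -1, class '%s' -> +1", lev[1L], lev[2L])
  } else {
    if (!setequal(names(mapping), lev) || !setequal(mapping, c(-1, 1)))
      stop("explicit label mapping must assign -1 and +1 to the two classes",
           call. = FALSE)
  }
  as.numeric(mapping[labels])
}

#' @describeIn ExpressionDataset feature identifiers (matrix columns).
#' @param x an \code{ExpressionDataset}.
#' @export
setMethod("featureIds", "ExpressionDataset", function(x) rownames(x))

#' Expression values as a sample-by-feature matrix
#'
#' @param x an \linkS4class{ExpressionDataset}.
#' @return Numeric matrix, samples in rows, features in columns.
#' @export
exprValues <- function(x) t(SummarizedExperiment::assay(x, "exprs"))

#' Sample class labels (-1/+1)
#'
#' @param x an \linkS4class{ExpressionDataset}.
#' @return Numeric vector named by sample identifier.
#' @export
sampleLabels <- function(x) {
  y <- x$label
  names(y) <- colnames(x)
  y
}

#' Read an expression table with class labels
#'
#' Expects a tab- or comma-delimited table with samples in rows and features
#' in columns: header row of feature identifiers, first column of sample
#' identifiers. Labels are taken from the column named \code{labelColumn}
#' if present, otherwise from a two-column sidecar file
#' (\code{sample_id<TAB>label}). Class strings are mapped to -1/+1 by
#' lexicographic order (first class to -1) unless \code{labelMapping} gives
#' an explicit named vector such as \code{c(neg = -1, pos = 1)}.
#'
#' @param path path to the expression table (.tsv/.csv, extension decides
#'   the delimiter; anything not ending in .csv is read as tab-delimited).
#' @param labelColumn name of the label column inside the table.
#' @param labelsPath optional sidecar label file.
#' @param labelMapping optional explicit class-to-sign mapping.
#' @param exclude optional character vector (or path to a one-column file)
#'   of feature identifiers to drop before validation.
#' @return An \linkS4class{ExpressionDataset}.
#' @export
readExpression <- function(path, labelColumn = "label", labelsPath = NULL,
                           labelMapping = NULL, exclude = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  sampleIds <- rownames(tab)
  if (labelColumn %in% colnames(tab)) {
    labels <- tab[[labelColumn]]
    tab[[labelColumn]] <- NULL
  } else if (!is.null(labelsPath)) {
    lt <- utils::read.table(labelsPath, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    labels <- lt[[2L]][match(sampleIds, lt[[1L]])]
  } else {
    stop(sprintf("no label column '%s' and no sidecar label file given",
                 labelColumn))
  }
  vals <- as.matrix(tab)
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab, is.numeric, TRUE))
    stop(sprintf("non-numeric expression values in column(s): %s",
                 paste(utils::head(colnames(tab)[bad], 5L), collapse = ", ")))
  }
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing expression value at sample '%s', feature '%s'",
                 sampleIds[idx[1L]], colnames(vals)[idx[2L]]))
  }
  if (!is.null(exclude)) {
    if (length(exclude) == 1L && file.exists(exclude))
      exclude <- utils::read.table(exclude, header = FALSE,
                                   stringsAsFactors = FALSE)[[1L]]
    drop <- colnames(vals) %in% exclude
    if (any(drop)) .msg("excluding %d feature(s) by id list", sum(drop))
    vals <- vals[, !drop, drop = FALSE]
  }
  labels <- .coerceLabels(labels, sampleIds, mapping = labelMapping)
  ExpressionDataset(vals, labels, sampleIds = sampleIds)
}

#' Write an expression table (round-trips with [readExpression()])
#'
#' @param x an \linkS4class{ExpressionDataset}.
#' @param path output path; tab-delimited unless it ends in .csv.
#' @param labelColumn name under which the -1/+1 labels are stored.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path, labelColumn = "label") {
  stopifnot(is(x, "ExpressionDataset"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- data.frame(sample_id = colnames(x),
                    label = unname(sampleLabels(x)),
                    exprValues(x), check.names = FALSE)
  names(out)[2L] <- labelColumn
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a dataset and a similarity matrix to their shared features
#'
#' Both objects are restricted to the intersection of their feature
#' identifiers, kept in the dataset's feature order; the number of features
#' dropped from each side is reported.
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param S a \linkS4class{SimilarityMatrix}.
#' @return List with elements \code{dataset} and \code{similarity}.
#' @export
alignFeatures <- function(dataset, S) {
  fd <- featureIds(dataset)
  fs <- featureIds(S)
  shared <- fd[fd %in% fs]
  if (length(shared) < 2L)
    stop(sprintf("only %d shared feature id(s); need at least 2",
                 length(shared)))
  if (length(shared) < length(fd) || length(shared) < length(fs))
    .msg("aligning features: dropped %d from dataset, %d from similarity",
         length(fd) - length(shared), length(fs) - length(shared))
  ds <- dataset[shared, ]
  sv <- similarityValues(S)[shared, shared]
  list(dataset = ds,
       similarity = SimilarityMatrix(sv, source = similaritySource(S)))
}

setMethod("show", "ExpressionDataset", function(object) {
  y <- sampleLabels(object)
  cat(sprintf(
    "ExpressionDataset: %d samples x %d features (%d '+1', %d '-1')\n",
    ncol(object), nrow(object), sum(y > 0), sum(y < 0)))
})
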
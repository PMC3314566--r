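#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.SIM_SOURCES <- c("GO_BP", "GO_MF", "PPI_NG", "PPI_JA", "PPI_FS", "PPI_SC",
                  "PE", "SP", "MI", "CUSTOM")

#' ExpressionDataset: labelled expression matrix
#'
#' A \linkS4class{SummarizedExperiment} holding one assay \code{"exprs"}
#' (features in rows, samples in columns, normalized log-scale expression)
#' and a binary class label per sample in \code{colData(x)$label}, coded
#' \eqn{-1/+1}. Algorithms in this package work on the sample-by-feature
#' orientation returned by [exprValues()], where each row is one subject's
#' expression vector.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso [ExpressionDataset()], [readExpression()], [exprValues()],
#'   [sampleLabels()]
#' @exportClass ExpressionDataset
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msgs <- character(0)
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    return("assay 'exprs' is missing")
  v <- SummarizedExperiment::assay(object, "exprs")
  if (anyNA(v)) msgs <- c(msgs, "expression values contain missing entries")
  if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData column 'label' is missing")
  y <- object$label
  if (!all(y %in% c(-1, 1)))
    msgs <- c(msgs, "labels must be coded -1/+1")
  else if (length(unique(y)) < 2L)
    msgs <- c(msgs, "both classes must be present")
  fid <- rownames(object)
  if (is.null(fid) || anyDuplicated(fid))
    msgs <- c(msgs, "feature identifiers must be present and unique")
  if (length(msgs)) msgs else TRUE
})

#' SimilarityMatrix: feature-by-feature prior-knowledge similarity
#'
#' Symmetric matrix with entries in \eqn{[0,1]} and unit diagonal, tagged
#' with the provenance of the prior knowledge it encodes (GO semantic
#' similarity, interaction-network topology, expression dependency).
#'
#' @slot values numeric matrix with feature identifiers as dimnames.
#' @slot source one of \code{GO_BP, GO_MF, PPI_NG, PPI_JA, PPI_FS, PPI_SC,
#'   PE, SP, MI, CUSTOM}.
#' @seealso [SimilarityMatrix()], [validateSimilarity()], [buildEmbedding()]
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
         representation(values = "matrix", source = "character"))

setValidity("SimilarityMatrix", function(object) {
  msgs <- character(0)
  if (length(object@source) != 1L || !object@source %in% .SIM_SOURCES)
    msgs <- c(msgs, sprintf("source must be one of: %s",
                            paste(.SIM_SOURCES, collapse = ", ")))
  fid <- rownames(object@values)
  if (is.null(fid) || anyDuplicated(fid))
    msgs <- c(msgs, "feature identifiers must be present and unique")
  v <- validateSimilarity(object@values)
  if (length(v)) msgs <- c(msgs, v)
  if (length(msgs)) msgs else TRUE
})

#' RankedList: ordered biomarker list
#'
#' A permutation of feature identifiers, position 1 being the most important
#' feature. The implicit rank function \eqn{\tau} (feature to 1-based
#' position) is returned by [ranks()].
#'
#' @slot features character vector, an ordering of the feature universe.
#' @seealso [RankedList()], [rankFeatures()], [canberra()]
#' @exportClass RankedList
setClass("RankedList", representation(features = "character"))

setValidity("RankedList", function(object) {
  f <- object@features
  if (length(f) < 1L) return("ranked list is empty")
  if (anyDuplicated(f)) return("features must be a permutation (no duplicates)")
  if (anyNA(f) || any(f == "")) return("features must be non-missing ids")
  TRUE
})

#' StochasticEmbedding: row-stochastic feature-coding matrix
#'
#' The matrix \eqn{P = D^{-1}(I + \alpha(S - I))} built from a similarity
#' matrix \eqn{S} and mixing weight \eqn{\alpha \ge 0}, where \eqn{D} holds
#' the row sums of \eqn{I + \alpha(S - I)}. Row \eqn{P_i} is the code of
#' feature \eqn{i}; samples are mapped \eqn{x \mapsto Px} before
#' standardization. Per-feature standardization statistics computed by
#' [transformStandardize()] are stored alongside for reuse.
#'
#' @slot P numeric matrix with feature ids as dimnames; rows sum to 1.
#' @slot alpha non-negative scalar.
#' @slot standardization list with elements \code{mean} and \code{sd}
#'   (empty until data are transformed).
#' @seealso [buildEmbedding()], [transformStandardize()]
#' @exportClass StochasticEmbedding
setClass("StochasticEmbedding",
         representation(P = "matrix", alpha = "numeric",
                        standardization = "list"))

setValidity("StochasticEmbedding", function(object) {
  msgs <- character(0)
  P <- object@P
  if (nrow(P) != ncol(P)) return("P must be square")
  if (is.null(rownames(P))) msgs <- c(msgs, "P must carry feature ids")
  if (any(P < -1e-12)) msgs <- c(msgs, "P has negative entries")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-10))
    msgs <- c(msgs, "rows of P must sum to 1 within 1e-10")
  if (length(object@alpha) != 1L || object@alpha < 0)
    msgs <- c(msgs, "alpha must be a single non-negative number")
  if (length(msgs)) msgs else TRUE
})

#' EnsembleResult: bootstrap perceptron ensemble
#'
#' Per-split unit-norm weight vectors \eqn{w_t}, test accuracies \eqn{a_t},
#' epochs to convergence, the design matrix \eqn{Q} (\eqn{Q_{tm}=1} iff
#' sample \eqn{m} was in the training partition of split \eqn{t}), and the
#' averaged weight vector \eqn{W = \mathrm{AVE}(w_t)} used for feature
#' ranking.
#'
#' @slot weights numeric matrix, one unit-norm row per split.
#' @slot testAccuracies numeric vector in \eqn{[0,1]}.
#' @slot epochs integer vector, epochs executed per split.
#' @slot converged logical vector.
#' @slot designMatrix binary matrix, splits by samples.
#' @slot averagedWeights named numeric vector \eqn{W}.
#' @seealso [bootstrapEnsemble()], [oobAccuracy()], [rankFeatures()]
#' @exportClass EnsembleResult
setClass("EnsembleResult",
         representation(weights = "matrix", testAccuracies = "numeric",
                        epochs = "integer", converged = "logical",
                        designMatrix = "matrix",
                        averagedWeights = "numeric"))

setValidity("EnsembleResult", function(object) {
  msgs <- character(0)
  T <- nrow(object@weights)
  if (length(object@testAccuracies) != T || length(object@epochs) != T ||
      length(object@converged) != T || nrow(object@designMatrix) != T)
    msgs <- c(msgs, "per-split slots must all have one entry per split")
  nrm <- sqrt(rowSums(object@weights^2))
  if (any(object@converged & abs(nrm - 1) > 1e-10))
    msgs <- c(msgs, "converged weight vectors must have unit norm")
  ones <- rowSums(object@designMatrix)
  if (length(unique(ones)) > 1L)
    msgs <- c(msgs, "each design-matrix row must have the same number of ones")
  W <- colMeans(object@weights)
  if (max(abs(W - object@averagedWeights)) > 1e-8)
    msgs <- c(msgs, "averagedWeights must equal the mean of per-split weights")
  if (length(msgs)) msgs else TRUE
})

#' OntologyDag: rooted directed acyclic graph of ontology terms
#'
#' Child-to-parent adjacency over one ontology namespace with a single root.
#' Only subsumption (\code{is_a}) edges are represented.
#'
#' @slot terms character vector of term identifiers.
#' @slot parents named list mapping each term to its parent terms
#'   (\code{character(0)} for the root).
#' @slot root the root term identifier.
#' @seealso [OntologyDag()], [readOntology()], [termFrequencies()]
#' @exportClass OntologyDag
setClass("OntologyDag",
         representation(terms = "character", parents = "list",
                        root = "character"))

setValidity("OntologyDag", function(object) {
  msgs <- character(0)
  trm <- object@terms
  if (anyDuplicated(trm)) msgs <- c(msgs, "duplicate term identifiers")
  if (!setequal(names(object@parents), trm))
    msgs <- c(msgs, "parents must be named by exactly the term set")
  allp <- unique(unlist(object@parents, use.names = FALSE))
  if (length(allp) && !all(allp %in% trm))
    msgs <- c(msgs, "parent edges point to unknown terms")
  roots <- trm[vapply(object@parents[trm], length, 1L) == 0L]
  if (length(roots) != 1L || !identical(roots, object@root))
    msgs <- c(msgs, "exactly one parentless term (the root) is required")
  # acyclicity + reachability of the root via Kahn-style peeling
  if (!length(msgs)) {
    remaining <- setdiff(trm, object@root)
    reached <- object@root
    repeat {
      nxt <- remaining[vapply(object@parents[remaining],
                              function(p) all(p %in% reached), TRUE)]
      if (!length(nxt)) break
      reached <- c(reached, nxt)
      remaining <- setdiff(remaining, nxt)
    }
    if (length(remaining))
      msgs <- c(msgs, sprintf(
        "cyclic or root-unreachable terms: %s",
        paste(utils::head(remaining, 5L), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})
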
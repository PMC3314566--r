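# Stochastic feature-space embedding: P = D^{-1}(I + alpha (S - I)).

#' Build the stochastic embedding from a similarity matrix
#'
#' Forms \eqn{A = I + \alpha(S - I)} (unit diagonal, off-diagonal
#' \eqn{\alpha s_{ij} \ge 0}) and row-normalizes it through the diagonal
#' matrix \eqn{D} of row sums: \eqn{P = D^{-1}A}. \eqn{P} is row-stochastic
#' with non-negative entries and real eigenvalues in \eqn{[-1, 1]} (it is
#' diagonally similar to a symmetric matrix), so mapping samples through
#' \eqn{P} compresses them; \eqn{\alpha = 0} gives \eqn{P = I} and leaves
#' the feature space untouched. \eqn{\alpha} is a tuning parameter, chosen
#' in practice by [tuneAlpha()] for best list stability.
#'
#' @param S a \linkS4class{SimilarityMatrix} (validated).
#' @param alpha non-negative mixing weight.
#' @return A \linkS4class{StochasticEmbedding}.
#' @examples
#' S <- SimilarityMatrix(matrix(c(1, .5, .5, 1), 2,
#'                              dimnames = list(c("a", "b"), c("a", "b"))))
#' embeddingMatrix(buildEmbedding(S, 1))   # rows (2/3, 1/3), (1/3, 2/3)
#' @export
buildEmbedding <- function(S, alpha) {
  .assertScalarNumber(alpha, "alpha", lower = 0)
  v <- validateSimilarity(S)
  if (length(v))
    stop(sprintf("invalid similarity matrix: %s", paste(v, collapse = "; ")))
  sv <- similarityValues(S)
  A <- alpha * sv
  diag(A) <- 1
  rs <- rowSums(A)
  if (any(rs <= 0)) stop("zero row sum in I + alpha(S - I)")  # defensive
  P <- A / rs
  new("StochasticEmbedding", P = P, alpha = alpha,
      standardization = list())
}

#' @describeIn buildEmbedding the matrix \eqn{P}.
#' @param emb a \linkS4class{StochasticEmbedding}.
#' @export
embeddingMatrix <- function(emb) emb@P

#' @describeIn buildEmbedding the mixing weight \eqn{\alpha}.
#' @export
embeddingAlpha <- function(emb) emb@alpha

#' @describeIn buildEmbedding feature identifiers of the embedding.
#' @param x a \code{StochasticEmbedding}.
#' @export
setMethod("featureIds", "StochasticEmbedding", function(x) rownames(x@P))

#' Map samples through the embedding and standardize features
#'
#' Each sample vector \eqn{x} is replaced by \eqn{Px}; every transformed
#' feature is then centered and scaled to unit standard deviation across
#' all samples. The statistics are computed once on the full dataset,
#' before any train/test splitting (the protocol implemented by the
#' ensemble); pass precomputed \code{stats} (e.g. from training folds only)
#' for a strict no-leakage variant. Zero-variance transformed features are
#' set to all-zeros with a warning.
#'
#' @param dataset an \linkS4class{ExpressionDataset} whose features match
#'   the embedding.
#' @param emb a \linkS4class{StochasticEmbedding}.
#' @param stats optional list with \code{mean} and \code{sd} vectors to
#'   apply instead of computing them from \code{dataset}.
#' @return The transformed, standardized \linkS4class{ExpressionDataset};
#'   the statistics used are stored in its metadata under
#'   \code{"standardization"} (see [standardizationStats()]).
#' @export
transformStandardize <- function(dataset, emb, stats = NULL) {
  fid <- featureIds(dataset)
  if (!identical(fid, featureIds(emb)))
    stop("feature identifiers of dataset and embedding do not match")
  X <- exprValues(dataset)
  Xt <- X %*% t(emb@P)
  if (is.null(stats)) {
    stats <- list(mean = colMeans(Xt), sd = .colSds(Xt))
  } else {
    if (length(stats$mean) != ncol(Xt) || length(stats$sd) != ncol(Xt))
      stop("standardization statistics do not match the feature count")
  }
  degenerate <- stats$sd < 1e-12
  if (any(degenerate))
    warning(sprintf("%d zero-variance transformed feature(s) set to 0",
                    sum(degenerate)))
  sd <- ifelse(degenerate, 1, stats$sd)
  Z <- sweep(sweep(Xt, 2L, stats$mean, "-"), 2L, sd, "/")
  Z[, degenerate] <- 0
  out <- ExpressionDataset(Z, unname(sampleLabels(dataset)),
                           sampleIds = rownames(X), featureIds = fid)
  S4Vectors::metadata(out)$standardization <- stats
  S4Vectors::metadata(out)$alpha <- emb@alpha
  out
}

#' Standardization statistics stored on a transformed dataset
#'
#' @param x an \linkS4class{ExpressionDataset} returned by
#'   [transformStandardize()].
#' @return List with \code{mean} and \code{sd}, or NULL.
#' @export
standardizationStats <- function(x) S4Vectors::metadata(x)$standardization

setMethod("show", "StochasticEmbedding", function(object) {
  cat(sprintf("StochasticEmbedding: %d features, alpha = %g\n",
              nrow(object@P), object@alpha))
})
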
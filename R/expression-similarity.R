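# Expression-dependency similarity across a compendium: absolute Pearson or
# Spearman correlation, and binned mutual information.

#' Correlation-based similarity matrix
#'
#' \eqn{s_{ij} = |\rho_{ij}|} with \eqn{\rho} the Pearson or Spearman
#' coefficient across compendium samples. The absolute value makes strong
#' anticorrelation count as similarity and keeps entries in \eqn{[0,1]} as
#' the downstream embedding requires. Constant features (undefined
#' correlation) get 0 off-diagonal.
#'
#' @param X numeric matrix, compendium samples in rows and features in
#'   columns (at least 3 samples), or an \linkS4class{ExpressionDataset}
#'   (labels ignored).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return A \linkS4class{SimilarityMatrix} tagged PE or SP.
#' @export
correlationSimilarity <- function(X, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is(X, "ExpressionDataset")) X <- exprValues(X)
  if (nrow(X) < 3L) stop("need at least 3 compendium samples")
  if (is.null(colnames(X))) colnames(X) <- sprintf("F%04d", seq_len(ncol(X)))
  nConst <- sum(.colSds(X) == 0)
  if (nConst > 0) .msg("%d constant feature(s): similarity set to 0", nConst)
  s <- abs(suppressWarnings(stats::cor(X, method = method)))
  s[is.na(s)] <- 0
  s <- pmin(s, 1)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  SimilarityMatrix(s, source = if (method == "pearson") "PE" else "SP")
}

#' Heuristic number of quantization intervals for mutual information
#'
#' Lower bound \eqn{MI_{low} = \lfloor 1 + \log_2 m \rfloor}, upper bound
#' \eqn{MI_{up} = \sqrt m}; the default interval count is the midpoint of
#' the two bounds rounded half up, clamped into
#' \eqn{[MI_{low}, \lfloor MI_{up} \rfloor]}. For a compendium of
#' \eqn{m = 1586} samples this gives \eqn{L = 25}.
#'
#' @param m number of compendium samples (at least 4).
#' @return Integer number of intervals \eqn{L}.
#' @examples
#' chooseBins(1586)   # 25
#' @export
chooseBins <- function(m) {
  .assertScalarNumber(m, "m", lower = 4)
  low <- floor(1 + log2(m))
  up <- sqrt(m)
  L <- .roundHalfUp((low + up) / 2)
  L <- max(min(L, floor(up)), low)
  as.integer(L)
}

# Per-feature quantization into L bins: equal-width over the observed range
# (default), or equal-frequency via average ranks.
.quantize <- function(x, L, equalFrequency = FALSE) {
  if (equalFrequency) {
    b <- ceiling(L * rank(x, ties.method = "average") / length(x))
    return(as.integer(pmin(pmax(b, 1), L)))
  }
  r <- range(x)
  if (r[1L] == r[2L]) return(rep(1L, length(x)))
  b <- floor((x - r[1L]) / (r[2L] - r[1L]) * L) + 1
  as.integer(pmin(b, L))
}

.entropyFromCounts <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Mutual-information similarity matrix
#'
#' Each feature is quantized into \code{L} intervals; mutual information is
#' computed from the \eqn{L \times L} joint histogram in nats and normalized
#' as \eqn{s_{ij} = MI_{ij} / \max(H_i, H_j)} with \eqn{H} the marginal
#' entropies, which bounds \eqn{s} in \eqn{[0,1]} with \eqn{s_{ii} = 1}.
#' Constant features (zero entropy) get 0 off-diagonal.
#'
#' @inheritParams correlationSimilarity
#' @param L number of quantization intervals (default [chooseBins()] on the
#'   sample count).
#' @param equalFrequency quantize into equal-frequency instead of
#'   equal-width bins.
#' @return A \linkS4class{SimilarityMatrix} tagged MI.
#' @export
mutualInformationSimilarity <- function(X, L = chooseBins(nrow(X)),
                                        equalFrequency = FALSE) {
  if (is(X, "ExpressionDataset")) X <- exprValues(X)
  if (L < 2L) stop("need at least 2 quantization intervals")
  if (is.null(colnames(X))) colnames(X) <- sprintf("F%04d", seq_len(ncol(X)))
  m <- nrow(X)
  n <- ncol(X)
  B <- vapply(seq_len(n), function(j) .quantize(X[, j], L, equalFrequency),
              integer(m))
  H <- vapply(seq_len(n), function(j) .entropyFromCounts(tabulate(B[, j], L)),
              0)
  s <- matrix(0, n, n, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(n)) {
    if (H[i] == 0) next
    for (j in i:n) {
      if (H[j] == 0) next
      joint <- tabulate(B[, i] + L * (B[, j] - 1L), nbins = L * L)
      mi <- H[i] + H[j] - .entropyFromCounts(joint)
      s[i, j] <- s[j, i] <- mi / max(H[i], H[j])
    }
  }
  s <- pmin(pmax(s, 0), 1)
  diag(s) <- 1
  SimilarityMatrix(s, source = "MI")
}
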
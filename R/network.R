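# Topological similarity on protein-protein interaction networks:
# normalized geodesic (NG), Jaccard (JA), functional similarity (FS),
# hypergeometric common-neighborhood significance (SC), plus aggregation
# from protein-level scores to feature-level similarity.

#' Read an undirected interaction graph from a two-column edge list
#'
#' Self-loops and duplicate edges are dropped (with a reported count).
#'
#' @param path TSV edge list of protein identifiers (no header).
#' @return An \code{igraph} object (undirected, simple).
#' @export
readInteractionGraph <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(tab[, 1:2], directed = FALSE)
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  dropped <- igraph::ecount(g) - igraph::ecount(gs)
  if (dropped > 0)
    .msg("dropped %d duplicate/self-loop edge(s)", dropped)
  gs
}

#' Read a feature-to-protein mapping table
#'
#' @param path two-column TSV (feature_id, protein_id), multiple rows per
#'   feature.
#' @return Named list mapping features to protein identifier sets.
#' @export
readFeatureProteinMap <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  lapply(split(tab[[2L]], tab[[1L]]), unique)
}

.graphNames <- function(graph) {
  nm <- igraph::V(graph)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(graph))) else nm
}

.adjacency <- function(graph) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph, type = "both"))
  A[A > 1] <- 1
  diag(A) <- 0
  dimnames(A) <- list(.graphNames(graph), .graphNames(graph))
  A
}

#' Normalized geodesic similarity between proteins
#'
#' \eqn{s(p_i,p_j) = 1 - l(path(p_i,p_j)) / \max l(path)}, the shortest-path
#' length normalized by the largest shortest path among connected pairs
#' (the graph diameter). Pairs in different components get similarity 0;
#' self-similarity is 1.
#'
#' @param graph an undirected \code{igraph} object.
#' @return Symmetric numeric matrix over the graph's proteins.
#' @export
geodesicSimilarity <- function(graph) {
  d <- igraph::distances(graph)
  finite <- is.finite(d) & d > 0
  if (!any(finite)) {
    s <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  } else {
    dmax <- max(d[finite])
    s <- 1 - d / dmax
    s[!is.finite(d)] <- 0
  }
  diag(s) <- 1
  dimnames(s) <- list(.graphNames(graph), .graphNames(graph))
  s
}

#' Jaccard neighborhood similarity between proteins
#'
#' \eqn{|N(p_i) \cap N(p_j)| / |N(p_i) \cup N(p_j)|}; 0 when the union is
#' empty; self-similarity forced to 1. Neighborhoods are pure graph
#' neighbors (a node is not its own neighbor).
#'
#' @inheritParams geodesicSimilarity
#' @return Symmetric numeric matrix.
#' @export
jaccardSimilarity <- function(graph) {
  A <- .adjacency(graph)
  common <- A %*% A
  deg <- rowSums(A)
  uni <- outer(deg, deg, "+") - common
  s <- ifelse(uni > 0, common / uni, 0)
  diag(s) <- 1
  s
}

# FS denominators read as |N(pa)\N(pb)| + 2|Ncap| + lambda_ab with
# lambda_ab = max(0, n_avg - |N(pa)\N(pb)| - 2|Ncap|): lambda pads the
# denominator up to the network's average neighbor count, penalizing pairs
# where a protein has too few neighbors. Isolated here for easy revision.
.fsFactor <- function(degA, common, navg) {
  setdiffA <- degA - common           # |N(pa) \ N(pb)|
  lam <- pmax(0, navg - setdiffA - 2 * common)
  den <- setdiffA + 2 * common + lam
  ifelse(den > 0, 2 * common / den, 0)
}

#' FS-Weight-style functional similarity between proteins
#'
#' Product of two directional common-neighborhood fractions, each penalized
#' by a term that pads the denominator up to the average neighbor count
#' \eqn{n_{avg}} of the network, so proteins with too few neighbors cannot
#' reach high similarity. Pairs with no common neighbor score 0;
#' self-similarity is forced to 1.
#'
#' @inheritParams geodesicSimilarity
#' @return Symmetric numeric matrix.
#' @export
fsSimilarity <- function(graph) {
  A <- .adjacency(graph)
  common <- A %*% A
  deg <- rowSums(A)
  navg <- mean(deg)
  degI <- matrix(deg, nrow(A), ncol(A))
  s <- .fsFactor(degI, common, navg) * .fsFactor(t(degI), common, navg)
  s[common == 0] <- 0
  diag(s) <- 1
  (s + t(s)) / 2
}

#' Hypergeometric common-neighborhood significance (raw scores)
#'
#' \eqn{-\log_{10}} of the probability of observing at least the given
#' number of common neighbors by chance, under the hypergeometric
#' distribution with population size \eqn{N = |V|}:
#' \deqn{prob = \sum_{k=|N_\cap|}^{\min(|N_i|,|N_j|)}
#'   \binom{|N_i|}{k}\binom{N-|N_i|}{|N_j|-k} \big/ \binom{N}{|N_j|}}
#' The tail sum is evaluated in log space (via \code{phyper}) to avoid
#' underflow; no common neighbors gives tail probability 1 and raw score 0.
#' Raw scores are unbounded above and must be passed through
#' [rescaleUnit()] before use as a similarity.
#'
#' @inheritParams geodesicSimilarity
#' @return Symmetric non-negative matrix of raw \eqn{-\log_{10}} scores
#'   (diagonal included, also raw).
#' @export
scSimilarityRaw <- function(graph) {
  A <- .adjacency(graph)
  n <- nrow(A)
  common <- A %*% A
  deg <- rowSums(A)
  degI <- matrix(deg, n, n)
  logTail <- stats::phyper(as.vector(common) - 1, as.vector(degI),
                           n - as.vector(degI), as.vector(t(degI)),
                           lower.tail = FALSE, log.p = TRUE)
  raw <- matrix(-logTail / log(10), n, n, dimnames = dimnames(A))
  raw[common == 0] <- 0
  raw <- pmax(raw, 0)
  (raw + t(raw)) / 2
}

#' Rescale non-negative raw scores to [0,1]
#'
#' Divides by the maximum finite off-diagonal raw score (a monotone map),
#' then sets self-similarity to 1. An all-zero table is returned unchanged
#' apart from the unit diagonal.
#'
#' @param raw symmetric non-negative numeric matrix.
#' @return Matrix with entries in \eqn{[0,1]} and unit diagonal.
#' @export
rescaleUnit <- function(raw) {
  s <- raw
  off <- s[row(s) != col(s)]
  mx <- suppressWarnings(max(off[is.finite(off)]))
  if (is.finite(mx) && mx > 0) {
    s[!is.finite(s)] <- mx
    s <- s / mx
  }
  s <- pmin(s, 1)
  diag(s) <- 1
  s
}

#' Aggregate protein-level similarity to feature-level
#'
#' Each feature maps to a set of proteins; the feature-level similarity is
#' the symmetrized best-match average of the protein-level scores:
#' \deqn{s_{ij} = \frac12\Big[\frac{1}{|P_i|}\sum_{p \in P_i}\max_{q \in P_j}
#'   s(p,q) + \frac{1}{|P_j|}\sum_{q \in P_j}\max_{p \in P_i} s(q,p)\Big]}
#' Features mapping to no protein present in the score table get 0
#' off-diagonal; the diagonal is forced to 1.
#'
#' @param proteinSims symmetric protein-by-protein score matrix in [0,1]
#'   with protein identifiers as dimnames.
#' @param mapping named list, feature to protein identifier set.
#' @param featureIds features to include, in matrix order.
#' @param source provenance tag (\code{"PPI_NG"}, \code{"PPI_JA"},
#'   \code{"PPI_FS"} or \code{"PPI_SC"}).
#' @return A \linkS4class{SimilarityMatrix}.
#' @export
aggregateToFeatures <- function(proteinSims, mapping, featureIds,
                                source = "PPI_NG") {
  prot <- rownames(proteinSims)
  sets <- lapply(featureIds, function(f) {
    ps <- mapping[[f]]
    if (is.null(ps)) character(0) else ps[ps %in% prot]
  })
  nDroppedProt <- sum(lengths(lapply(featureIds, function(f) {
    ps <- mapping[[f]]
    if (is.null(ps)) character(0) else ps[!ps %in% prot]
  })))
  if (nDroppedProt > 0)
    .msg("dropped %d mapped protein(s) absent from the graph", nDroppedProt)
  mapped <- lengths(sets) > 0L
  if (any(!mapped))
    .msg("%d of %d features map to no protein (similarity 0)",
         sum(!mapped), length(featureIds))

  n <- length(featureIds)
  if (all(lengths(sets) == 1L)) {            # fast path: one protein each
    idx <- unlist(sets)
    S <- proteinSims[idx, idx, drop = FALSE]
  } else {
    S <- matrix(0, n, n)
    for (a in seq_len(n)) {
      if (!mapped[a]) next
      for (b in a:n) {
        if (!mapped[b]) next
        sub <- proteinSims[sets[[a]], sets[[b]], drop = FALSE]
        S[a, b] <- S[b, a] <- .bmaFromMatrix(sub)
      }
    }
  }
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  dimnames(S) <- list(featureIds, featureIds)
  SimilarityMatrix(S, source = source)
}

#' Feature-level similarity matrix from an interaction graph
#'
#' Convenience wrapper chaining one of the four topological measures,
#' unit rescaling for the unbounded SC scores, and [aggregateToFeatures()].
#'
#' @param graph undirected \code{igraph}.
#' @param mapping feature-to-protein mapping list.
#' @param featureIds features to include.
#' @param measure one of \code{"geodesic"}, \code{"jaccard"}, \code{"fs"},
#'   \code{"sc"}.
#' @return A \linkS4class{SimilarityMatrix} tagged PPI_NG/JA/FS/SC.
#' @export
networkSimilarityMatrix <- function(graph, mapping, featureIds,
                                    measure = c("geodesic", "jaccard",
                                                "fs", "sc")) {
  measure <- match.arg(measure)
  ps <- switch(measure,
               geodesic = geodesicSimilarity(graph),
               jaccard = jaccardSimilarity(graph),
               fs = fsSimilarity(graph),
               sc = rescaleUnit(scSimilarityRaw(graph)))
  src <- switch(measure, geodesic = "PPI_NG", jaccard = "PPI_JA",
                fs = "PPI_FS", sc = "PPI_SC")
  aggregateToFeatures(ps, mapping, featureIds, source = src)
}
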
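# Seeded synthetic-data generators with block ground truth. The generators
# emulate the structure the method assumes: groups of co-regulated features
# (blocks) sharing a latent factor, a subset of blocks carrying the class
# signal, prior knowledge (similarity matrix, annotation DAG, interaction
# graph) aligned with the blocks, plus unstructured noise features.

#' Block design for the synthetic generators
#'
#' The default values define the package's standard study conditions:
#' 500 features (10 blocks of 40 plus 100 noise features), 120 samples with
#' balanced classes, 2 class-informative blocks, within-block correlation
#' 0.7 and a class mean shift of 1 standard deviation on the informative
#' latent factors.
#'
#' @param nFeatures,nSamples problem size.
#' @param nBlocks,blockSize correlated feature blocks
#'   (\code{nBlocks * blockSize + noiseFeatures == nFeatures}).
#' @param informativeBlocks indices of blocks whose latent factor carries
#'   the class signal.
#' @param withinCorrelation target pairwise correlation inside a block,
#'   in \eqn{[0, 1)}.
#' @param effectSize between-class mean shift on informative latent
#'   factors, in standard-deviation units.
#' @param noiseFeatures number of i.i.d. standard-normal features.
#' @param seed RNG seed; all generators derive their streams from it.
#' @return A list of class \code{"BlockDesign"}.
#' @export
blockDesign <- function(nFeatures = 500L, nSamples = 120L, nBlocks = 10L,
                        blockSize = 40L, informativeBlocks = 1:2,
                        withinCorrelation = 0.7, effectSize = 1.0,
                        noiseFeatures = nFeatures - nBlocks * blockSize,
                        seed = 1L) {
  if (nBlocks * blockSize + noiseFeatures != nFeatures)
    stop("nBlocks * blockSize + noiseFeatures must equal nFeatures")
  if (!all(informativeBlocks %in% seq_len(nBlocks)))
    stop("informativeBlocks must index existing blocks")
  if (withinCorrelation < 0 || withinCorrelation >= 1)
    stop("withinCorrelation must be in [0, 1)")
  if (nSamples < 4L) stop("need at least 4 samples")
  structure(list(nFeatures = as.integer(nFeatures),
                 nSamples = as.integer(nSamples),
                 nBlocks = as.integer(nBlocks),
                 blockSize = as.integer(blockSize),
                 informativeBlocks = as.integer(informativeBlocks),
                 withinCorrelation = withinCorrelation,
                 effectSize = effectSize,
                 noiseFeatures = as.integer(noiseFeatures),
                 seed = as.integer(seed)),
            class = "BlockDesign")
}

# feature ids and block membership implied by a design (0 = noise)
.designBlocks <- function(design) {
  block <- rep(c(seq_len(design$nBlocks), 0L),
               c(rep(design$blockSize, design$nBlocks),
                 design$noiseFeatures))
  ids <- character(design$nFeatures)
  inBlock <- block > 0L
  ids[inBlock] <- sprintf("B%02d_F%03d", block[inBlock],
                          sequence(rep(design$blockSize, design$nBlocks)))
  ids[!inBlock] <- sprintf("NOISE_F%03d", seq_len(design$noiseFeatures))
  stats::setNames(block, ids)
}

#' Generate block-correlated expression data with class-informative blocks
#'
#' Samples carry balanced -1/+1 labels. Features of block b share a latent
#' factor \eqn{z_b}: \eqn{x = \sqrt{\rho}\, z_b + \sqrt{1-\rho}\,\epsilon},
#' which gives pairwise within-block correlation approximately \eqn{\rho}.
#' Informative blocks draw \eqn{z_b \sim N(\delta y/2, 1)}, i.e. a
#' between-class mean shift of \eqn{\delta} on the factor; noise features
#' are i.i.d. standard normal. Deterministic under the design seed.
#'
#' @param design a [blockDesign()].
#' @return List with \code{dataset} (an \linkS4class{ExpressionDataset})
#'   and \code{truth} (named block-membership vector, 0 for noise, plus
#'   the informative feature identifiers).
#' @export
makeExpression <- function(design) {
  stopifnot(inherits(design, "BlockDesign"))
  blocks <- .designBlocks(design)
  M <- design$nSamples
  y <- rep_len(c(-1, 1), M)
  rho <- design$withinCorrelation
  .withSeed(design$seed, {
    X <- matrix(0, M, design$nFeatures,
                dimnames = list(sprintf("S%03d", seq_len(M)), names(blocks)))
    for (b in seq_len(design$nBlocks)) {
      z <- stats::rnorm(M)
      if (b %in% design$informativeBlocks)
        z <- z + design$effectSize * y / 2
      cols <- which(blocks == b)
      eps <- matrix(stats::rnorm(M * length(cols)), M)
      X[, cols] <- sqrt(rho) * z + sqrt(1 - rho) * eps
    }
    if (design$noiseFeatures > 0L) {
      cols <- which(blocks == 0L)
      X[, cols] <- stats::rnorm(M * length(cols))
    }
    list(dataset = ExpressionDataset(X, y),
         truth = list(
           blocks = blocks,
           informativeFeatures =
             names(blocks)[blocks %in% design$informativeBlocks]))
  })
}

#' Generate a block-structured similarity matrix with tunable fidelity
#'
#' Same-block pairs get similarity \code{sIn}, all other pairs \code{sOut},
#' the diagonal is 1. A fraction \code{1 - fidelity} of the off-diagonal
#' entries is then randomly permuted (symmetrically), modelling wrong prior
#' knowledge: \code{fidelity = 1} is the exact block prior,
#' \code{fidelity = 0} destroys the structure completely while preserving
#' the value distribution.
#'
#' @param design a [blockDesign()].
#' @param fidelity fraction of off-diagonal entries left intact.
#' @param sIn,sOut within-block and background similarity values.
#' @return A \linkS4class{SimilarityMatrix} (source CUSTOM).
#' @export
makeSimilarity <- function(design, fidelity = 1, sIn = 0.9, sOut = 0.05) {
  stopifnot(inherits(design, "BlockDesign"))
  if (fidelity < 0 || fidelity > 1) stop("fidelity must be in [0, 1]")
  blocks <- .designBlocks(design)
  same <- outer(blocks, blocks, "==") & outer(blocks > 0L, blocks > 0L, "&")
  S <- matrix(sOut, design$nFeatures, design$nFeatures,
              dimnames = list(names(blocks), names(blocks)))
  S[same] <- sIn
  if (fidelity < 1) {
    up <- which(upper.tri(S))
    nSwap <- round((1 - fidelity) * length(up))
    if (nSwap >= 2L) {
      S <- .withSeed(design$seed + 1000L, {
        pick <- sample(up, nSwap)
        S[pick] <- S[sample(pick)]
        S
      })
    }
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
  }
  diag(S) <- 1
  SimilarityMatrix(S, source = "CUSTOM")
}

#' Generate an annotation DAG aligned with the block structure
#'
#' Three-level ontology: a root, one term per block, and two sub-terms per
#' block term. Each block feature is annotated to one of its block's
#' sub-terms (alternating), and every fourth feature to both; noise
#' features stay unannotated. Within-block pairs therefore share an
#' informative ancestor (the block term) while cross-block pairs share
#' only the root, so the semantic similarity matrix built on this fixture
#' recovers high within-block and zero cross-block similarity.
#'
#' @param design a [blockDesign()].
#' @return List with \code{dag} (an \linkS4class{OntologyDag}) and
#'   \code{annotations} (named list, feature to terms).
#' @export
makeGoFixture <- function(design) {
  stopifnot(inherits(design, "BlockDesign"))
  blocks <- .designBlocks(design)
  root <- "GO:ROOT"
  blockTerm <- sprintf("GO:B%02d", seq_len(design$nBlocks))
  edges <- data.frame(child = blockTerm, parent = root)
  for (s in 1:2)
    edges <- rbind(edges, data.frame(child = sprintf("%s_S%d", blockTerm, s),
                                     parent = blockTerm))
  dag <- OntologyDag(edges)
  ann <- list()
  for (f in names(blocks)[blocks > 0L]) {
    b <- blocks[[f]]
    i <- as.integer(sub(".*_F", "", f))
    terms <- sprintf("GO:B%02d_S%d", b, (i %% 2L) + 1L)
    if (i %% 4L == 0L) terms <- sprintf("GO:B%02d_S%d", b, 1:2)
    ann[[f]] <- terms
  }
  list(dag = dag, annotations = ann)
}

#' Generate a modular interaction graph aligned with the block structure
#'
#' Stochastic block model with one protein per feature: within-block
#' protein pairs are wired with probability \code{pIn}, all other pairs
#' (including pairs involving noise proteins) with probability \code{pOut}.
#' The feature-to-protein mapping is one-to-one. Deterministic under the
#' design seed.
#'
#' @param design a [blockDesign()].
#' @param pIn,pOut within-block and background edge probabilities
#'   (\code{pIn > pOut}).
#' @return List with \code{graph} (an \code{igraph}) and \code{mapping}
#'   (feature to protein list).
#' @export
makePpiFixture <- function(design, pIn = 0.6, pOut = 0.02) {
  stopifnot(inherits(design, "BlockDesign"))
  if (pIn <= pOut) stop("pIn must exceed pOut")
  blocks <- .designBlocks(design)
  prot <- paste0("P_", names(blocks))
  n <- length(prot)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sameBlock <- blocks[idx[, 1L]] == blocks[idx[, 2L]] & blocks[idx[, 1L]] > 0L
  pEdge <- ifelse(sameBlock, pIn, pOut)
  keep <- .withSeed(design$seed + 2000L, stats::runif(nrow(idx)) < pEdge)
  g <- igraph::graph_from_data_frame(
    data.frame(from = prot[idx[keep, 1L]], to = prot[idx[keep, 2L]]),
    directed = FALSE,
    vertices = data.frame(name = prot))
  mapping <- stats::setNames(as.list(prot), names(blocks))
  list(graph = g, mapping = mapping)
}
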
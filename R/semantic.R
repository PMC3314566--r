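# GO-based semantic similarity: information content, Lin term similarity,
# Best-Match Average feature similarity.

#' Descendant-inclusive term frequencies in an annotation corpus
#'
#' The frequency of a term t is the number of direct (feature, term')
#' annotation pairs whose term' is t or one of its descendants -- i.e. every
#' direct annotation pair is propagated once to each ancestor of its term
#' (true-path rule). The root frequency therefore equals the total number of
#' direct annotation pairs.
#'
#' @param annotations named list mapping features to sets of directly
#'   annotated terms (see [readAnnotations()]).
#' @param dag an \linkS4class{OntologyDag}.
#' @return Named numeric vector of frequencies over all DAG terms.
#' @export
termFrequencies <- function(annotations, dag) {
  if (!length(annotations)) stop("empty annotation table")
  used <- unique(unlist(annotations, use.names = FALSE))
  unknown <- setdiff(used, dag@terms)
  if (length(unknown))
    stop(sprintf("annotation(s) to unknown term(s): %s",
                 paste(utils::head(unknown, 10L), collapse = ", ")))
  anc <- .ancestorSets(dag)
  freq <- stats::setNames(numeric(length(dag@terms)), dag@terms)
  for (ts in annotations) {
    ts <- unique(ts)
    for (t in ts) {
      a <- anc[[t]]
      freq[a] <- freq[a] + 1
    }
  }
  freq
}

#' Information content from term frequencies
#'
#' \eqn{IC(t) = -\log(freq(t)/freq(root))} in natural-log units. Terms with
#' zero corpus frequency get \code{NA} (no defined IC) and are excluded from
#' similarity computations. IC is 0 at the root and monotone non-decreasing
#' towards the leaves. The logarithm base is immaterial for the downstream
#' Lin similarity, which is a ratio of ICs.
#'
#' @param counts named frequency vector from [termFrequencies()].
#' @param dag the \linkS4class{OntologyDag} the counts were computed on.
#' @param base logarithm base (natural log by default).
#' @return Named numeric vector of IC values (NA where frequency is 0).
#' @export
informationContent <- function(counts, dag, base = exp(1)) {
  total <- counts[[dag@root]]
  if (!isTRUE(total > 0)) stop("root frequency must be positive")
  ic <- -log(counts / total, base = base)
  ic[counts == 0] <- NA_real_
  ic
}

#' Lin similarity between two ontology terms
#'
#' \eqn{2\,IC(MICA(t,u)) / (IC(t)+IC(u))}, where MICA is the common ancestor
#' with maximal IC (a term counts among its own ancestors). Returns 0 when
#' both terms carry zero information (the root-level degenerate case).
#'
#' @param t,u term identifiers with defined IC.
#' @param dag an \linkS4class{OntologyDag}.
#' @param ic named IC vector from [informationContent()].
#' @return Similarity in \eqn{[0,1]}.
#' @export
linSimilarity <- function(t, u, dag, ic) {
  for (x in c(t, u)) {
    if (!x %in% dag@terms) stop(sprintf("term '%s' absent from DAG", x))
    if (is.na(ic[[x]])) stop(sprintf("term '%s' has no defined IC", x))
  }
  anc <- .ancestorSets(dag)
  .linFromAncestors(anc[[t]], anc[[u]], ic[[t]], ic[[u]], ic)
}

.linFromAncestors <- function(ancT, ancU, icT, icU, ic) {
  denom <- icT + icU
  if (denom == 0) return(0)
  common <- intersect(ancT, ancU)
  mica <- suppressWarnings(max(ic[common], na.rm = TRUE))
  if (!is.finite(mica)) mica <- 0
  2 * mica / denom
}

#' Best-Match Average similarity between two term sets
#'
#' Symmetrized best-match average of Lin similarities:
#' \deqn{\frac12\Big[\frac{1}{|GO_i|}\sum_{t \in GO_i}\max_{u \in GO_j}
#'   Sim_{Lin}(t,u) + \frac{1}{|GO_j|}\sum_{u \in GO_j}\max_{t \in GO_i}
#'   Sim_{Lin}(u,t)\Big]}
#' Terms without defined IC are dropped first; if either set becomes empty
#' the similarity is undefined and \code{NA} is returned (the matrix builder
#' treats such features as unannotated).
#'
#' @param termsI,termsJ character vectors of term identifiers.
#' @param dag an \linkS4class{OntologyDag}.
#' @param ic named IC vector.
#' @return Similarity in \eqn{[0,1]}, or NA.
#' @export
bmaSimilarity <- function(termsI, termsJ, dag, ic) {
  termsI <- unique(termsI[!is.na(ic[termsI])])
  termsJ <- unique(termsJ[!is.na(ic[termsJ])])
  if (!length(termsI) || !length(termsJ)) return(NA_real_)
  L <- matrix(0, length(termsI), length(termsJ))
  anc <- .ancestorSets(dag)
  for (a in seq_along(termsI))
    for (b in seq_along(termsJ))
      L[a, b] <- .linFromAncestors(anc[[termsI[a]]], anc[[termsJ[b]]],
                                   ic[[termsI[a]]], ic[[termsJ[b]]], ic)
  .bmaFromMatrix(L)
}

.bmaFromMatrix <- function(L) {
  (mean(apply(L, 1L, max)) + mean(apply(L, 2L, max))) / 2
}

#' Semantic similarity matrix over a feature set
#'
#' Builds the feature-by-feature similarity matrix with entries equal to the
#' Best-Match Average of Lin similarities between the features' term sets.
#' Pairs involving an unannotated feature (no terms, or only terms without
#' defined IC) get similarity 0, leaving such features untransformed by the
#' downstream embedding; the diagonal is 1 by definition.
#'
#' @param annotations named list of direct annotations (feature -> terms).
#' @param dag an \linkS4class{OntologyDag} for one namespace.
#' @param featureIds features to include, in matrix order.
#' @param corpus annotation corpus used for term frequencies; defaults to
#'   \code{annotations} itself.
#' @param source provenance tag (\code{"GO_BP"} or \code{"GO_MF"}).
#' @return A \linkS4class{SimilarityMatrix}.
#' @export
semanticSimilarityMatrix <- function(annotations, dag, featureIds,
                                     corpus = annotations,
                                     source = "GO_BP") {
  counts <- termFrequencies(corpus, dag)
  ic <- informationContent(counts, dag)
  anc <- .ancestorSets(dag)

  termSets <- lapply(featureIds, function(f) {
    ts <- annotations[[f]]
    if (is.null(ts)) return(character(0))
    unique(ts[ts %in% dag@terms & !is.na(ic[ts])])
  })
  annotated <- lengths(termSets) > 0L
  if (any(!annotated))
    .msg("%d of %d features are unannotated (similarity 0)",
         sum(!annotated), length(featureIds))

  # de-duplicate identical term sets: BMA depends only on the set
  sig <- vapply(termSets, function(ts) paste(sort(ts), collapse = "\r"), "")
  usets <- termSets[!duplicated(sig)]
  usig <- sig[!duplicated(sig)]
  grp <- match(sig, usig)

  # Lin similarity between all terms in use, computed once
  terms <- unique(unlist(usets, use.names = FALSE))
  nt <- length(terms)
  L <- matrix(0, nt, nt, dimnames = list(terms, terms))
  if (nt) {
    for (a in seq_len(nt)) {
      L[a, a] <- if (ic[[terms[a]]] > 0) 1 else 0
      if (a < nt) for (b in (a + 1L):nt) {
        L[a, b] <- L[b, a] <- .linFromAncestors(
          anc[[terms[a]]], anc[[terms[b]]],
          ic[[terms[a]]], ic[[terms[b]]], ic)
      }
    }
  }

  nu <- length(usets)
  B <- matrix(0, nu, nu)
  for (a in seq_len(nu)) {
    if (length(usets[[a]]) == 0L) next
    B[a, a] <- .bmaFromMatrix(L[usets[[a]], usets[[a]], drop = FALSE])
    if (a < nu) for (b in (a + 1L):nu) {
      if (length(usets[[b]]) == 0L) next
      B[a, b] <- B[b, a] <-
        .bmaFromMatrix(L[usets[[a]], usets[[b]], drop = FALSE])
    }
  }

  S <- B[grp, grp, drop = FALSE]
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  dimnames(S) <- list(featureIds, featureIds)
  SimilarityMatrix(S, source = source)
}
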
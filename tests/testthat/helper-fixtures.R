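# Shared fixtures built in code: tiny ontologies, graphs and datasets with
# hand-checkable structure, plus brute-force oracles used across tests.

# DAG  root -> {a, c}, a -> b ; annotations: 1 feature to b, 1 to a, 2 to c.
# Hand ICs (pair-counting, natural log): IC(b)=log 4, IC(a)=log 2, IC(c)=log 2.
tinyDag <- function() {
  OntologyDag(data.frame(child = c("a", "c", "b"),
                         parent = c("root", "root", "a")))
}

tinyAnnotations <- function() {
  list(f1 = "b", f2 = "a", f3 = "c", f4 = "c")
}

# random rooted DAG over nTerms terms: each non-root term gets 1-2 parents
# among earlier terms (guarantees acyclicity and root reachability)
randomDag <- function(nTerms, seed) {
  set.seed(seed)
  terms <- c("root", sprintf("t%02d", seq_len(nTerms - 1L)))
  child <- character(0); parent <- character(0)
  for (i in 2:nTerms) {
    np <- sample(1:min(2L, i - 1L), 1L)
    ps <- sample(terms[seq_len(i - 1L)], np)
    child <- c(child, rep(terms[i], np))
    parent <- c(parent, ps)
  }
  OntologyDag(data.frame(child = child, parent = parent))
}

randomAnnotations <- function(dag, nFeatures, seed) {
  set.seed(seed)
  terms <- setdiff(dag@terms, dag@root)
  ann <- lapply(seq_len(nFeatures), function(i)
    sample(terms, sample(1:3, 1L)))
  names(ann) <- sprintf("g%02d", seq_len(nFeatures))
  ann
}

# brute-force descendant enumeration: freq(t) = #(feature, term') pairs
# with term' equal to t or a descendant of t
oracleTermFrequencies <- function(annotations, dag) {
  anc <- sapply(dag@terms, function(t) termAncestors(dag, t),
                simplify = FALSE)
  freq <- stats::setNames(numeric(length(dag@terms)), dag@terms)
  for (ts in annotations)
    for (t in unique(ts))
      for (a in dag@terms)
        if (a %in% anc[[t]]) freq[a] <- freq[a] + 1
  freq
}

# exhaustive-ancestor-search Lin oracle
oracleLin <- function(t, u, dag, ic) {
  common <- intersect(termAncestors(dag, t), termAncestors(dag, u))
  mica <- max(c(0, ic[common][!is.na(ic[common])]))
  den <- ic[[t]] + ic[[u]]
  if (den == 0) 0 else 2 * mica / den
}

# exhaustive best-match double loop
oracleBma <- function(ti, tj, dag, ic) {
  ti <- ti[!is.na(ic[ti])]; tj <- tj[!is.na(ic[tj])]
  m1 <- mean(sapply(ti, function(t) max(sapply(tj, function(u)
    oracleLin(t, u, dag, ic)))))
  m2 <- mean(sapply(tj, function(u) max(sapply(ti, function(t)
    oracleLin(u, t, dag, ic)))))
  (m1 + m2) / 2
}

# direct choose()-based hypergeometric tail (independent of phyper)
oracleScTail <- function(nPop, degI, degJ, common) {
  ks <- common:min(degI, degJ)
  sum(choose(degI, ks) * choose(nPop - degI, degJ - ks)) /
    choose(nPop, degJ)
}

# small labelled expression matrix with separable classes
separableDataset <- function(M = 20, N = 10, gap = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(-1, 1), length.out = M)
  X <- matrix(rnorm(M * N), M, N)
  X[, 1] <- X[, 1] + gap * y
  colnames(X) <- sprintf("f%02d", seq_len(N))
  rownames(X) <- sprintf("s%02d", seq_len(M))
  ExpressionDataset(X, y)
}

# enumerate all permutations of 1..n (small n)
allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPermutations(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

# small igraph from an edge character matrix
edgeGraph <- function(..., vertices = NULL) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  df <- data.frame(from = e[, 1], to = e[, 2])
  if (is.null(vertices)) igraph::graph_from_data_frame(df, directed = FALSE)
  else igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = data.frame(name = vertices))
}

randomGraph <- function(n, p, seed) {
  set.seed(seed)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < p
  nm <- sprintf("p%02d", seq_len(n))
  igraph::graph_from_data_frame(
    data.frame(from = nm[idx[keep, 1]], to = nm[idx[keep, 2]]),
    directed = FALSE, vertices = data.frame(name = nm))
}

smallDesign <- function(seed = 5, ...) {
  args <- list(nFeatures = 60L, nSamples = 40L, nBlocks = 4L,
               blockSize = 10L, informativeBlocks = 1:2,
               noiseFeatures = 20L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(blockDesign, args)
}
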
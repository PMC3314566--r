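# Ranked-list stability: Canberra distance, its expected-value
# normalization, top-k sublist variants, multi-list protocols, union-list
# curves, and stability-driven tuning of the embedding weight alpha.

# shared environment caching empirical top-k normalizers across calls
.topkNormCache <- new.env(parent = emptyenv())

.canberraRanks <- function(r1, r2) sum(abs(r1 - r2) / (r1 + r2))

.alignedRanks <- function(t1, t2) {
  r1 <- ranks(t1)
  r2 <- ranks(t2)
  if (length(r1) != length(r2) || !all(names(r1) %in% names(r2)))
    stop("ranked lists must cover the same feature universe")
  list(r1 = r1, r2 = r2[names(r1)])
}

#' @describeIn canberra Canberra distance
#'   \eqn{\sum_i |\tau_1(i)-\tau_2(i)| / (\tau_1(i)+\tau_2(i))} between two
#'   complete ranked lists over the same features. Rank disagreements near
#'   the top of the lists weigh more than the same displacement near the
#'   bottom.
#' @export
setMethod("canberra", signature("RankedList", "RankedList"), function(t1, t2) {
  a <- .alignedRanks(t1, t2)
  .canberraRanks(a$r1, a$r2)
})

#' @describeIn canberra convenience method coercing character vectors of
#'   ordered features.
#' @export
setMethod("canberra", signature("ANY", "ANY"), function(t1, t2) {
  canberra(RankedList(t1), RankedList(t2))
})

#' Expected Canberra distance between random ranked lists
#'
#' Asymptotic expectation of the Canberra distance between two independent
#' uniform-random permutations of \eqn{p} items:
#' \eqn{(\log 4 - 1)\,p + \log 4 - 2} (natural log). Used as the
#' normalizer for complete lists; accurate for large \eqn{p} (for very
#' small \eqn{p} the exact permutation average differs noticeably).
#'
#' @param p list length (at least 2).
#' @return Numeric scalar.
#' @export
expectedCanberra <- function(p) {
  .assertScalarNumber(p, "p", lower = 2)
  (log(4) - 1) * p + log(4) - 2
}

#' Normalized Canberra distance between complete ranked lists
#'
#' [canberra()] divided by [expectedCanberra()] of the list length:
#' 0 for identical lists (maximal stability), approximately 1 for
#' independently random lists, bounded by about 1.4 (maximal instability,
#' approached by reversed lists).
#'
#' @inheritParams canberra
#' @return Non-negative numeric scalar.
#' @export
normalizedCanberra <- function(t1, t2) {
  if (!is(t1, "RankedList")) t1 <- RankedList(t1)
  if (!is(t2, "RankedList")) t2 <- RankedList(t2)
  canberra(t1, t2) / expectedCanberra(length(featureIds(t1)))
}

# Canberra distance on top-k sublists: features in either top-k
# participate; a feature missing from one list's top-k gets rank k+1 there.
.topkRaw <- function(r1, r2, k) {
  u <- union(names(r1)[r1 <= k], names(r2)[r2 <= k])
  a <- pmin(r1[u], k + 1)
  b <- pmin(r2[u], k + 1)
  .canberraRanks(a, b)
}

# Empirical expected top-k distance for random permutations of length p,
# estimated once per (p, k) from seeded random pairs and cached.
.topkNorm <- function(p, k, nPairs = 100L) {
  key <- sprintf("%d:%d:%d", p, k, nPairs)
  if (!is.null(.topkNormCache[[key]])) return(.topkNormCache[[key]])
  val <- .withSeed(190100L + k, {
    mean(vapply(seq_len(nPairs), function(i) {
      r1 <- stats::setNames(sample.int(p), seq_len(p))
      r2 <- stats::setNames(sample.int(p), seq_len(p))
      .topkRaw(r1, r2, k)
    }, 0))
  })
  .topkNormCache[[key]] <- val
  val
}

#' Normalized Canberra distance between top-k sublists
#'
#' The Canberra sum runs over the union of the two top-k sets; a feature
#' absent from one list's top k is assigned rank \eqn{k+1} there. The raw
#' distance is normalized by its empirical expectation for random lists of
#' the same \eqn{(p, k)}, estimated once from seeded random permutation
#' pairs and cached. At \eqn{k = p} this reduces exactly to
#' [normalizedCanberra()] (and uses the analytic normalizer).
#'
#' @inheritParams canberra
#' @param k sublist length, \eqn{1 \le k \le p}.
#' @return Non-negative numeric scalar.
#' @export
topkCanberra <- function(t1, t2, k) {
  if (!is(t1, "RankedList")) t1 <- RankedList(t1)
  if (!is(t2, "RankedList")) t2 <- RankedList(t2)
  a <- .alignedRanks(t1, t2)
  p <- length(a$r1)
  if (k < 1 || k > p) stop("k must be in [1, p]")
  if (k == p) return(.canberraRanks(a$r1, a$r2) / expectedCanberra(p))
  .topkRaw(a$r1, a$r2, k) / .topkNorm(p, k)
}

#' Within-dataset stability of a collection of ranked lists
#'
#' Mean normalized Canberra distance over unordered list pairs: all pairs
#' when their number does not exceed \code{pairBudget}, otherwise a seeded
#' random subsample of pairs. Smaller is more stable; independently random
#' lists score about 1.
#'
#' @param lists a list of \linkS4class{RankedList}s over one feature
#'   universe (e.g. the per-split lists of a bootstrap ensemble).
#' @param k optional sublist length; full lists when \code{NULL}.
#' @param pairBudget maximum number of pairs evaluated.
#' @param seed seed for the pair subsample.
#' @return List with \code{mean}, \code{se} (standard error over the
#'   evaluated pairs) and \code{nPairs}.
#' @export
withinStability <- function(lists, k = NULL, pairBudget = 10000L, seed = 1L) {
  Tn <- length(lists)
  if (Tn < 2L) stop("need at least 2 ranked lists")
  rk <- lapply(lists, ranks)
  fu <- names(rk[[1L]])
  rk <- lapply(rk, function(r) r[fu])
  p <- length(fu)
  norm <- expectedCanberra(p)
  dist1 <- if (is.null(k)) {
    function(a, b) .canberraRanks(a, b) / norm
  } else {
    tn <- .topkNorm(p, k)
    function(a, b) .topkRaw(a, b, k) / tn
  }
  nAll <- Tn * (Tn - 1) / 2
  if (nAll <= pairBudget) {
    prs <- which(upper.tri(matrix(0, Tn, Tn)), arr.ind = TRUE)
  } else {
    prs <- .withSeed(seed, {
      i <- sample.int(Tn, 2L * pairBudget, replace = TRUE)
      j <- sample.int(Tn, 2L * pairBudget, replace = TRUE)
      ok <- i != j
      cbind(i[ok], j[ok])[seq_len(pairBudget), , drop = FALSE]
    })
  }
  d <- vapply(seq_len(nrow(prs)),
              function(r) dist1(rk[[prs[r, 1L]]], rk[[prs[r, 2L]]]), 0)
  list(mean = mean(d), se = stats::sd(d) / sqrt(length(d)),
       nPairs = length(d))
}

#' Stability profile over sublist lengths
#'
#' Mean top-k normalized Canberra distance for each k in \code{kGrid}, and
#' the minimizing sublist length \eqn{k^*} (smallest k on ties). When
#' several datasets are analyzed, the protocol uses the average of their
#' per-dataset \eqn{k^*} values (see [averageKStar()]).
#'
#' @inheritParams withinStability
#' @param kGrid increasing vector of sublist lengths within \eqn{[1, p]}.
#' @return List with \code{profile} (data.frame of k, stability, se) and
#'   \code{kStar}.
#' @export
stabilityProfile <- function(lists, kGrid, pairBudget = 10000L, seed = 1L) {
  p <- length(featureIds(lists[[1L]]))
  if (any(kGrid < 1 | kGrid > p)) stop("kGrid must lie in [1, p]")
  rows <- lapply(kGrid, function(k) {
    ws <- withinStability(lists, k = if (k == p) NULL else k,
                          pairBudget = pairBudget, seed = seed)
    data.frame(k = k, stability = ws$mean, se = ws$se)
  })
  profile <- do.call(rbind, rows)
  list(profile = profile,
       kStar = profile$k[which.min(profile$stability)])
}

#' @describeIn stabilityProfile the multi-dataset protocol's sublist
#'   length: the average of per-dataset \eqn{k^*} values, rounded.
#' @param kStars numeric vector of per-dataset minimizers.
#' @export
averageKStar <- function(kStars) as.integer(.roundHalfUp(mean(kStars)))

#' Union-list curve across datasets
#'
#' For each k, the size of the union of the datasets' top-k feature sets.
#' Identical global lists trace the diagonal (union size = k); disjoint
#' lists approach \code{D * k} for D datasets. The curve quantifies the
#' consistency of the final biomarker lists across studies.
#'
#' @param globalLists list of \linkS4class{RankedList}s, one per dataset,
#'   over a shared feature universe.
#' @param kGrid sublist lengths.
#' @return data.frame with columns \code{k} and \code{unionSize}.
#' @export
unionCurve <- function(globalLists, kGrid) {
  p <- length(featureIds(globalLists[[1L]]))
  if (any(kGrid < 1 | kGrid > p)) stop("kGrid must lie in [1, p]")
  sizes <- vapply(kGrid, function(k) {
    length(unique(unlist(lapply(globalLists, topFeatures, k = k))))
  }, 0L)
  data.frame(k = kGrid, unionSize = sizes)
}

#' Tune the embedding weight alpha for list stability
#'
#' Runs the full pipeline (embedding, transformation, bootstrap ensemble,
#' per-split ranked lists) for every alpha in the grid and measures the
#' within-dataset mean normalized Canberra distance over the per-split
#' lists. Returns the alpha with the best (lowest) stability value --
#' smallest alpha on ties, so an uninformative similarity matrix yields
#' the no-prior baseline \eqn{\alpha^* = 0} -- together with the per-alpha
#' stability/accuracy/epochs table that exposes the stability-accuracy
#' trade-off.
#'
#' Every ensemble is restarted from \code{cfg$seed}, so all alphas see
#' identical train/test partitions and the comparison is paired.
#'
#' @param dataset an \linkS4class{ExpressionDataset} (raw, untransformed).
#' @param S a \linkS4class{SimilarityMatrix} aligned with the dataset.
#' @param alphaGrid candidate alphas; must contain 0 (the baseline).
#' @param cfg a [runConfig()].
#' @return List with \code{alphaStar}, \code{report} (data.frame: alpha,
#'   stability, stabilitySE, meanAccuracy, meanEpochs), \code{best}
#'   (the \linkS4class{EnsembleResult} at \code{alphaStar}) and
#'   \code{bestLists} (its per-split ranked lists).
#' @export
tuneAlpha <- function(dataset, S, alphaGrid = NULL, cfg = runConfig()) {
  if (is.null(alphaGrid)) alphaGrid <- cfg$alphaGrid
  if (!0 %in% alphaGrid) stop("alphaGrid must include 0 as the baseline")
  alphaGrid <- sort(unique(alphaGrid))
  fid <- featureIds(dataset)
  rows <- list()
  results <- vector("list", length(alphaGrid))
  lists <- vector("list", length(alphaGrid))
  for (a in seq_along(alphaGrid)) {
    alpha <- alphaGrid[a]
    emb <- buildEmbedding(S, alpha)
    td <- transformStandardize(dataset, emb)
    res <- bootstrapEnsemble(td, cfg)
    perSplit <- lapply(seq_len(nrow(splitWeights(res))), function(t)
      rankFeatures(splitWeights(res)[t, ], fid))
    ws <- withinStability(perSplit, pairBudget = cfg$pairBudget,
                          seed = cfg$seed)
    rows[[a]] <- data.frame(alpha = alpha, stability = ws$mean,
                            stabilitySE = ws$se,
                            meanAccuracy = mean(testAccuracies(res)),
                            meanEpochs = meanEpochs(res))
    results[[a]] <- res
    lists[[a]] <- perSplit
  }
  report <- do.call(rbind, rows)
  best <- which.min(report$stability)    # ties: first = smallest alpha
  list(alphaStar = report$alpha[best], report = report,
       best = results[[best]], bestLists = lists[[best]])
}
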
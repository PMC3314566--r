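test_that("Canberra distance matches hand values and brute force on all permutation pairs", {
  expect_equal(canberra(c("a", "b", "c"), c("a", "b", "c")), 0)
  expect_equal(canberra(c("a", "b", "c"), c("c", "b", "a")), 1)   # 2/4+0+2/4
  expect_equal(canberra(c("a", "b"), c("b", "a")), 2 / 3)

  bruteCanberra <- function(p1, p2) {
    # p1, p2 are rank vectors indexed by item
    s <- 0
    for (i in seq_along(p1)) s <- s + abs(p1[i] - p2[i]) / (p1[i] + p2[i])
    s
  }
  ids <- letters[1:4]
  for (n in 3:4) {
    perms <- allPermutations(n)
    for (p1 in perms) for (p2 in perms) {
      l1 <- RankedList(ids[seq_len(n)][order(p1)])  # item i at rank p1[i]
      l2 <- RankedList(ids[seq_len(n)][order(p2)])
      expect_equal(canberra(l1, l2), bruteCanberra(p1, p2))
    }
  }
  expect_error(canberra(c("a", "b"), c("a", "x")), "universe")
})

test_that("Canberra distance is a symmetric non-negative semimetric on rankings", {
  set.seed(4)
  ids <- sprintf("f%03d", 1:50)
  for (i in 1:10) {
    l1 <- RankedList(sample(ids))
    l2 <- RankedList(sample(ids))
    d12 <- canberra(l1, l2)
    expect_gte(d12, 0)
    expect_equal(d12, canberra(l2, l1))
    expect_equal(canberra(l1, l1), 0)
    if (!identical(featureIds(l1), featureIds(l2))) expect_gt(d12, 0)
  }
})

test_that("expected Canberra follows the asymptotic formula, which fails for tiny p", {
  expect_equal(expectedCanberra(100), (log(4) - 1) * 100 + log(4) - 2)
  expect_equal(expectedCanberra(100), 38.015, tolerance = 1e-4)

  # exact mean over all permutation pairs at p = 3 vs the asymptotic value:
  # the approximation is poor at tiny p (documented, not relied upon)
  perms <- allPermutations(3L)
  ids <- c("a", "b", "c")
  ds <- sapply(perms, function(p1) sapply(perms, function(p2)
    canberra(RankedList(ids[order(p1)]), RankedList(ids[order(p2)]))))
  exact <- mean(ds)
  expect_gt(abs(exact - expectedCanberra(3)) / exact, 0.1)
})

test_that("normalized Canberra hits its landmarks: 0, ~1 random, <= 1.4", {
  ids <- sprintf("f%04d", 1:1000)
  l <- RankedList(sample(ids))
  expect_equal(normalizedCanberra(l, l), 0)

  set.seed(8)
  p <- 2000
  ids <- sprintf("f%04d", seq_len(p))
  vals <- replicate(50, normalizedCanberra(RankedList(sample(ids)),
                                           RankedList(sample(ids))))
  expect_lt(abs(mean(vals) - 1), 0.02)
  expect_true(all(vals <= 1.4))
  # reversal approaches the maximal-instability end of the range
  rev <- normalizedCanberra(RankedList(ids), RankedList(base::rev(ids)))
  expect_gt(rev, 1.2)
  expect_lte(rev, 1.4)
})

test_that("top-k Canberra reduces to the full distance at k = p and orders overlap", {
  set.seed(12)
  ids <- sprintf("f%03d", 1:60)
  l1 <- RankedList(sample(ids))
  l2 <- RankedList(sample(ids))
  expect_equal(topkCanberra(l1, l2, k = 60), normalizedCanberra(l1, l2))

  # identical top-k in identical order -> 0
  l3 <- RankedList(ids)
  l4 <- RankedList(c(ids[1:10], sample(ids[11:60])))
  expect_equal(topkCanberra(l3, l3, k = 10), 0)

  # monotone in disagreement: identical < half-overlapping < disjoint top-k
  half <- RankedList(c(ids[6:15], ids[1:5], ids[16:60]))
  disj <- RankedList(c(ids[31:60], ids[1:30]))
  dId <- topkCanberra(l3, l4, k = 10)
  dHalf <- topkCanberra(l3, half, k = 10)
  dDisj <- topkCanberra(l3, disj, k = 10)
  expect_lt(dId, dHalf)
  expect_lt(dHalf, dDisj)
})

test_that("within-dataset stability averages pairs and subsampling is consistent", {
  ids <- sprintf("f%03d", 1:40)
  same <- replicate(10, RankedList(ids), simplify = FALSE)
  expect_equal(withinStability(same)$mean, 0)

  set.seed(21)
  rnd <- replicate(50, RankedList(sample(ids)), simplify = FALSE)
  full <- withinStability(rnd)                      # all 1225 pairs
  expect_lt(abs(full$mean - 1), 0.05)
  sub <- withinStability(rnd, pairBudget = 300L, seed = 2)
  expect_equal(sub$nPairs, 300L)
  expect_lt(abs(sub$mean - full$mean), 3 * sub$se)
})

test_that("stability profile localizes the agreement depth and k* tie-breaks low", {
  ids <- sprintf("f%03d", 1:100)
  same <- replicate(6, RankedList(ids), simplify = FALSE)
  prof0 <- stabilityProfile(same, kGrid = c(5, 10, 50, 100))
  expect_true(all(prof0$profile$stability == 0))
  expect_equal(prof0$kStar, 5)                      # smallest k on ties

  # ensembles whose top-30 feature set is fixed (order shuffled) and whose
  # tail is random: the stability profile is minimized at k = 30
  set.seed(31)
  agree <- replicate(12,
                     RankedList(c(sample(ids[1:30]), sample(ids[31:100]))),
                     simplify = FALSE)
  prof <- stabilityProfile(agree, kGrid = c(5, 30, 70, 100))
  expect_equal(prof$kStar, 30)
  # profile at k = p equals the full-list within-stability
  expect_equal(prof$profile$stability[prof$profile$k == 100],
               withinStability(agree)$mean)

  expect_equal(averageKStar(c(10, 21, 30)), 20L)
})

test_that("union curve traces agreement between global lists", {
  ids <- sprintf("f%03d", 1:30)
  l1 <- RankedList(ids)
  same <- unionCurve(list(l1, l1, l1), kGrid = c(1, 5, 10))
  expect_equal(same$unionSize, c(1, 5, 10))         # diagonal

  disj <- list(RankedList(ids),
               RankedList(c(ids[11:20], ids[21:30], ids[1:10])),
               RankedList(c(ids[21:30], ids[1:10], ids[11:20])))
  worst <- unionCurve(disj, kGrid = c(5, 10))
  expect_equal(worst$unionSize, c(15, 30))          # 3k

  set.seed(41)
  rndLists <- replicate(3, RankedList(sample(ids)), simplify = FALSE)
  curve <- unionCurve(rndLists, kGrid = 1:30)
  expect_true(all(diff(curve$unionSize) >= 0))
  expect_true(all(curve$unionSize <= pmin(3 * curve$k, 30)))
})

test_that("alpha tuning returns the baseline for an inert identity prior", {
  d <- smallDesign(2)
  ex <- makeExpression(d)
  Sid <- SimilarityMatrix(diag(d$nFeatures),
                          featureIds = featureIds(ex$dataset))
  cfg <- runConfig(T = 25, seed = 3)
  tuned <- tuneAlpha(ex$dataset, Sid, alphaGrid = c(0, 1, 4), cfg = cfg)
  # identity similarity is inert: every alpha gives P = I and equal reports
  expect_equal(tuned$alphaStar, 0)
  expect_equal(diff(range(tuned$report$stability)), 0, tolerance = 1e-12)
  expect_named(tuned$report,
               c("alpha", "stability", "stabilitySE", "meanAccuracy",
                 "meanEpochs"))
})
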
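test_that("perceptron follows the hand-simulated update schedule", {
  # 1-D: x1 = +1 (y +1), x2 = -1 (y -1); w starts at 0 so the first sample
  # always fires an update; epoch 2 is mistake-free
  X <- matrix(c(1, -1), 2, 1)
  set.seed(1)
  fit <- perceptronTrain(X, c(1, -1), maxEpochs = 10)
  expect_true(fit$converged)
  expect_identical(fit$epochs, 2L)
  expect_gt(fit$w, 0)

  expect_error(perceptronTrain(X[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("perceptron converges on separable data and separates it strictly", {
  for (seed in 1:5) {
    d <- separableDataset(M = 24, N = 8, gap = 4, seed = seed)
    X <- scale(exprValues(d))
    y <- unname(sampleLabels(d))
    set.seed(seed)
    fit <- perceptronTrain(X, y, maxEpochs = 500)
    expect_true(fit$converged)
    expect_true(all(y * (X %*% fit$w) > 0))
  }
})

test_that("bootstrap ensemble keeps its structural invariants", {
  d <- separableDataset(M = 30, N = 12, gap = 3, seed = 2)
  td <- transformStandardize(
    d, buildEmbedding(SimilarityMatrix(diag(12), featureIds(d)), 0))
  cfg <- runConfig(T = 40, seed = 5)
  res <- bootstrapEnsemble(td, cfg)
  W <- splitWeights(res)
  expect_equal(unname(sqrt(rowSums(W^2))), rep(1, 40), tolerance = 1e-10)
  Q <- designMatrix(res)
  expect_true(all(rowSums(Q) == ceiling(0.7 * 30)))
  # every training partition is class-stratified
  y <- unname(sampleLabels(td))
  expect_true(all(apply(Q, 1, function(q) length(unique(y[q == 1])) == 2L)))
  expect_equal(unname(averagedWeights(res)), unname(colMeans(W)))
  # determinism: same seed, bit-identical result
  res2 <- bootstrapEnsemble(td, cfg)
  expect_identical(splitWeights(res2), W)
  expect_identical(testAccuracies(res2), testAccuracies(res))
})

test_that("duplicated transformed features receive exactly equal averaged weights", {
  set.seed(3)
  X <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("f", 1:10)))
  X[, 2] <- X[, 1]                       # identical columns
  d <- ExpressionDataset(X, rep(c(-1, 1), 10))
  res <- bootstrapEnsemble(d, runConfig(T = 25, seed = 9, maxEpochs = 50))
  W <- averagedWeights(res)
  expect_identical(W[["f1"]], W[["f2"]])
  expect_true(all(splitWeights(res)[, 1] == splitWeights(res)[, 2]))
})

test_that("null and signal models bracket the ensemble's test accuracy", {
  # permuted labels, balanced classes -> chance-level accuracy
  set.seed(11)
  Xn <- matrix(rnorm(60 * 20), 60, 20,
               dimnames = list(NULL, sprintf("f%02d", 1:20)))
  dn <- ExpressionDataset(scale(Xn), rep(c(-1, 1), 30))
  resN <- bootstrapEnsemble(dn, runConfig(T = 200, seed = 13, maxEpochs = 100))
  se <- sd(testAccuracies(resN)) / sqrt(200)
  expect_lt(abs(mean(testAccuracies(resN)) - 0.5), 3 * se + 0.02)
  expect_lt(abs(oobAccuracy(resN, dn) - 0.5), 0.15)

  # strongly separated two-Gaussian data -> high accuracy
  ds <- separableDataset(M = 40, N = 10, gap = 4, seed = 17)
  tds <- ExpressionDataset(scale(exprValues(ds)), unname(sampleLabels(ds)),
                           featureIds = featureIds(ds))
  resS <- bootstrapEnsemble(tds, runConfig(T = 100, seed = 19))
  expect_gt(mean(testAccuracies(resS)), 0.9)
  expect_gt(oobAccuracy(resS, tds), 0.9)
})

test_that("out-of-bag averaging counts zero predictions as errors", {
  # degenerate ensemble: identical, perfectly separating weight vectors
  resPerfect <- new("EnsembleResult",
                    weights = matrix(c(1, 1, 0, 0), 2, 2,  # both w_t = (1, 0)
                                     dimnames = list(NULL, c("f1", "f2"))),
                    testAccuracies = c(1, 1), epochs = c(1L, 1L),
                    converged = c(TRUE, TRUE),
                    designMatrix = matrix(c(1L, 0L, 0L, 1L), 2, 2),
                    averagedWeights = c(1, 0))
  dPerfect <- ExpressionDataset(
    matrix(c(2, -2, 1, 1), 2, 2, dimnames = list(NULL, c("f1", "f2"))),
    c(1, -1))
  expect_equal(oobAccuracy(resPerfect, dPerfect), 1.0)

  # constructed tie: orthogonal weights give sign 0 on the tested sample
  resTie <- new("EnsembleResult",
                weights = matrix(c(0, 0, 1, 1), 2, 2,   # both w_t = (0, 1)
                                 dimnames = list(NULL, c("f1", "f2"))),
                testAccuracies = c(1, 1), epochs = c(1L, 1L),
                converged = c(TRUE, TRUE),
                designMatrix = matrix(c(1L, 0L, 0L, 1L), 2, 2),
                averagedWeights = c(0, 1))
  dTie <- ExpressionDataset(
    matrix(c(1, 1, 0, 0), 2, 2, dimnames = list(NULL, c("f1", "f2"))),
    c(1, -1))
  # both samples: W(m) = (0, 1), x_m = (1, 0) -> W.x = 0 -> counted wrong
  expect_equal(oobAccuracy(resTie, dTie), 0)
})

test_that("k-fold accuracy approaches the out-of-bag estimate on separable data", {
  d <- separableDataset(M = 30, N = 8, gap = 4, seed = 23)
  td <- ExpressionDataset(scale(exprValues(d)), unname(sampleLabels(d)),
                          featureIds = featureIds(d))
  cfg <- runConfig(T = 30, seed = 25)
  kf <- kfoldAccuracy(td, k = 5, cfg = cfg)
  expect_gt(kf, 0.9)
  res <- bootstrapEnsemble(td, cfg)
  expect_lt(abs(kf - oobAccuracy(res, td)), 0.1)
})

test_that("feature ranking sorts by |weight| with lexicographic ties", {
  rl <- rankFeatures(c(f1 = 0.2, f2 = -0.9, f3 = 0.5))
  expect_identical(featureIds(rl), c("f2", "f3", "f1"))
  # all-equal magnitudes -> identifier order
  rl2 <- rankFeatures(c(b = 1, a = -1, c = 1))
  expect_identical(featureIds(rl2), c("a", "b", "c"))
  # negation leaves the ranking unchanged
  w <- c(x = 0.3, y = -0.7, z = 0.1)
  expect_identical(featureIds(rankFeatures(w)), featureIds(rankFeatures(-w)))
  expect_error(rankFeatures(c(a = NA_real_)), "finite")
})

test_that("mean epochs tracks task difficulty through the margin", {
  mk <- function(gap, seed) {
    d <- separableDataset(M = 30, N = 10, gap = gap, seed = seed)
    ExpressionDataset(scale(exprValues(d)), unname(sampleLabels(d)),
                      featureIds = featureIds(d))
  }
  cfg <- runConfig(T = 40, seed = 31, maxEpochs = 200)
  easy <- bootstrapEnsemble(mk(5, 1), cfg)
  hard <- bootstrapEnsemble(mk(0.7, 1), cfg)
  expect_identical(meanEpochs(easy), mean(easy@epochs))
  expect_gt(meanEpochs(hard), meanEpochs(easy))
})
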
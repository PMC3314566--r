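# Bootstrap perceptron ensemble: a Bayes-point-machine-like averaging of
# perceptron solutions over random 70/30 splits, with out-of-bag and k-fold
# accuracy estimation and |W|-based feature ranking.

#' Run configuration for the ensemble
#'
#' @param T number of bootstrap splits (default 1000, as in the underlying
#'   protocol; tests use smaller values).
#' @param trainFraction fraction of samples in each training partition.
#' @param maxEpochs perceptron epoch cap for non-separable partitions.
#' @param seed RNG seed applied at the start of [bootstrapEnsemble()].
#' @param alphaGrid candidate mixing weights for [tuneAlpha()].
#' @param stratified stratify splits by class (recommended; avoids
#'   single-class training partitions).
#' @param pairBudget maximum number of list pairs evaluated when measuring
#'   within-dataset stability.
#' @param bias include an intercept term in the perceptron (default off:
#'   the separating hyperplane is homogeneous and data are standardized).
#' @return A list of class \code{"RunConfig"}.
#' @export
runConfig <- function(T = 1000L, trainFraction = 0.7, maxEpochs = 500L,
                      seed = 1L, alphaGrid = c(0, 0.25, 0.5, 1, 2, 4),
                      stratified = TRUE, pairBudget = 10000L, bias = FALSE) {
  if (T < 2L) stop("need at least 2 splits")
  if (!(trainFraction > 0 && trainFraction < 1))
    stop("trainFraction must be in (0,1)")
  .assertScalarNumber(maxEpochs, "maxEpochs", lower = 1)
  structure(list(T = as.integer(T), trainFraction = trainFraction,
                 maxEpochs = as.integer(maxEpochs), seed = as.integer(seed),
                 alphaGrid = alphaGrid, stratified = isTRUE(stratified),
                 pairBudget = as.integer(pairBudget), bias = isTRUE(bias)),
            class = "RunConfig")
}

#' Train a perceptron on a labelled sample matrix
#'
#' Starts from the zero weight vector and runs epochs over the samples,
#' shuffling the presentation order before every epoch. On each sample the
#' update \eqn{w \leftarrow w + y_i x_i} fires whenever
#' \eqn{y_i (w \cdot x_i) \le 0} -- a zero margin counts as a mistake, so
#' the very first sample of a run always triggers an update. Training stops
#' at the first mistake-free epoch (converged) or at \code{maxEpochs}
#' (not converged; the current \eqn{w} is returned). On linearly separable
#' data convergence is guaranteed.
#'
#' @param X numeric matrix, samples in rows (standardized features).
#' @param y labels in \{-1,+1\}.
#' @param maxEpochs epoch cap.
#' @param bias include an intercept (an implicit constant 1 feature).
#' @return List with \code{w} (weights, plus \code{b} if \code{bias}),
#'   \code{epochs} (number executed) and \code{converged}.
#' @export
perceptronTrain <- function(X, y, maxEpochs = 500L, bias = FALSE) {
  M <- nrow(X)
  if (M == 0L) stop("empty training set")
  stopifnot(length(y) == M)
  Xt <- t(X)                      # features x samples: column access is cheap
  N <- nrow(Xt)
  w <- numeric(N)
  b <- 0
  converged <- FALSE
  epochs <- 0L
  for (ep in seq_len(maxEpochs)) {
    epochs <- ep
    mistakes <- 0L
    for (i in sample.int(M)) {
      xi <- Xt[, i]
      marg <- y[i] * (sum(w * xi) + b)
      if (marg <= 0) {
        w <- w + y[i] * xi
        if (bias) b <- b + y[i]
        mistakes <- mistakes + 1L
      }
    }
    if (mistakes == 0L) {
      converged <- TRUE
      break
    }
  }
  out <- list(w = w, epochs = epochs, converged = converged)
  if (bias) out$b <- b
  out
}

# Stratified train-partition indices: nTrain samples total with both
# classes represented (class counts proportional, clamped so that train
# and test each keep at least one sample of some class).
.splitIndices <- function(y, nTrain, stratified) {
  M <- length(y)
  if (nTrain >= M) stop("training fraction leaves no test samples")
  if (!stratified) {
    repeat {
      idx <- sample.int(M, nTrain)
      if (length(unique(y[idx])) == 2L) return(idx)
      .msg("resampled a single-class training partition")
    }
  }
  pos <- which(y > 0)
  neg <- which(y < 0)
  nPos <- round(nTrain * length(pos) / M)
  nPos <- min(max(nPos, 1L), length(pos) - 1L, nTrain - 1L)
  nNeg <- nTrain - nPos
  if (nNeg > length(neg) - 1L) {
    nNeg <- length(neg) - 1L
    nPos <- nTrain - nNeg
  }
  c(sample(pos, nPos), sample(neg, nNeg))
}

#' Bootstrap perceptron ensemble
#'
#' Splits the (transformed, standardized) dataset into random
#' train/test partitions \code{cfg$T} times (70/30 by default, stratified
#' by class), trains a perceptron on each training partition, normalizes
#' each solution \eqn{w_t} to unit norm, scores it on the matching test
#' partition, and averages the solutions into \eqn{W = \mathrm{AVE}(w_t)}.
#' A prediction of exactly 0 counts as an error.
#'
#' @param dataset an \linkS4class{ExpressionDataset}, already passed
#'   through [transformStandardize()].
#' @param cfg a [runConfig()]; \code{cfg$seed} (unless \code{NULL}) seeds
#'   the split/shuffle randomness, making the result reproducible.
#' @return An \linkS4class{EnsembleResult}.
#' @export
bootstrapEnsemble <- function(dataset, cfg = runConfig()) {
  X <- exprValues(dataset)
  y <- unname(sampleLabels(dataset))
  M <- nrow(X)
  N <- ncol(X)
  if (min(sum(y > 0), sum(y < 0)) < 2L)
    stop("each class needs at least 2 samples")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nTrain <- ceiling(cfg$trainFraction * M)
  Tn <- cfg$T
  weights <- matrix(0, Tn, N, dimnames = list(NULL, colnames(X)))
  acc <- numeric(Tn)
  epochs <- integer(Tn)
  converged <- logical(Tn)
  Q <- matrix(0L, Tn, M, dimnames = list(NULL, rownames(X)))
  for (t in seq_len(Tn)) {
    tr <- .splitIndices(y, nTrain, cfg$stratified)
    fit <- perceptronTrain(X[tr, , drop = FALSE], y[tr],
                           maxEpochs = cfg$maxEpochs, bias = cfg$bias)
    wb <- c(fit$w, if (cfg$bias) fit$b)
    nrm <- sqrt(sum(wb^2))
    if (nrm > 0) {
      fit$w <- fit$w / nrm
      if (cfg$bias) fit$b <- fit$b / nrm
    }
    te <- setdiff(seq_len(M), tr)
    pred <- X[te, , drop = FALSE] %*% fit$w + if (cfg$bias) fit$b else 0
    acc[t] <- mean(y[te] * pred > 0)
    weights[t, ] <- fit$w
    epochs[t] <- fit$epochs
    converged[t] <- fit$converged
    Q[t, tr] <- 1L
  }
  if (any(!converged))
    .msg("%d of %d splits hit the epoch cap without converging",
         sum(!converged), Tn)
  new("EnsembleResult", weights = weights, testAccuracies = acc,
      epochs = epochs, converged = converged, designMatrix = Q,
      averagedWeights = colMeans(weights))
}

#' @describeIn bootstrapEnsemble feature identifiers of the weight vectors.
#' @param x an \code{EnsembleResult}.
#' @export
setMethod("featureIds", "EnsembleResult", function(x) colnames(x@weights))

#' Accessors for ensemble results
#'
#' @param x an \linkS4class{EnsembleResult}.
#' @return \code{averagedWeights}: the named vector \eqn{W};
#'   \code{splitWeights}: the splits-by-features matrix of unit-norm
#'   \eqn{w_t}; \code{testAccuracies}: per-split test accuracies \eqn{a_t};
#'   \code{designMatrix}: the binary splits-by-samples matrix \eqn{Q}.
#' @export
averagedWeights <- function(x) {
  stats::setNames(x@averagedWeights, colnames(x@weights))
}

#' @rdname averagedWeights
#' @export
splitWeights <- function(x) x@weights

#' @rdname averagedWeights
#' @export
testAccuracies <- function(x) x@testAccuracies

#' @rdname averagedWeights
#' @export
designMatrix <- function(x) x@designMatrix

#' Mean perceptron epochs across splits
#'
#' The average number of epochs the perceptron needed, an indicator of how
#' difficult the (transformed) task is: it tracks the ratio between the
#' maximal sample norm and the achievable margin.
#'
#' @param x an \linkS4class{EnsembleResult}.
#' @return Numeric scalar (capped, non-converged splits included at the cap).
#' @export
meanEpochs <- function(x) mean(x@epochs)

#' Out-of-bag accuracy estimate of the averaged classifier
#'
#' For each sample \eqn{x_m}, averages only the weight vectors from splits
#' whose training partition did not contain \eqn{m} (design-matrix entry
#' \eqn{Q_{tm} = 0}) and tests that leave-one-sample-out average on
#' \eqn{x_m}. A prediction of exactly 0 counts as an error. Samples used by
#' every split are skipped with a warning.
#'
#' @param result an \linkS4class{EnsembleResult}.
#' @param dataset the dataset the ensemble was trained on.
#' @return Fraction of evaluable samples classified correctly.
#' @export
oobAccuracy <- function(result, dataset) {
  X <- exprValues(dataset)
  y <- unname(sampleLabels(dataset))
  Q <- result@designMatrix
  stopifnot(ncol(Q) == nrow(X))
  evaluable <- colSums(Q == 0L) > 0L
  if (!all(evaluable))
    warning(sprintf("%d sample(s) appear in every training partition; skipped",
                    sum(!evaluable)))
  correct <- vapply(which(evaluable), function(m) {
    Wm <- colMeans(result@weights[Q[, m] == 0L, , drop = FALSE])
    y[m] * sum(Wm * X[m, ]) > 0
  }, TRUE)
  mean(correct)
}

#' k-fold cross-validated accuracy of the full procedure
#'
#' Splits samples into \code{k} class-stratified folds; for each fold the
#' complete bootstrap ensemble is trained on the remaining samples and its
#' averaged classifier \eqn{W} is scored on the held-out fold. With
#' \code{k} equal to the sample count this reduces to a leave-one-out
#' scheme.
#'
#' @param dataset a transformed, standardized
#'   \linkS4class{ExpressionDataset}.
#' @param k number of folds.
#' @param cfg a [runConfig()]; fold ensembles are seeded
#'   \code{cfg$seed + fold}.
#' @return Mean held-out accuracy across folds.
#' @export
kfoldAccuracy <- function(dataset, k, cfg = runConfig()) {
  X <- exprValues(dataset)
  y <- unname(sampleLabels(dataset))
  M <- nrow(X)
  if (k < 2L || k > M) stop("k must be in [2, number of samples]")
  folds <- integer(M)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  for (cls in c(-1, 1)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  accs <- vapply(seq_len(k), function(f) {
    te <- which(folds == f)
    tr <- setdiff(seq_len(M), te)
    sub <- dataset[, tr]
    cfgF <- cfg
    cfgF$seed <- cfg$seed + f
    res <- bootstrapEnsemble(sub, cfgF)
    W <- res@averagedWeights
    mean(y[te] * (X[te, , drop = FALSE] %*% W) > 0)
  }, 0)
  mean(accs)
}

#' Rank features by absolute weight
#'
#' Features are ordered by decreasing \eqn{|W_i|}; ties are broken by
#' lexicographic feature identifier so the ranking is deterministic.
#' Negating the weight vector leaves the ranking unchanged.
#'
#' @param weights numeric weight vector (e.g. [averagedWeights()] of an
#'   ensemble, or one row of [splitWeights()]), named by feature, or an
#'   \linkS4class{EnsembleResult} (its \eqn{W} is used).
#' @param featureIds identifiers matching \code{weights} (defaults to its
#'   names).
#' @return A \linkS4class{RankedList}.
#' @examples
#' featureIds(rankFeatures(c(f1 = 0.2, f2 = -0.9, f3 = 0.5)))  # f2 f3 f1
#' @export
rankFeatures <- function(weights, featureIds = names(weights)) {
  if (is(weights, "EnsembleResult")) {
    featureIds <- colnames(weights@weights)
    weights <- weights@averagedWeights
  }
  if (is.null(featureIds)) stop("feature identifiers are required")
  if (any(!is.finite(weights))) stop("weights must be finite")
  ord <- order(-abs(weights), featureIds, method = "radix")
  RankedList(featureIds[ord])
}

setMethod("show", "EnsembleResult", function(object) {
  cat(sprintf(paste0("EnsembleResult: %d splits x %d features; mean test ",
                     "accuracy %.3f; mean epochs %.1f (%d%% converged)\n"),
              nrow(object@weights), ncol(object@weights),
              mean(object@testAccuracies), mean(object@epochs),
              round(100 * mean(object@converged))))
})
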
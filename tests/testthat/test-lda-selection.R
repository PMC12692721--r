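test_that("LDA separates well-separated classes and respects contracts", {
  set.seed(1)
  X <- matrix(c(rnorm(100, -5, 0.1), rnorm(100, 5, 0.1)), ncol = 1)
  y <- rep(c("H", "E"), each = 100)
  m <- fitLda(X, y)
  expect_equal(mean(predictLda(m, X) == y), 1.0)
  ## prediction at a class mean returns that class
  expect_identical(predictLda(m, matrix(-5, 1, 1)), "H")
  expect_identical(predictLda(m, matrix(5, 1, 1)), "E")
  ## dimension mismatch
  expect_error(predictLda(m, matrix(0, 1, 2)), "mismatch")
  ## degenerate labels
  expect_error(fitLda(X, rep("H", 200)), "two classes")
  expect_error(fitLda(X[1:3, , drop = FALSE], c("H", "H", "E")), "two rows")
})

test_that("the two-class boundary equals the closed-form Fisher direction", {
  set.seed(2)
  X <- matrix(rnorm(400 * 4), 400, 4)
  y <- rep(c("a", "b"), each = 200)
  X[y == "b", 1] <- X[y == "b", 1] + 2
  X[y == "b", 3] <- X[y == "b", 3] - 1
  m <- fitLda(X, y, ridge = 0)
  dir1 <- m@coef[, 1] - m@coef[, 2]          # discriminant difference
  dir2 <- fisherDirection(X, y)
  cs <- abs(sum(dir1 * dir2)) / sqrt(sum(dir1^2) * sum(dir2^2))
  expect_gt(cs, 1 - 1e-8)
})

test_that("fitting is invariant to row permutation", {
  set.seed(3)
  X <- matrix(rnorm(300 * 3), 300, 3)
  y <- sample(c("H", "E", "C"), 300, replace = TRUE)
  X[y == "H", 1] <- X[y == "H", 1] + 1
  m1 <- fitLda(X, y)
  perm <- sample(300)
  m2 <- fitLda(X[perm, ], y[perm])
  expect_equal(m1@coef, m2@coef, tolerance = 1e-10)
  expect_equal(m1@intercept, m2@intercept, tolerance = 1e-10)
})

test_that("predictions agree with an independent discriminant implementation", {
  skip_if_not_installed("MASS")
  set.seed(4)
  X <- matrix(rnorm(500 * 5), 500, 5)
  y <- sample(LABELS8[1:4], 500, replace = TRUE)
  for (cl in unique(y)) {
    shift <- rnorm(5, 0, 1.5)
    X[y == cl, ] <- sweep(X[y == cl, , drop = FALSE], 2, shift, "+")
  }
  ours <- fitLda(X, y, ridge = 0)
  ref <- MASS::lda(X, grouping = factor(y))
  refPred <- as.character(predict(ref, X)$class)
  expect_identical(predictLda(ours, X), refPred)
})

test_that("score argmax is invariant to adding a constant to all classes", {
  set.seed(5)
  X <- matrix(rnorm(50 * 2), 50, 2)
  y <- rep(c("H", "E"), 25)
  X[y == "H", ] <- X[y == "H", ] + 1
  m <- fitLda(X, y)
  sc <- predictLda(m, X, scores = TRUE)
  shifted <- sc$scores + 7.5
  expect_identical(m@classes[max.col(shifted, ties.method = "first")],
                   sc$labels)
})

test_that("stepwise screening drops duplicates and needs class structure", {
  set.seed(6)
  fm <- genPlantedFeatures(nRows = 600, nClasses = 4, nInformative = 2,
                           nNoise = 10, effectSize = 2, seed = 6)
  X <- featureValues(fm)
  X <- cbind(X, dup = X[, 1])              # exactly collinear pair
  sel <- sdaSelect(X, featureLabels(fm))
  expect_false(all(c(1, ncol(X)) %in% sel))  # at most one of the pair
  expect_true(any(c(1, ncol(X)) %in% sel))
  ## constant column skipped with warning
  Xc <- cbind(X[, 1:5], const = 0)
  expect_warning(sdaSelect(Xc, featureLabels(fm)), "constant")
  ## single class: empty selection with warning
  expect_warning(out <- sdaSelect(X[1:50, 1:5],
                                  rep("H", 50)), "single class")
  expect_identical(out, integer(0))
})

test_that("stepwise screening ranks planted signal ahead of noise", {
  hits <- 0
  for (s in 1:20) {
    fm <- genPlantedFeatures(nRows = 2000, nClasses = 8, nInformative = 3,
                             nNoise = 50, effectSize = 1.5, seed = 100 + s)
    sel <- sdaSelect(featureValues(fm), featureLabels(fm))
    first3 <- sel[1:3]
    if (all(sort(first3) == 1:3)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("greedy selection finds a dominating column first and stops", {
  set.seed(7)
  n <- 400
  y <- sample(LABELS8[1:4], n, replace = TRUE)
  dominant <- match(y, LABELS8[1:4]) + rnorm(n, 0, 0.05)
  X <- cbind(noise1 = rnorm(n), dom = dominant, noise2 = rnorm(n))
  tr <- greedyLdaSelect(X, y, evalSplit = 0.25, seed = 7)
  expect_identical(tr@chosen[1], 2L)
  expect_lte(length(tr@chosen), 2L)
  expect_gt(tr@cumulativeAccuracy[1], 0.95)
  expect_identical(tr@stopReason, "gain_below_threshold")
})

test_that("greedy cumulative accuracy is internally consistent and monotone", {
  fm <- genPlantedFeatures(nRows = 1200, nClasses = 8, nInformative = 5,
                           nNoise = 10, effectSize = 2, seed = 8)
  X <- featureValues(fm); y <- featureLabels(fm)
  tr <- greedyLdaSelect(X, y, evalSplit = 0.2, seed = 8)
  cum <- tr@cumulativeAccuracy
  expect_true(all(diff(cum) > 0))
  expect_equal(tr@marginalGain, c(cum[1], diff(cum)), tolerance = 1e-12)
  ## re-fit on exactly the first k chosen columns reproduces cum[k]
  set.seed(8)
  evalIdx <- sort(sample.int(nrow(X), round(0.2 * nrow(X))))
  trainIdx <- setdiff(seq_len(nrow(X)), evalIdx)
  for (k in seq_along(tr@chosen)) {
    cols <- tr@chosen[1:k]
    m <- fitLda(X[trainIdx, cols, drop = FALSE], y[trainIdx])
    acc <- mean(predictLda(m, X[evalIdx, cols, drop = FALSE]) ==
                  as.character(y[evalIdx]))
    expect_equal(acc, cum[k], tolerance = 1e-12)
  }
})

test_that("the stop-gain rule halts exactly at a constructed marginal gain", {
  ## three strong columns, then a fourth adding a vanishing gain
  set.seed(9)
  n <- 4000
  y <- sample(LABELS8[1:8], n, replace = TRUE)
  ci <- match(y, LABELS8)
  ## columns 1-3 jointly encode the class index almost noiselessly
  X <- cbind(b1 = (ci %% 2) + rnorm(n, 0, 0.01),
             b2 = (ci %/% 2 %% 2) + rnorm(n, 0, 0.01),
             b3 = (ci %/% 4) + rnorm(n, 0, 0.01),
             tiny = rnorm(n))
  tr <- greedyLdaSelect(X, y, stopGain = 5e-5, evalSplit = 0.25, seed = 9)
  expect_identical(length(tr@chosen), 3L)
  expect_setequal(tr@chosen, 1:3)
  expect_identical(tr@stopReason, "gain_below_threshold")
  expect_gt(tr@cumulativeAccuracy[3], 0.999)
})

test_that("two-stage selection recovers planted columns and never hurts", {
  fm <- genPlantedFeatures(nRows = 2000, nClasses = 8, nInformative = 5,
                           nNoise = 45, effectSize = 2, seed = 10)
  X <- featureValues(fm); y <- featureLabels(fm)
  keep <- sdaSelect(X, y)
  expect_true(all(1:5 %in% keep))
  tr <- greedyLdaSelect(X, y, candidates = keep, evalSplit = 0.2, seed = 10)
  k <- length(tr@chosen)
  ## greedy refinement at least matches LDA on the full SDA set
  set.seed(10)
  evalIdx <- sort(sample.int(nrow(X), round(0.2 * nrow(X))))
  trainIdx <- setdiff(seq_len(nrow(X)), evalIdx)
  mFull <- fitLda(X[trainIdx, keep, drop = FALSE], y[trainIdx])
  accFull <- mean(predictLda(mFull, X[evalIdx, keep, drop = FALSE]) ==
                    as.character(y[evalIdx]))
  expect_gte(tr@cumulativeAccuracy[k], accFull - 1e-9)
})

test_that("selection curves difference correctly and locate k95/k99", {
  tr <- new("SelectionTrace", chosen = 1:3,
            cumulativeAccuracy = c(0.5, 0.6, 0.6),
            marginalGain = c(0.5, 0.1, 0.0), stopReason = "max_k")
  sc <- selectionCurve(tr)
  expect_equal(sc$curve$marginal_gain, c(0.5, 0.1, 0.0))
  expect_true(all(sc$curve$marginal_gain >= 0))
  tr2 <- new("SelectionTrace", chosen = 1:4,
             cumulativeAccuracy = c(0.90, 0.94, 0.949, 0.95),
             marginalGain = c(0.90, 0.04, 0.009, 0.001),
             stopReason = "max_k")
  sc2 <- selectionCurve(tr2)
  ## threshold rule cum[k] >= frac * final: 0.95 * 0.95 = 0.9025, first met
  ## at k = 2 (0.90 falls short); 0.99 * 0.95 = 0.9405, first met at k = 3
  expect_identical(sc2$k95, 2L)
  expect_identical(sc2$k99, 3L)
  expect_error(selectionCurve(new("SelectionTrace", chosen = integer(0),
                                  cumulativeAccuracy = numeric(0),
                                  marginalGain = numeric(0),
                                  stopReason = "x")), "empty")
})

test_that("standardization imputes missing values at the population mean", {
  X <- matrix(c(1, 2, NA, 4, 0, 0, 0, 0), 4, 2)
  Z <- standardizeFeatures(X)
  expect_true(all(is.finite(Z)))
  expect_equal(Z[3, 1], 0)               # imputed at the column mean
  expect_equal(unname(Z[, 2]), rep(0, 4))        # zero-variance column
  expect_equal(mean(Z[-3, 1]), 0, tolerance = 1e-12)
})
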
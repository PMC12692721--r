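## Independent oracles used across the suite. Each re-derives the quantity
## it checks through a different route than the implementation under test.

## Optimal-superposition RMSD via the quaternion (Horn) eigenvalue method:
## largest eigenvalue of the 4x4 key matrix built from the covariance of
## the centred point sets. Independent of the SVD route in the package.
quaternionRmsd <- function(X, Y) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- crossprod(Xc, Yc)
  K <- matrix(c(
    S[1,1] + S[2,2] + S[3,3], S[2,3] - S[3,2], S[3,1] - S[1,3], S[1,2] - S[2,1],
    S[2,3] - S[3,2], S[1,1] - S[2,2] - S[3,3], S[1,2] + S[2,1], S[3,1] + S[1,3],
    S[3,1] - S[1,3], S[1,2] + S[2,1], -S[1,1] + S[2,2] - S[3,3], S[2,3] + S[3,2],
    S[1,2] - S[2,1], S[3,1] + S[1,3], S[2,3] + S[3,2], -S[1,1] - S[2,2] + S[3,3]),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(Xc^2) + sum(Yc^2) - 2 * lmax) / n))
}

## two-pass mean/variance (unbiased)
twoPassStats <- function(x) {
  m <- sum(x) / length(x)
  list(mean = m, var = sum((x - m)^2) / (length(x) - 1))
}

## literal evaluation of the t statistic from its defining quantities
directTStat <- function(muGlobal, muSeq, varSeq, nOcc, varGlobal, N) {
  (muGlobal - muSeq) / sqrt(varSeq / nOcc + varGlobal / N)
}

## literal term-by-term evaluation of the periodicity descriptor
directPeriodic <- function(H, T, nT, A) {
  n <- round((T * nT - 1) / 2)
  stopifnot(length(H) == 2 * n + 1)
  ca <- 0; sa <- 0
  for (idx in seq_along(H)) {
    k <- idx - n - 1
    f <- exp(-A * (k / n)^2)
    ca <- ca + H[idx] * cos(2 * pi * k / T) * f
    sa <- sa + H[idx] * sin(2 * pi * k / T) * f
  }
  sqrt(ca^2 + sa^2)
}

## literal window-sum descriptor at one position of a property vector
directWindow <- function(H, p, left, right, A, power = 1) {
  m <- max(abs(left), abs(right))
  acc <- 0
  for (k in left:right) {
    q <- p + k
    if (q < 1 || q > length(H)) next
    w <- if (m == 0) 1 else exp(-A * (k / m)^2)
    acc <- acc + H[q] * w
  }
  acc^power
}

## brute-force per-class TP/FP/FN and F1
bruteF1 <- function(true, pred, classes) {
  per <- sapply(classes, function(cl) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(true)) {
      if (true[i] == cl && pred[i] == cl) tp <- tp + 1
      if (true[i] != cl && pred[i] == cl) fp <- fp + 1
      if (true[i] == cl && pred[i] != cl) fn <- fn + 1
    }
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  })
  list(perClass = per, macro = mean(per))
}

## closed-form two-class Fisher discriminant direction
fisherDirection <- function(X, y) {
  lv <- unique(y)
  X1 <- X[y == lv[1], , drop = FALSE]
  X2 <- X[y == lv[2], , drop = FALSE]
  Sw <- (crossprod(sweep(X1, 2, colMeans(X1))) +
           crossprod(sweep(X2, 2, colMeans(X2))))
  solve(Sw, colMeans(X1) - colMeans(X2))
}
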
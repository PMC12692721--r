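## Two-stage descriptor pre-selection: stepwise discriminant analysis on
## Wilks' lambda, then greedy forward selection maximizing the accuracy of
## a linear discriminant classifier.

#' Standardize a feature matrix and impute missing values
#'
#' Column-wise z-standardization followed by zero imputation of missing
#' entries, i.e. missing descriptor values (chain ends, sparse keys,
#' out-of-range offsets) are placed at the population mean. Zero-variance
#' columns become all-zero.
#'
#' @param X numeric matrix, possibly with NA.
#' @return matrix with finite entries; attributes `center` and `scale`.
#' @export
standardizeFeatures <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X, na.rm = TRUE)
  sd0 <- apply(X, 2, stats::sd, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  sd0[!is.finite(sd0) | sd0 == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd0, "/")
  Z[is.na(Z)] <- 0
  attr(Z, "center") <- mu
  attr(Z, "scale") <- sd0
  Z
}

## Wilks' lambda of a column subset: det(W_S) / det(T_S)
wilksLambda <- function(Wmat, Tmat, S) {
  dW <- determinant(Wmat[S, S, drop = FALSE], logarithm = TRUE)
  dT <- determinant(Tmat[S, S, drop = FALSE], logarithm = TRUE)
  exp(as.numeric(dW$modulus) - as.numeric(dT$modulus))
}

#' Stepwise discriminant analysis (variable pre-screening)
#'
#' Classical stepwise selection on Wilks' lambda: at each step the
#' candidate with the largest partial F-to-enter above `fEnter` is added,
#' then entered variables whose partial F-to-remove falls below `fRemove`
#' are dropped, until no entry or removal is possible or `maxKeep` is
#' reached. Constant columns are skipped with a warning; candidates that
#' are (near-)collinear with the current subset are never entered, so the
#' returned subset contains no exactly collinear pair. Designed as a fast
#' pre-screen that cuts a large descriptor pool down to a tractable,
#' mutually non-redundant subset before the greedy stage.
#'
#' @param X numeric matrix (standardized, finite).
#' @param y class labels.
#' @param fEnter,fRemove entry/removal thresholds, `fEnter > fRemove > 0`;
#'   defaults 3.84 / 2.71.
#' @param maxKeep maximum number of variables to retain.
#' @return integer vector of selected column indices (entry order).
#' @export
sdaSelect <- function(X, y, fEnter = 3.84, fRemove = 2.71, maxKeep = Inf) {
  stopifnot(fEnter > fRemove, fRemove > 0)
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  g <- nlevels(y)
  n <- nrow(X); d <- ncol(X)
  if (g < 2) {
    warning("single class: no between-class variance, empty selection")
    return(integer(0))
  }
  sds <- apply(X, 2, stats::sd)
  usable <- which(sds > 0)
  if (length(usable) < d) warning("constant column(s) skipped")
  ## total and within scatter, computed once
  Xc <- sweep(X, 2, colMeans(X))
  Tmat <- crossprod(Xc)
  Wmat <- matrix(0, d, d)
  for (cl in levels(y)) {
    Xi <- X[y == cl, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    Wmat <- Wmat + crossprod(Xi)
  }
  sel <- integer(0)
  lambdaSel <- 1
  tolDet <- 1e-10
  repeat {
    changed <- FALSE
    ## entry step
    p <- length(sel)
    if (p < maxKeep) {
      cand <- setdiff(usable, sel)
      bestF <- -Inf; bestJ <- NA_integer_; bestLambda <- NA_real_
      for (j in cand) {
        S2 <- c(sel, j)
        dT <- determinant(Tmat[S2, S2, drop = FALSE], logarithm = TRUE)
        if (dT$sign <= 0) next
        ## collinearity guard: relative det of the candidate set
        rel <- as.numeric(dT$modulus) -
          sum(log(diag(Tmat)[S2]))
        if (rel < log(tolDet)) next
        lam <- wilksLambda(Wmat, Tmat, S2)
        ratio <- lam / lambdaSel
        ratio <- min(max(ratio, 1e-300), 1)
        Fj <- ((n - g - p) / (g - 1)) * (1 - ratio) / ratio
        if (is.finite(Fj) && Fj > bestF) {
          bestF <- Fj; bestJ <- j; bestLambda <- lam
        }
      }
      if (!is.na(bestJ) && bestF > fEnter) {
        sel <- c(sel, bestJ)
        lambdaSel <- bestLambda
        changed <- TRUE
      }
    }
    ## removal step
    if (length(sel) > 1) {
      repeat {
        p <- length(sel)
        Frem <- vapply(seq_along(sel), function(i) {
          S0 <- sel[-i]
          lam0 <- wilksLambda(Wmat, Tmat, S0)
          ratio <- lambdaSel / lam0
          ratio <- min(max(ratio, 1e-300), 1)
          ((n - g - p + 1) / (g - 1)) * (1 - ratio) / ratio
        }, 0)
        worst <- which.min(Frem)
        if (Frem[worst] < fRemove) {
          lambdaSel <- wilksLambda(Wmat, Tmat, sel[-worst])
          sel <- sel[-worst]
          changed <- TRUE
        } else break
      }
    }
    if (!changed || length(sel) >= maxKeep) break
  }
  sel
}

#' Greedy forward descriptor selection under an LDA classifier
#'
#' Forward selection over a (pre-screened) candidate set: at each step the
#' model is refit with each remaining candidate appended and the
#' accuracy-maximizing candidate is kept; ties break toward the lowest
#' column index. Selection stops when the best marginal accuracy gain is
#' not strictly positive, falls below `stopGain`, or `maxK` columns are
#' selected. By default accuracy is evaluated on a held-out split of the
#' rows (seeded, default 20%), mirroring internal-validation usage;
#' `evalSplit = 0` evaluates on the training rows.
#'
#' @param X numeric matrix (standardized, finite).
#' @param y class labels.
#' @param stopGain minimum accepted marginal gain (accuracy fraction;
#'   the default 5e-5 is 0.005 percentage points).
#' @param maxK maximum number of descriptors.
#' @param evalSplit held-out fraction for accuracy evaluation.
#' @param seed seed for the split.
#' @param candidates candidate column indices (e.g. the SDA subset);
#'   default all columns.
#' @param ridge passed to [fitLda()].
#' @return A [SelectionTrace-class].
#' @export
greedyLdaSelect <- function(X, y, stopGain = 5e-5, maxK = ncol(X),
                            evalSplit = 0.2, seed = 1L, candidates = NULL,
                            ridge = NULL) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  n <- nrow(X)
  if (is.null(candidates)) candidates <- seq_len(ncol(X))
  candidates <- sort(candidates)
  if (evalSplit > 0) {
    rng <- local({
      set.seed(seed)
      sample.int(n, size = max(1, round(evalSplit * n)))
    })
    evalIdx <- sort(rng)
    trainIdx <- setdiff(seq_len(n), evalIdx)
  } else {
    evalIdx <- trainIdx <- seq_len(n)
  }
  ## guard: training split must keep every class twice
  if (any(table(y[trainIdx]) < 2))
    stop("training split too small for some class; lower evalSplit")
  chosen <- integer(0)
  cum <- numeric(0)
  gain <- numeric(0)
  lastAcc <- 0
  stopReason <- "candidates_exhausted"
  while (length(chosen) < maxK && length(setdiff(candidates, chosen))) {
    remaining <- setdiff(candidates, chosen)
    accs <- rep(NA_real_, length(remaining))
    for (i in seq_along(remaining)) {
      cols <- c(chosen, remaining[i])
      m <- tryCatch(fitLda(X[trainIdx, cols, drop = FALSE], y[trainIdx],
                           ridge = ridge),
                    error = function(e) NULL)
      if (!is.null(m))
        accs[i] <- mean(predictLda(m, X[evalIdx, cols, drop = FALSE]) ==
                          as.character(y[evalIdx]))
    }
    if (all(is.na(accs))) { stopReason <- "fit_failed"; break }
    best <- which.max(accs)          # first max: lowest column index wins ties
    bestGain <- accs[best] - lastAcc
    if (!is.finite(bestGain) || bestGain <= 0 || bestGain < stopGain) {
      stopReason <- "gain_below_threshold"
      break
    }
    chosen <- c(chosen, remaining[best])
    lastAcc <- accs[best]
    cum <- c(cum, lastAcc)
    gain <- c(gain, bestGain)
  }
  if (length(chosen) == maxK && stopReason == "candidates_exhausted")
    stopReason <- "max_k"
  new("SelectionTrace", chosen = chosen, cumulativeAccuracy = cum,
      marginalGain = gain, stopReason = stopReason)
}

#' Selection-curve summary of a trace
#'
#' Emits the cumulative-accuracy and marginal-gain curves and the smallest
#' number of descriptors reaching 95% and 99% of the final cumulative
#' accuracy (threshold rule: smallest `k` with `cum[k] >= frac * final`).
#'
#' @param trace a [SelectionTrace-class].
#' @return list with `curve` (data.frame k, cumulative_accuracy,
#'   marginal_gain), `k95`, `k99`.
#' @export
selectionCurve <- function(trace) {
  k <- length(trace@chosen)
  if (!k) stop("empty selection trace")
  cum <- trace@cumulativeAccuracy
  final <- cum[k]
  kAt <- function(frac) which(cum >= frac * final)[1]
  list(curve = data.frame(k = seq_len(k), column = trace@chosen,
                          cumulative_accuracy = cum,
                          marginal_gain = trace@marginalGain),
       k95 = kAt(0.95), k99 = kAt(0.99))
}
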
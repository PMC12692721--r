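## Multiclass linear discriminant classifier on the pooled within-class
## covariance, with a ridge term for numerical stability.

#' Fit a multiclass linear discriminant model
#'
#' Pooled within-class covariance LDA. The discriminant score of class `c`
#' at `x` is `x' S^{-1} m_c - m_c' S^{-1} m_c / 2 + log pi_c` with `S` the
#' (ridge-regularized) pooled covariance, `m_c` the class mean and `pi_c`
#' the empirical prior. Default ridge: `1e-6 * trace(S) / d` added to the
#' diagonal.
#'
#' @param X numeric matrix (rows observations).
#' @param y class labels (factor or character); at least two classes with
#'   at least two rows each.
#' @param ridge non-negative scalar, or NULL for the default.
#' @return An [LdaModel-class].
#' @export
fitLda <- function(X, y, ridge = NULL) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  classes <- levels(y)
  g <- length(classes)
  if (g < 2) stop("at least two classes required")
  tab <- table(y)
  if (any(tab < 2)) stop("each class needs at least two rows")
  n <- nrow(X); d <- ncol(X)
  M <- matrix(0, g, d, dimnames = list(classes, colnames(X)))
  W <- matrix(0, d, d)
  for (ci in seq_len(g)) {
    Xi <- X[y == classes[ci], , drop = FALSE]
    M[ci, ] <- colMeans(Xi)
    Xc <- sweep(Xi, 2, M[ci, ])
    W <- W + crossprod(Xc)
  }
  S <- W / (n - g)
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(S)) / d
  S <- S + diag(ridge, d)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular pooled covariance; increase ridge (", conditionMessage(e), ")"))
  coef <- Sinv %*% t(M)                     # d x g
  logPriors <- log(as.numeric(tab) / n)
  intercept <- -0.5 * colSums(t(M) * coef) + logPriors
  new("LdaModel", classMeans = M, coef = coef, intercept = intercept,
      logPriors = logPriors, classes = classes, ridge = ridge)
}

#' Predict with a linear discriminant model
#'
#' Argmax of the linear discriminant scores; ties break deterministically
#' toward the lowest class index.
#'
#' @param model an [LdaModel-class].
#' @param X numeric matrix with the model's column count.
#' @param scores also return the per-class score matrix.
#' @return character vector of labels, or a list with `labels` and
#'   `scores`.
#' @export
predictLda <- function(model, X, scores = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(model@coef))
    stop("feature dimension mismatch: ", ncol(X), " vs ", nrow(model@coef))
  sc <- X %*% model@coef
  sc <- sweep(sc, 2, model@intercept, "+")
  labels <- model@classes[max.col(sc, ties.method = "first")]
  if (scores) list(labels = labels, scores = sc) else labels
}

ldaAccuracy <- function(model, X, y) {
  mean(predictLda(model, X) == as.character(y))
}
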
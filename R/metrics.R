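## Residue-level evaluation: Q score, per-class and macro F1, confusion
## matrices. The mask label is excluded from every metric.

## resolve a class set argument: 8, 3, or an explicit character vector
resolveClassSet <- function(classSet) {
  if (is.numeric(classSet)) {
    if (classSet == 8) return(LABELS8)
    if (classSet == 3) return(LABELS3)
    stop("classSet must be 8, 3, or a character vector")
  }
  classSet
}

maskedPairs <- function(true, pred, mask = NULL) {
  stopifnot(length(true) == length(pred))
  keep <- true != MASK_LABEL
  if (!is.null(mask)) keep <- keep & mask
  list(true = true[keep], pred = pred[keep])
}

#' Q score: fraction of correctly predicted residues
#'
#' The proportion of unmasked residues whose predicted label equals the
#' true label. Independent of the number of classes (Q3, Q8 or 16-state
#' alike). Masked positions (the mask label, or `mask = FALSE`) never
#' contribute.
#'
#' @param true,pred character vectors of equal length.
#' @param mask optional logical; `FALSE` positions are excluded on top of
#'   mask-labelled ones.
#' @return fraction in \[0, 1\].
#' @export
qScore <- function(true, pred, mask = NULL) {
  mp <- maskedPairs(true, pred, mask)
  if (!length(mp$true)) stop("no unmasked residues: Q score undefined")
  mean(mp$true == mp$pred)
}

#' Per-class and macro F1
#'
#' `F1 = 2 TP / (2 TP + FP + FN)` per class; a class with no true and no
#' predicted instances gets F1 = 0 (conservative convention). The macro
#' score is the unweighted mean over the full fixed class set, regardless
#' of class presence.
#'
#' @param true,pred character vectors.
#' @param classSet 8 (default), 3, or an explicit class vector.
#' @param mask optional logical exclusion mask.
#' @return list with `perClass` (named numeric) and `macro`.
#' @export
f1Scores <- function(true, pred, classSet = 8, mask = NULL) {
  classes <- resolveClassSet(classSet)
  mp <- maskedPairs(true, pred, mask)
  perClass <- vapply(classes, function(cl) {
    tp <- sum(mp$true == cl & mp$pred == cl)
    fp <- sum(mp$true != cl & mp$pred == cl)
    fn <- sum(mp$true == cl & mp$pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  list(perClass = perClass, macro = mean(perClass))
}

#' Confusion matrix over a fixed class set
#'
#' Counts of (true class, predicted class) pairs over unmasked residues;
#' rows are true classes. The row-normalized view is available through
#' [confusionNormalized()]. Three-state evaluation of eight-state labels
#' should map labels through [map8to3()] first.
#'
#' @param true,pred character vectors with labels inside the class set.
#' @param classSet 8 (default), 3, or an explicit class vector.
#' @param mask optional logical exclusion mask.
#' @return A [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(true, pred, classSet = 8, mask = NULL) {
  classes <- resolveClassSet(classSet)
  mp <- maskedPairs(true, pred, mask)
  bad <- unique(c(mp$true, mp$pred))
  bad <- bad[!bad %in% classes]
  if (length(bad))
    stop("label outside the class set: ", paste(bad, collapse = ","))
  counts <- table(factor(mp$true, levels = classes),
                  factor(mp$pred, levels = classes))
  new("ConfusionMatrix",
      counts = matrix(as.integer(counts), nrow = length(classes),
                      dimnames = list(true = classes, predicted = classes)),
      classes = classes)
}

#' Aggregate an eight-state confusion matrix to three states
#'
#' Sums count blocks through the H,G,I -> H; E,B -> E; T,S,C -> C mapping.
#'
#' @param cm an eight-state [ConfusionMatrix-class].
#' @return a three-state [ConfusionMatrix-class].
#' @export
aggregateConfusion8to3 <- function(cm) {
  stopifnot(identical(cm@classes, LABELS8))
  grp <- map8to3(cm@classes)
  counts3 <- matrix(0L, 3, 3, dimnames = list(true = LABELS3,
                                              predicted = LABELS3))
  for (i in seq_along(LABELS8))
    for (j in seq_along(LABELS8))
      counts3[grp[i], grp[j]] <- counts3[grp[i], grp[j]] + cm@counts[i, j]
  new("ConfusionMatrix", counts = counts3, classes = LABELS3)
}

#' Full evaluation report
#'
#' Q score, per-class F1, macro F1, and the confusion matrix (counts and
#' row-normalized), as written by the evaluation entry point.
#'
#' @param true,pred label vectors.
#' @param classSet 8 or 3 (eight-state labels are mapped with [map8to3()]
#'   when 3).
#' @param mask optional exclusion mask.
#' @return list.
#' @export
evaluationReport <- function(true, pred, classSet = 8, mask = NULL) {
  if (identical(classSet, 3) || identical(classSet, 3L)) {
    true <- map8to3(true); pred <- map8to3(pred)
  }
  cm <- confusionMatrix(true, pred, classSet, mask)
  f1 <- f1Scores(true, pred, classSet, mask)
  list(q = qScore(true, pred, mask), f1_per_class = f1$perClass,
       f1_macro = f1$macro, confusion_counts = confusionCounts(cm),
       confusion_normalized = confusionNormalized(cm))
}
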
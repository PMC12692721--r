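#' @import methods
NULL

## ---------------------------------------------------------------------------
## ProteinChain
## ---------------------------------------------------------------------------

#' ProteinChain: a single polypeptide chain with labels and backbone
#'
#' Container for one chain: one- and three-letter sequences (non-canonical
#' residue codes preserved in the three-letter form), per-residue eight-state
#' labels plus the mask label for unresolved positions, optional backbone
#' N/CA/C coordinates and a per-residue resolved flag. Residue indexing in
#' the API is 1-based; author-provided residue numbers are retained in
#' `resno` solely for reconciliation with DSSP output.
#'
#' @slot chainId single chain identifier.
#' @slot seq1 character vector, one letter per residue ('X' for unmapped
#'   non-canonical codes).
#' @slot seq3 character vector of three-letter codes, non-canonical codes
#'   verbatim.
#' @slot labels8 character vector over `c(LABELS8, MASK_LABEL)`.
#' @slot backbone numeric array `n x 3 x 3` (residue, atom N/CA/C, x/y/z)
#'   in Angstrom, or a zero-length array when no coordinates are attached.
#' @slot resolved logical; unresolved residues always carry the mask label.
#' @slot resno integer author residue numbers (NA where unknown).
#' @export
setClass("ProteinChain",
  representation(chainId = "character", seq1 = "character",
                 seq3 = "character", labels8 = "character",
                 backbone = "array", resolved = "logical",
                 resno = "integer"))

setValidity("ProteinChain", function(object) {
  n <- length(object@seq1)
  msg <- character()
  if (length(object@seq3) != n || length(object@labels8) != n ||
      length(object@resolved) != n || length(object@resno) != n)
    msg <- c(msg, "seq1, seq3, labels8, resolved, resno must share length")
  if (length(object@backbone) && !identical(dim(object@backbone)[1], n))
    msg <- c(msg, "backbone present but first dimension != residue count")
  bad <- !object@labels8 %in% c(LABELS8, MASK_LABEL)
  if (any(bad)) msg <- c(msg, "labels8 outside {H,G,I,E,B,T,S,C, mask}")
  if (any(!object@resolved & object@labels8 != MASK_LABEL))
    msg <- c(msg, "unresolved residues must carry the mask label")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProteinChain", function(object) {
  n <- length(object@seq1)
  cat(sprintf("ProteinChain '%s': %d residues, %d resolved, coords: %s\n",
              object@chainId, n, sum(object@resolved),
              if (length(object@backbone)) "yes" else "no"))
  if (n) {
    cat("  seq1:    ", paste(utils::head(object@seq1, 40), collapse = ""),
        if (n > 40) "..." else "", "\n", sep = "")
    cat("  labels8: ", paste(utils::head(object@labels8, 40), collapse = ""),
        if (n > 40) "..." else "", "\n", sep = "")
  }
})

#' Construct a ProteinChain
#'
#' @param seq1 character vector of one-letter codes (one per residue).
#' @param seq3 three-letter codes; defaults to the canonical expansion of
#'   `seq1`.
#' @param labels8 per-residue labels; defaults to all-mask.
#' @param backbone optional `n x 3 x 3` coordinate array (N, CA, C).
#' @param resolved logical; defaults to `TRUE` where backbone is complete
#'   (or everywhere when no backbone is attached and labels are present).
#' @param chainId,resno identifiers kept for bookkeeping.
#' @return A [ProteinChain-class] object.
#' @export
proteinChain <- function(seq1, seq3 = unname(AA3[seq1]), labels8 = NULL,
                         backbone = NULL, resolved = NULL, chainId = "A",
                         resno = seq_along(seq1)) {
  n <- length(seq1)
  seq3[is.na(seq3)] <- "UNK"
  if (is.null(backbone)) backbone <- array(numeric(0), dim = c(0, 3, 3))
  if (is.null(resolved)) {
    resolved <- if (dim(backbone)[1] == n)
      apply(is.finite(backbone), 1, all) else rep(TRUE, n)
  }
  if (is.null(labels8)) labels8 <- rep(MASK_LABEL, n)
  labels8[!resolved] <- MASK_LABEL
  new("ProteinChain", chainId = as.character(chainId), seq1 = seq1,
      seq3 = seq3, labels8 = labels8, backbone = backbone,
      resolved = resolved, resno = as.integer(resno))
}

#' @rdname proteinChain
#' @param x a `ProteinChain`.
#' @export
chainLength <- function(x) length(x@seq1)

#' @rdname proteinChain
#' @export
chainSeq <- function(x) paste(x@seq1, collapse = "")

#' @rdname proteinChain
#' @export
chainLabels <- function(x) x@labels8

#' @rdname proteinChain
#' @export
chainBackbone <- function(x) x@backbone

#' @rdname proteinChain
#' @export
chainResolved <- function(x) x@resolved

## ---------------------------------------------------------------------------
## ProteinBlockSet
## ---------------------------------------------------------------------------

#' ProteinBlockSet: the 16 reference pentapeptide conformations
#'
#' The structural alphabet of 16 five-residue backbone conformations
#' (letters a..p). Each block is defined by eight consecutive dihedrals
#' (psi1, phi2, psi2, phi3, psi3, phi4, psi4, phi5) from which 15 backbone
#' atoms (N, CA, C of five residues) are rebuilt with ideal geometry.
#'
#' @slot labels the 16 block letters.
#' @slot dihedrals 16 x 8 matrix of dihedral angles in degrees.
#' @slot refCoords list of 16 matrices, each 15 x 3, in Angstrom.
#' @export
setClass("ProteinBlockSet",
  representation(labels = "character", dihedrals = "matrix",
                 refCoords = "list"))

setValidity("ProteinBlockSet", function(object) {
  msg <- character()
  if (length(object@labels) != 16) msg <- c(msg, "exactly 16 blocks required")
  if (!all(dim(object@dihedrals) == c(16, 8)))
    msg <- c(msg, "dihedrals must be 16 x 8")
  if (length(object@refCoords) != 16 ||
      !all(vapply(object@refCoords, function(m) all(dim(m) == c(15, 3)), TRUE)))
    msg <- c(msg, "refCoords must hold 16 matrices of 15 x 3")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProteinBlockSet", function(object) {
  cat(sprintf("ProteinBlockSet: %d blocks (%s)\n", length(object@labels),
              paste(object@labels, collapse = "")))
})

## ---------------------------------------------------------------------------
## PBStats
## ---------------------------------------------------------------------------

#' PBStats: accumulated RMSD statistics per pattern key and protein block
#'
#' Streaming (Welford) accumulator of fragment-to-block RMSD statistics.
#' Holds, per protein block, the global mean and variance of the RMSD over
#' all pentapeptide fragments of the corpus; per (alphabet, pattern key),
#' the key-conditional means/variances/counts; and, per key, counts of the
#' assigned protein-block letter strings over the key window.
#'
#' @slot blockLabels the 16 block letters.
#' @slot alphabetNames names of the reduced alphabets accumulated.
#' @slot fragmentLengths named integer, key-window length per alphabet.
#' @slot globalN total number of fragments accumulated.
#' @slot globalMean,globalM2 per-block streaming mean and sum of squared
#'   deviations.
#' @slot keyStats per alphabet, an environment mapping pattern key to
#'   `list(n, mean, m2)`.
#' @slot pbStrings per alphabet, an environment mapping pattern key to a
#'   named count vector of observed block-letter strings.
#' @slot stringVocab per alphabet, an environment of observed strings.
#' @slot alphabetN named numeric, fragments accumulated per alphabet.
#' @export
setClass("PBStats",
  representation(blockLabels = "character", alphabetNames = "character",
                 fragmentLengths = "integer", globalN = "numeric",
                 globalMean = "numeric", globalM2 = "numeric",
                 keyStats = "list", pbStrings = "list", stringVocab = "list",
                 alphabetN = "numeric"))

setMethod("show", "PBStats", function(object) {
  cat(sprintf("PBStats: %d fragments over %d blocks; alphabets: %s\n",
              object@globalN, length(object@blockLabels),
              paste(object@alphabetNames, collapse = ", ")))
  for (a in object@alphabetNames)
    cat(sprintf("  %s: %d keys, %g fragments\n", a,
                length(ls(object@keyStats[[a]])), object@alphabetN[[a]]))
})

## ---------------------------------------------------------------------------
## ReducedAlphabet
## ---------------------------------------------------------------------------

#' ReducedAlphabet: position-dependent residue equivalence classes
#'
#' A reduced alphabet partitions the 20 canonical one-letter codes into
#' equivalence classes, independently at each position of an odd-length
#' fragment. Two fragments share a pattern key iff their letters fall into
#' the same class at every position.
#'
#' @slot name alphabet name.
#' @slot fragmentLength odd fragment length.
#' @slot classMaps list (one per position) of named character vectors
#'   mapping a letter to its class identifier.
#' @slot wildcard whether letters outside the partition map to a wildcard
#'   class instead of erroring.
#' @slot unverified placeholder definitions not backed by a published table.
#' @export
setClass("ReducedAlphabet",
  representation(name = "character", fragmentLength = "integer",
                 classMaps = "list", wildcard = "logical",
                 unverified = "logical"))

setValidity("ReducedAlphabet", function(object) {
  msg <- character()
  L <- object@fragmentLength
  if (L < 1 || L %% 2 == 0) msg <- c(msg, "fragmentLength must be odd")
  if (length(object@classMaps) != L)
    msg <- c(msg, "one class map per position required")
  ok <- vapply(object@classMaps, function(m) all(AA1 %in% names(m)), TRUE)
  if (!all(ok)) msg <- c(msg, "each position must cover the 20 canonical letters")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReducedAlphabet", function(object) {
  nclass <- vapply(object@classMaps, function(m) length(unique(m)), 0L)
  cat(sprintf("ReducedAlphabet '%s': length %d, classes per position: %s%s\n",
              object@name, object@fragmentLength,
              paste(nclass, collapse = "/"),
              if (object@unverified) " [unverified placeholder]" else ""))
})

## ---------------------------------------------------------------------------
## PropertyTable
## ---------------------------------------------------------------------------

#' PropertyTable: one physicochemical property scale
#'
#' One value per residue, keyed by three-letter code. Canonical coverage is
#' mandatory; non-canonical codes are optional extension entries.
#'
#' @slot accession scale identifier (AAindex-style accession or user label).
#' @slot values named numeric, three-letter code to property value.
#' @slot source one of `aaindex`, `aaindexnc`, `user`, `synthetic`.
#' @slot standardized whether canonical values were z-scaled on load.
#' @export
setClass("PropertyTable",
  representation(accession = "character", values = "numeric",
                 source = "character", standardized = "logical"))

setValidity("PropertyTable", function(object) {
  msg <- character()
  if (!all(AA3 %in% names(object@values)))
    msg <- c(msg, "all 20 canonical three-letter codes must be present")
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PropertyTable", function(object) {
  extra <- setdiff(names(object@values), AA3)
  cat(sprintf("PropertyTable %s (%s%s): 20 canonical%s\n", object@accession,
              object@source, if (object@standardized) ", standardized" else "",
              if (length(extra)) paste0(" + ", length(extra), " ncAA (",
                                        paste(extra, collapse = ","), ")")
              else ""))
})

## ---------------------------------------------------------------------------
## FeatureMatrix
## ---------------------------------------------------------------------------

#' FeatureMatrix: residues x descriptors with labels and mask
#'
#' @slot X numeric matrix, rows are residues (possibly pooled over chains),
#'   columns are descriptors. May contain NA before standardization;
#'   after [standardizeFeatures()] all entries are finite.
#' @slot y factor of per-row labels over the eight structural classes
#'   (NA at masked rows).
#' @slot mask logical; `TRUE` rows participate in fitting and metrics,
#'   `FALSE` rows are structurally unresolved.
#' @slot columnMeta data.frame with one row per descriptor column.
#' @export
setClass("FeatureMatrix",
  representation(X = "matrix", y = "factor", mask = "logical",
                 columnMeta = "data.frame"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (nrow(object@X) != length(object@y) ||
      nrow(object@X) != length(object@mask))
    msg <- c(msg, "X rows, y and mask must share length")
  if (any(object@mask & is.na(object@y)))
    msg <- c(msg, "labels must be defined wherever mask is TRUE")
  if (nrow(object@columnMeta) && nrow(object@columnMeta) != ncol(object@X))
    msg <- c(msg, "columnMeta must have one row per column of X")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d rows (%d masked) x %d descriptors\n",
              nrow(object@X), sum(!object@mask), ncol(object@X)))
})

#' @rdname FeatureMatrix-class
#' @param X,y,mask,columnMeta see slots.
#' @export
featureMatrix <- function(X, y, mask = rep(TRUE, nrow(X)),
                          columnMeta = data.frame()) {
  y <- factor(as.character(y), levels = LABELS8)
  new("FeatureMatrix", X = as.matrix(X), y = y, mask = mask,
      columnMeta = columnMeta)
}

#' @rdname FeatureMatrix-class
#' @param object a `FeatureMatrix`.
#' @export
featureValues <- function(object) object@X

#' @rdname FeatureMatrix-class
#' @export
featureLabels <- function(object) object@y

#' @rdname FeatureMatrix-class
#' @export
featureMask <- function(object) object@mask

## ---------------------------------------------------------------------------
## LdaModel / SelectionTrace
## ---------------------------------------------------------------------------

#' LdaModel: multiclass linear discriminant classifier
#'
#' Pooled within-class covariance LDA with a ridge term on the covariance
#' diagonal. Prediction is the argmax of the linear discriminant scores,
#' ties broken toward the lowest class index.
#'
#' @slot classMeans classes x features matrix.
#' @slot coef features x classes discriminant coefficient matrix.
#' @slot intercept per-class intercepts (including log priors).
#' @slot logPriors log class priors.
#' @slot classes class labels in fixed order.
#' @slot ridge the ridge actually added to the covariance diagonal.
#' @export
setClass("LdaModel",
  representation(classMeans = "matrix", coef = "matrix",
                 intercept = "numeric", logPriors = "numeric",
                 classes = "character", ridge = "numeric"))

setMethod("show", "LdaModel", function(object) {
  cat(sprintf("LdaModel: %d classes x %d features (ridge %.3g)\n",
              length(object@classes), nrow(object@coef), object@ridge))
})

#' SelectionTrace: result of greedy forward descriptor selection
#'
#' @slot chosen ordered column indices, in selection order.
#' @slot cumulativeAccuracy accuracy after each accepted step.
#' @slot marginalGain per-step accuracy increments.
#' @slot stopReason why selection halted.
#' @export
setClass("SelectionTrace",
  representation(chosen = "integer", cumulativeAccuracy = "numeric",
                 marginalGain = "numeric", stopReason = "character"))

setValidity("SelectionTrace", function(object) {
  k <- length(object@chosen)
  msg <- character()
  if (length(object@cumulativeAccuracy) != k ||
      length(object@marginalGain) != k)
    msg <- c(msg, "trace vectors must share length")
  if (k > 1 && any(diff(object@cumulativeAccuracy) < -1e-12))
    msg <- c(msg, "cumulative accuracy must be non-decreasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SelectionTrace", function(object) {
  k <- length(object@chosen)
  cat(sprintf("SelectionTrace: %d descriptors, final accuracy %.4f (%s)\n",
              k, if (k) object@cumulativeAccuracy[k] else NA_real_,
              object@stopReason))
})

## ---------------------------------------------------------------------------
## ConfusionMatrix
## ---------------------------------------------------------------------------

#' ConfusionMatrix: true-class by predicted-class counts
#'
#' Rows are true classes, columns predicted classes, in a fixed class
#' order; the mask label never appears. The row-normalized view divides
#' each row by its total (rows of zeros stay zero for absent classes).
#'
#' @slot counts integer matrix.
#' @slot classes class order.
#' @export
setClass("ConfusionMatrix",
  representation(counts = "matrix", classes = "character"))

setValidity("ConfusionMatrix", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (MASK_LABEL %in% object@classes) return("mask label not allowed")
  TRUE
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = true, cols = predicted):\n")
  print(object@counts)
})

#' @rdname ConfusionMatrix-class
#' @param object a `ConfusionMatrix`.
#' @export
confusionCounts <- function(object) object@counts

#' @rdname ConfusionMatrix-class
#' @export
confusionNormalized <- function(object) {
  rs <- rowSums(object@counts)
  out <- object@counts / ifelse(rs == 0, 1, rs)
  out[rs == 0, ] <- 0
  out
}
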
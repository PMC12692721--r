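## Deterministic synthetic-data generators: chains with known segmental
## geometry and labels, planted-signal feature matrices, property tables.

HELIX_PHI <- -57; HELIX_PSI <- -47      # idealized alpha-helix dihedrals
STRAND_PHI <- -120; STRAND_PSI <- 130   # idealized extended-strand dihedrals

#' Generate a synthetic chain with known geometry and labels
#'
#' Builds backbone coordinates from segmentally ideal dihedrals plus
#' optional Gaussian angular noise: helix segments use phi = -57,
#' psi = -47 (label H); strand segments phi = -120, psi = +130 (label E);
#' coil segments draw per-residue dihedrals uniformly from a broadly
#' plausible region (phi in \[-180, -30\], psi in \[-90, 180\]; label C).
#' Labels are generator-assigned ground truth, not derived from hydrogen
#' bonding. The sequence is drawn uniformly from the canonical letters
#' unless supplied. Deterministic per seed.
#'
#' @param segments data.frame with columns `state` ("helix", "strand",
#'   "coil") and `length`, or a list of `c(state, length)` pairs.
#' @param noiseSd Gaussian dihedral noise, degrees.
#' @param seed RNG seed.
#' @param seq1 optional one-letter sequence (character vector or string).
#' @param chainId identifier.
#' @return A [ProteinChain-class] with backbone coordinates and labels.
#' @export
genChain <- function(segments, noiseSd = 0, seed = 1L, seq1 = NULL,
                     chainId = "synth") {
  if (!is.data.frame(segments))
    segments <- do.call(rbind, lapply(segments, function(s)
      data.frame(state = s[[1]], length = as.integer(s[[2]]))))
  stopifnot(all(segments$length >= 1), noiseSd >= 0)
  set.seed(seed)
  phi <- psi <- numeric(0)
  labels <- character(0)
  for (i in seq_len(nrow(segments))) {
    len <- segments$length[i]
    st <- match.arg(segments$state[i], c("helix", "strand", "coil"))
    seg <- switch(st,
      helix = list(phi = rep(HELIX_PHI, len), psi = rep(HELIX_PSI, len),
                   lab = "H"),
      strand = list(phi = rep(STRAND_PHI, len), psi = rep(STRAND_PSI, len),
                    lab = "E"),
      coil = list(phi = stats::runif(len, -180, -30),
                  psi = stats::runif(len, -90, 180), lab = "C"))
    phi <- c(phi, seg$phi); psi <- c(psi, seg$psi)
    labels <- c(labels, rep(seg$lab, len))
  }
  n <- length(phi)
  if (noiseSd > 0) {
    phi <- phi + stats::rnorm(n, 0, noiseSd)
    psi <- psi + stats::rnorm(n, 0, noiseSd)
  }
  if (is.null(seq1)) seq1 <- sample(AA1, n, replace = TRUE)
  else if (length(seq1) == 1L) seq1 <- strsplit(seq1, "")[[1]]
  stopifnot(length(seq1) == n)
  bb <- buildBackbone(phi, psi)
  proteinChain(seq1 = seq1, labels8 = labels, backbone = bb,
               resolved = rep(TRUE, n), chainId = chainId)
}

#' Substitute one residue by a (non-canonical) three-letter code
#'
#' Replaces `seq3` at a position and recomputes the one-letter code via
#' the mapping table; coordinates and labels are untouched.
#'
#' @param chain a [ProteinChain-class].
#' @param pos residue position (1-based).
#' @param code3 three-letter code (e.g. "HYP").
#' @param ncaa mapping table from [ncaaTable()].
#' @return modified chain.
#' @export
substituteResidue <- function(chain, pos, code3, ncaa = ncaaTable()) {
  stopifnot(pos >= 1, pos <= chainLength(chain))
  chain@seq3[pos] <- code3
  chain@seq1[pos] <- threeToOne(code3, ncaa)
  chain
}

#' Generate a planted-signal feature matrix
#'
#' Class-labelled rows with `nInformative` informative columns (values
#' drawn N(mu_c, 1), with per-class means mu_c drawn N(0, effectSize^2)
#' per column) and `nNoise` pure-noise columns (N(0, 1)). The informative
#' column indices are recorded in the column metadata and as attribute
#' `informative`.
#'
#' @param nRows rows (residues).
#' @param nClasses classes (labelled by the first `nClasses` structural
#'   labels).
#' @param nInformative,nNoise column counts.
#' @param effectSize class-mean spread in within-class standard
#'   deviations.
#' @param seed RNG seed.
#' @return A [FeatureMatrix-class]; attribute `informative` holds the
#'   planted column indices.
#' @export
genPlantedFeatures <- function(nRows = 2000L, nClasses = 8L,
                               nInformative = 5L, nNoise = 45L,
                               effectSize = 2, seed = 1L) {
  stopifnot(nInformative + nNoise >= 1, nClasses >= 1,
            nClasses <= length(LABELS8))
  set.seed(seed)
  y <- sample(LABELS8[seq_len(nClasses)], nRows, replace = TRUE)
  d <- nInformative + nNoise
  X <- matrix(stats::rnorm(nRows * d), nRows, d)
  classMeans <- matrix(stats::rnorm(nClasses * nInformative, 0, effectSize),
                       nClasses, nInformative)
  ci <- match(y, LABELS8)
  for (j in seq_len(nInformative))
    X[, j] <- X[, j] + classMeans[ci, j]
  colnames(X) <- c(sprintf("inf%02d", seq_len(nInformative)),
                   sprintf("noise%02d", seq_len(nNoise)))
  fm <- featureMatrix(X, y,
                      columnMeta = data.frame(
                        name = colnames(X),
                        informative = seq_len(d) <= nInformative))
  attr(fm, "informative") <- seq_len(nInformative)
  fm
}

#' Generate a random property table
#'
#' Random finite values for the 20 canonical residues plus optional
#' non-canonical entries; valid under the property-table invariants.
#'
#' @param seed RNG seed.
#' @param ncaaCodes optional three-letter codes to include.
#' @param accession label.
#' @param standardize passed to [propertyTable()].
#' @return A [PropertyTable-class].
#' @export
genPropertyTable <- function(seed = 1L, ncaaCodes = character(0),
                             accession = sprintf("SYNT%06d", seed),
                             standardize = TRUE) {
  set.seed(seed)
  codes <- c(AA3, ncaaCodes)
  vals <- structure(stats::rnorm(length(codes)), names = codes)
  propertyTable(vals, accession = accession, source = "synthetic",
                standardize = standardize)
}
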
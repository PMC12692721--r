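## The 16-letter protein-block structural alphabet: reference coordinates
## rebuilt from vendored dihedral definitions, and fragment RMSD profiles.

#' Rebuild reference pentapeptide coordinates from block dihedrals
#'
#' Builds the 15 backbone atoms (N, CA, C of five residues) of one block
#' from its eight consecutive dihedrals (psi1, phi2, psi2, phi3, psi3,
#' phi4, psi4, phi5) with ideal bond geometry and trans peptide bonds.
#'
#' @param dihedrals numeric vector of 8 angles in degrees.
#' @return 15 x 3 coordinate matrix, Angstrom.
#' @export
buildPBReferenceCoords <- function(dihedrals) {
  if (length(dihedrals) != 8)
    stop("exactly 8 dihedrals (psi1, phi2, ..., psi4, phi5) required")
  psi <- c(dihedrals[c(1, 3, 5, 7)], 0)   # psi5 unused by the builder
  phi <- c(0, dihedrals[c(2, 4, 6, 8)])   # phi1 unused by the builder
  flattenBackbone(buildBackbone(phi, psi))
}

#' Load the protein-block reference set
#'
#' Reads the vendored 16 x 8 dihedral table of the published structural
#' alphabet and rebuilds all 16 reference fragments.
#'
#' @param dihedralFile path to a TSV with columns block, psi1, phi2, ...,
#'   phi5; defaults to the vendored table.
#' @return A [ProteinBlockSet-class].
#' @export
proteinBlockSet <- function(dihedralFile = ffExtdata("pb_dihedrals.tsv")) {
  tab <- utils::read.table(dihedralFile, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  dih <- as.matrix(tab[, -1])
  rownames(dih) <- tab$block
  coords <- lapply(seq_len(nrow(dih)), function(i)
    buildPBReferenceCoords(dih[i, ]))
  names(coords) <- tab$block
  new("ProteinBlockSet", labels = tab$block, dihedrals = dih,
      refCoords = coords)
}

#' Per-position fragment RMSD profiles against all 16 blocks
#'
#' For each residue position whose pentapeptide window (the position and
#' two flanking residues on each side) is fully resolved, computes the
#' Kabsch RMSD of the 15-atom backbone fragment to each of the 16 block
#' references. Positions within two residues of either chain end, or whose
#' window spans unresolved residues, are returned as NA rows.
#'
#' @param chain a [ProteinChain-class] with backbone coordinates.
#' @param pbset a [ProteinBlockSet-class].
#' @return numeric matrix `n x 16`, columns named by block letter.
#' @export
fragmentRmsdVectors <- function(chain, pbset = proteinBlockSet()) {
  bb <- chainBackbone(chain)
  n <- chainLength(chain)
  if (!length(bb)) stop("chain has no backbone coordinates")
  out <- matrix(NA_real_, nrow = n, ncol = 16,
                dimnames = list(NULL, pbset@labels))
  if (n < 5) return(out)
  res <- chainResolved(chain)
  for (p in 3:(n - 2)) {
    win <- (p - 2):(p + 2)
    if (!all(res[win])) next
    frag <- flattenBackbone(bb, win)
    if (!all(is.finite(frag))) next
    out[p, ] <- vapply(pbset@refCoords, function(r)
      as.numeric(kabschRmsd(frag, r)), 0)
  }
  out
}

#' Assigned block letter per position
#'
#' The block whose reference fragment is nearest (minimal RMSD) to the
#' local pentapeptide; NA where the RMSD profile is undefined.
#'
#' @param rmsdVectors matrix from [fragmentRmsdVectors()].
#' @return character vector of block letters with NA at undefined positions.
#' @export
assignPBLetters <- function(rmsdVectors) {
  apply(rmsdVectors, 1, function(v) {
    if (anyNA(v)) NA_character_ else colnames(rmsdVectors)[which.min(v)]
  })
}
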
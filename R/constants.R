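## Shared constants: class sets, residue code tables, ideal backbone geometry.

#' Eight-state secondary structure labels
#'
#' The eight per-residue states assigned by DSSP, in the fixed order used
#' throughout the package: H (alpha-helix), G (3-10 helix), I (pi-helix),
#' E (extended strand), B (isolated beta-bridge), T (hydrogen-bonded turn),
#' S (bend), C (coil/irregular).
#' @export
LABELS8 <- c("H", "G", "I", "E", "B", "T", "S", "C")

#' Three-state secondary structure labels
#' @export
LABELS3 <- c("H", "E", "C")

#' Mask label for structurally unresolved residues
#'
#' A ninth, technical label marking residues without resolved structure.
#' Positions carrying it are excluded from model fitting and from every
#' evaluation metric.
#' @export
MASK_LABEL <- "-"

## canonical residues, one- and three-letter
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
names(AA3) <- AA1
AA3TO1 <- structure(AA1, names = AA3)

## protein block letters
PB_LETTERS <- letters[1:16]

## ideal backbone geometry (Engh-Huber-type constants), Angstrom / degrees
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
OMEGA_TRANS <- 180

ffExtdata <- function(file) {
  system.file("extdata", file, package = "featureforge", mustWork = TRUE)
}
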
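## Backbone geometry: internal-coordinate chain building (NeRF), dihedral
## measurement, and least-squares superposition.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v * v))

## Place atom D given A-B-C, bond length |C-D|, angle B-C-D and torsion
## A-B-C-D (degrees). Standard natural-extension reference frame.
placeAtom <- function(A, B, C, bond, angleDeg, torsionDeg) {
  th <- angleDeg * pi / 180
  chi <- torsionDeg * pi / 180
  bc <- unit3(C - B)
  n <- unit3(cross3(B - A, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(chi),
          -bond * sin(th) * sin(chi))
  C + cbind(bc, m, n) %*% d2
}

#' Measure a dihedral angle
#'
#' Torsion angle defined by four points, in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric xyz vectors.
#' @return angle in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Build backbone coordinates from phi/psi dihedrals
#'
#' Builds N, CA, C atoms for `n` residues from per-residue phi/psi (and a
#' constant trans omega) using ideal bond lengths and angles
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom; N-CA-C 111.2, CA-C-N 116.2,
#' C-N-CA 121.7 degrees). `phi[1]` and `psi[n]` are not used.
#'
#' @param phi,psi numeric vectors of equal length `n`, degrees.
#' @param omega peptide-bond torsion, degrees (trans by default).
#' @return array `n x 3 x 3` (residue, atom N/CA/C, xyz), Angstrom.
#' @export
buildBackbone <- function(phi, psi, omega = OMEGA_TRANS) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  xyz <- array(NA_real_, dim = c(n, 3, 3),
               dimnames = list(NULL, c("N", "CA", "C"), c("x", "y", "z")))
  xyz[1, 1, ] <- c(0, 0, 0)
  xyz[1, 2, ] <- c(BOND_N_CA, 0, 0)
  th <- ANGLE_N_CA_C * pi / 180
  xyz[1, 3, ] <- xyz[1, 2, ] + BOND_CA_C * c(-cos(th), sin(th), 0)
  if (n == 1) return(xyz)
  for (i in seq_len(n - 1)) {
    Ni <- xyz[i, 1, ]; CAi <- xyz[i, 2, ]; Ci <- xyz[i, 3, ]
    N2 <- placeAtom(Ni, CAi, Ci, BOND_C_N, ANGLE_CA_C_N, psi[i])
    CA2 <- placeAtom(CAi, Ci, N2, BOND_N_CA, ANGLE_C_N_CA, omega)
    C2 <- placeAtom(Ci, N2, CA2, BOND_CA_C, ANGLE_N_CA_C, phi[i + 1])
    xyz[i + 1, 1, ] <- N2
    xyz[i + 1, 2, ] <- CA2
    xyz[i + 1, 3, ] <- C2
  }
  xyz
}

## Flatten an n x 3 x 3 backbone array (or a residue range of it) into the
## (N1, CA1, C1, N2, ...) x 3 coordinate matrix used for superposition.
flattenBackbone <- function(backbone, residues = seq_len(dim(backbone)[1])) {
  m <- matrix(NA_real_, nrow = 3 * length(residues), ncol = 3)
  for (k in seq_along(residues)) {
    m[3 * k - 2, ] <- backbone[residues[k], 1, ]
    m[3 * k - 1, ] <- backbone[residues[k], 2, ]
    m[3 * k, ] <- backbone[residues[k], 3, ]
  }
  m
}

#' Minimal RMSD after optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of two equally sized point sets over proper
#' rotations and translations (reflections excluded), returning the
#' root-mean-square deviation in the units of the input.
#'
#' Degenerate inputs (all points collinear, so the rotation is not unique)
#' still return the minimal RMSD, with attribute `degenerate = TRUE`.
#'
#' @param X,Y numeric `n x 3` matrices, `n >= 3`.
#' @return RMSD (scalar); attribute `degenerate` flags rank-deficient cases.
#' @export
kabschRmsd <- function(X, Y) {
  if (!is.matrix(X) || !is.matrix(Y) || any(dim(X) != dim(Y)) ||
      ncol(X) != 3 || nrow(X) < 3)
    stop("X and Y must be equal-shape n x 3 matrices with n >= 3")
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop("coordinates must be finite")
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(tcrossprod(s$v, s$u)))
  ## proper rotation mapping Xc onto Yc (reflection excluded), then the
  ## residuals directly -- avoids the cancellation of the E0 - 2*sum(S) form
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  out <- sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
  if (s$d[2] < 1e-8 * max(s$d[1], 1e-12))
    attr(out, "degenerate") <- TRUE
  out
}
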
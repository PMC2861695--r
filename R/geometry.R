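#' Backbone geometry constants
#'
#' Standard backbone bond lengths and angles used everywhere a chain is
#' built or constrained: N-CA 1.46 A, CA-C 1.53 A, C-N(next) 1.33 A;
#' angles C-N-CA 121.7, N-CA-C 111.0, CA-C-N 116.2 degrees; the peptide
#' bond torsion (omega) is held trans at 180 degrees.
#'
#' @return named list of constants
#' @export
backbone_geometry <- function() {
  list(
    bond_n_ca  = 1.46,
    bond_ca_c  = 1.53,
    bond_c_n   = 1.33,
    ang_c_n_ca = 121.7,
    ang_n_ca_c = 111.0,
    ang_ca_c_n = 116.2,
    omega      = 180.0,
    bond_tol   = 0.03)
}

#' Canonical dihedral angles per secondary-structure class
#' @keywords internal
.ss_dihedrals <- list(
  ALPHA = c(phi = -57, psi = -47),
  BETA  = c(phi = -120, psi = 130),
  PPII  = c(phi = -75, psi = 145),
  TURN  = c(phi = 60, psi = 30))

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Place an atom from three predecessors (NeRF construction)
#'
#' Given positions a, b, c, places d with |c-d| = bond, angle b-c-d = theta
#' and torsion a-b-c-d = chi (degrees, IUPAC sign convention).
#' @keywords internal
.place_atom <- function(a, b, c, bond, theta, chi) {
  th <- .deg2rad(theta); ch <- .deg2rad(chi)
  d_local <- c(-bond * cos(th),
               bond * sin(th) * cos(ch),
               -bond * sin(th) * sin(ch))
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nv <- c(ab[2] * bc[3] - ab[3] * bc[2],
          ab[3] * bc[1] - ab[1] * bc[3],
          ab[1] * bc[2] - ab[2] * bc[1])
  # degenerate when a, b, c are collinear
  if (sqrt(sum(nv^2)) < 1e-10) stop("collinear atoms in chain construction")
  nv <- nv / sqrt(sum(nv^2))
  m2 <- c(nv[2] * bc[3] - nv[3] * bc[2],
          nv[3] * bc[1] - nv[1] * bc[3],
          nv[1] * bc[2] - nv[2] * bc[1])
  M <- cbind(bc, m2, nv)
  as.numeric(c + M %*% d_local)
}

#' Build N-CA-C backbone coordinates from dihedral angles
#'
#' Constructs a backbone chain with standard bond geometry and the given
#' per-residue torsions. Row order is N1, CA1, C1, N2, CA2, C2, ...
#'
#' @param phi,psi numeric vectors of length `n_res` (degrees); `phi[1]` and
#'   `psi[n_res]` are unused (undefined at the termini)
#' @param n_res number of residues (>= 2)
#' @return numeric matrix (3 * n_res) x 3 of coordinates (Angstrom)
#' @export
build_backbone <- function(phi, psi, n_res = length(phi)) {
  stopifnot(n_res >= 2, length(phi) >= n_res, length(psi) >= n_res)
  g <- backbone_geometry()
  xyz <- matrix(0, nrow = 3 * n_res, ncol = 3)
  # first residue laid out in the xy plane
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(g$bond_n_ca, 0, 0)
  th <- .deg2rad(g$ang_n_ca_c)
  xyz[3, ] <- xyz[2, ] + g$bond_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_res - 1)) {
    b <- 3 * (i - 1)
    # N(i+1): torsion psi_i about CA(i)-C(i)
    xyz[b + 4, ] <- .place_atom(xyz[b + 1, ], xyz[b + 2, ], xyz[b + 3, ],
                                g$bond_c_n, g$ang_ca_c_n, psi[i])
    # CA(i+1): omega (trans)
    xyz[b + 5, ] <- .place_atom(xyz[b + 2, ], xyz[b + 3, ], xyz[b + 4, ],
                                g$bond_n_ca, g$ang_c_n_ca, g$omega)
    # C(i+1): torsion phi_{i+1} about N(i+1)-CA(i+1)
    xyz[b + 6, ] <- .place_atom(xyz[b + 3, ], xyz[b + 4, ], xyz[b + 5, ],
                                g$bond_ca_c, g$ang_n_ca_c, phi[i + 1])
  }
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

#' Torsion angle of four points
#'
#' @param p1,p2,p3,p4 numeric xyz vectors
#' @return angle in degrees in (-180, 180], IUPAC sign convention; `NA`
#'   when a triplet is collinear
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-14 || sum(n2^2) < 1e-14) return(NA_real_)
  b2n <- b2 / sqrt(sum(b2^2))
  m1 <- c(n1[2] * b2n[3] - n1[3] * b2n[2],
          n1[3] * b2n[1] - n1[1] * b2n[3],
          n1[1] * b2n[2] - n1[2] * b2n[1])
  ang <- .rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Radius of gyration of a set of coordinates
#'
#' Mass-weighted root-mean-square distance from the centre of mass.
#' Coordinates must be unwrapped (minimum-image contiguous).
#'
#' @param coords numeric n x 3 matrix
#' @param masses per-bead masses (default uniform)
#' @return radius of gyration in Angstrom
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop("empty frame")
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  stopifnot(length(masses) == nrow(coords), all(masses > 0))
  com <- colSums(coords * masses) / sum(masses)
  d2 <- rowSums(sweep(coords, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' Unwrap a chain across periodic boundaries
#'
#' Reconstructs contiguous chain coordinates from wrapped positions by
#' walking the chain and applying the minimum-image displacement between
#' consecutive beads.
#'
#' @param coords wrapped n x 3 coordinates
#' @param box periodic box edge (Angstrom); `Inf` returns coords unchanged
#' @return unwrapped n x 3 coordinates
#' @export
unwrap_chain <- function(coords, box) {
  coords <- as.matrix(coords)
  if (!is.finite(box)) return(coords)
  out <- coords
  for (i in seq_len(nrow(coords) - 1)) {
    d <- coords[i + 1, ] - coords[i, ]
    d <- d - box * round(d / box)
    out[i + 1, ] <- out[i, ] + d
  }
  out
}

#' Wrap coordinates into the periodic box [0, L)
#' @param coords n x 3 coordinates
#' @param box box edge
#' @export
wrap_coords <- function(coords, box) {
  if (!is.finite(box)) return(as.matrix(coords))
  m <- as.matrix(coords) %% box
  m[m == box] <- 0
  m
}
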
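#' Ideal backbone geometry parameters
#'
#' Bond lengths, bond angles and atomic masses used to translate a
#' dihedral assignment into Cartesian backbone coordinates. Defaults are
#' Engh-Huber-style ideal values (N-CA 1.458, CA-C 1.525, C-N 1.329
#' Angstrom; N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7 degrees) plus a
#' standard carbonyl (C=O 1.231 Angstrom, CA-C-O 120.8 degrees).
#'
#' @param bond_n_ca,bond_ca_c,bond_c_n,bond_c_o Bond lengths, Angstrom;
#'   must lie in (1, 2).
#' @param angle_n_ca_c,angle_ca_c_n,angle_c_n_ca,angle_ca_c_o Bond angles,
#'   degrees; must lie in (90, 140).
#' @param masses Named numeric vector of atomic masses (Da) for the four
#'   backbone atoms N, CA, C, O.
#' @return An object of class \code{backbone_geometry}.
#' @export
backbone_geometry <- function(bond_n_ca = 1.458, bond_ca_c = 1.525,
                              bond_c_n = 1.329, bond_c_o = 1.231,
                              angle_n_ca_c = 111.2, angle_ca_c_n = 116.2,
                              angle_c_n_ca = 121.7, angle_ca_c_o = 120.8,
                              masses = c(N = 14.007, CA = 12.011,
                                         C = 12.011, O = 15.999)) {
  lens <- c(bond_n_ca, bond_ca_c, bond_c_n, bond_c_o)
  angs <- c(angle_n_ca_c, angle_ca_c_n, angle_c_n_ca, angle_ca_c_o)
  if (any(lens <= 1 | lens >= 2)) stop("bond lengths must lie in (1, 2) Angstrom")
  if (any(angs <= 90 | angs >= 140)) stop("bond angles must lie in (90, 140) degrees")
  if (!all(c("N", "CA", "C", "O") %in% names(masses)) || any(masses <= 0))
    stop("masses must be positive and named N, CA, C, O")
  structure(list(bond_n_ca = bond_n_ca, bond_ca_c = bond_ca_c,
                 bond_c_n = bond_c_n, bond_c_o = bond_c_o,
                 angle_n_ca_c = angle_n_ca_c, angle_ca_c_n = angle_ca_c_n,
                 angle_c_n_ca = angle_c_n_ca, angle_ca_c_o = angle_ca_c_o,
                 masses = masses[c("N", "CA", "C", "O")]),
            class = "backbone_geometry")
}

# Atom bookkeeping table shared by frames and trajectories: one row per
# backbone atom in residue order N, CA, C, O.
.atom_table <- function(residues) {
  n <- nrow(residues)
  data.frame(residue_number = rep(residues$number, each = 4L),
             residue_type = rep(residues$type, each = 4L),
             atom = rep(c("N", "CA", "C", "O"), n))
}

# Core chain-extension: one frame of coordinates (4*n_res x 3 matrix) from
# per-residue (phi, psi, omega) vectors. phi[1] and psi[n] do not affect
# chain extension; psi[n] still orients the terminal carbonyl O.
.build_frame <- function(phi, psi, omega, geom) {
  n <- length(phi)
  xyz <- matrix(NA_real_, nrow = 4L * n, ncol = 3L)
  idx <- function(i, atom) (i - 1L) * 4L + match(atom, c("N", "CA", "C", "O"))
  N <- c(0, 0, 0)
  CA <- c(geom$bond_n_ca, 0, 0)
  a <- geom$angle_n_ca_c * pi / 180
  C <- CA + geom$bond_ca_c * c(-cos(a), sin(a), 0)
  xyz[idx(1L, "N"), ] <- N
  xyz[idx(1L, "CA"), ] <- CA
  xyz[idx(1L, "C"), ] <- C
  for (i in seq_len(n)) {
    Ni <- xyz[idx(i, "N"), ]; CAi <- xyz[idx(i, "CA"), ]; Ci <- xyz[idx(i, "C"), ]
    xyz[idx(i, "O"), ] <- .place_atom(Ni, CAi, Ci, geom$bond_c_o,
                                      geom$angle_ca_c_o, wrap180(psi[i] + 180))
    if (i < n) {
      Nn <- .place_atom(Ni, CAi, Ci, geom$bond_c_n, geom$angle_ca_c_n, psi[i])
      CAn <- .place_atom(CAi, Ci, Nn, geom$bond_n_ca, geom$angle_c_n_ca,
                         omega[i + 1L])
      Cn <- .place_atom(Ci, Nn, CAn, geom$bond_ca_c, geom$angle_n_ca_c,
                        phi[i + 1L])
      xyz[idx(i + 1L, "N"), ] <- Nn
      xyz[idx(i + 1L, "CA"), ] <- CAn
      xyz[idx(i + 1L, "C"), ] <- Cn
    }
  }
  xyz
}

#' Build ideal-geometry backbone coordinates from a dihedral assignment
#'
#' Places N, CA, C and carbonyl O atoms for every residue of a
#' \code{peptide_model} by sequential internal-coordinate chain extension,
#' using the model's per-residue (phi, psi, omega) assignment and ideal
#' bond lengths/angles. Re-measuring dihedrals from the output reproduces
#' the assignment (interior residues) to well below 1e-6 degrees.
#'
#' @param model A \code{peptide_model}.
#' @param geometry A \code{backbone_geometry} (default: ideal values).
#' @return A \code{backbone_trajectory} with a single frame.
#' @examples
#' bb <- build_backbone(mucin_model())
#' compute_dihedrals(bb)
#' @export
build_backbone <- function(model, geometry = backbone_geometry()) {
  stopifnot(inherits(model, "peptide_model"),
            inherits(geometry, "backbone_geometry"))
  d <- model$dihedrals
  xyz <- .build_frame(d$phi, d$psi, d$omega, geometry)
  backbone_trajectory(array(xyz, dim = c(1L, nrow(xyz), 3L)),
                      model$residues, geometry)
}

#' Build backbone coordinates for every frame of a dihedral trajectory
#'
#' Applies the ideal-geometry chain extension of \code{\link{build_backbone}}
#' frame by frame, turning a (phi, psi) trajectory into Cartesian backbone
#' coordinates (omega fixed at 180). Used to derive radius-of-gyration
#' series from synthetic dihedral ensembles.
#'
#' @param traj A \code{dihedral_trajectory}.
#' @param geometry A \code{backbone_geometry}.
#' @return A \code{backbone_trajectory} with one frame per trajectory frame.
#' @export
build_backbone_trajectory <- function(traj, geometry = backbone_geometry()) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  n_frames <- nrow(traj$phi)
  n_res <- ncol(traj$phi)
  omega <- rep(180, n_res)
  coords <- array(NA_real_, dim = c(n_frames, 4L * n_res, 3L))
  for (f in seq_len(n_frames)) {
    phi <- traj$phi[f, ]; psi <- traj$psi[f, ]
    # termini may carry NA dihedrals; chain extension never reads phi[1],
    # and an NA psi[n] only orients the terminal O -- default it to 145
    phi[1L] <- if (is.na(phi[1L])) -75 else phi[1L]
    psi[n_res] <- if (is.na(psi[n_res])) 145 else psi[n_res]
    coords[f, , ] <- .build_frame(phi, psi, omega, geometry)
  }
  backbone_trajectory(coords, traj$residues, geometry, time_ns = traj$time_ns)
}

#' Helix parameters from consecutive CA positions
#'
#' Fits a helical axis through consecutive C-alpha atoms and reports the
#' mean twist per residue (degrees; negative = left-handed), the rise per
#' residue along the axis (Angstrom) and the number of residues per turn
#' (360 / |twist|). The axis direction is estimated from the second
#' differences of the CA trace (which are perpendicular to the axis of an
#' ideal helix) and oriented along the chain so that the rise is positive.
#'
#' An ideal polyproline-II chain (all residues at (-75, 145)) comes out
#' left-handed with three residues per turn; a canonical alpha helix
#' (-57, -47) right-handed with about 3.6.
#'
#' @param x A \code{backbone_trajectory} (first frame is used), or a
#'   numeric matrix of CA coordinates (rows = residues).
#' @param frame Frame index when \code{x} is a trajectory.
#' @return List with \code{twist} (deg/residue, signed), \code{rise}
#'   (Angstrom/residue), \code{residues_per_turn} and \code{handedness}
#'   ("left" or "right").
#' @export
helix_parameters <- function(x, frame = 1L) {
  ca <- if (inherits(x, "backbone_trajectory")) {
    x$coords[frame, x$atoms$atom == "CA", , drop = TRUE]
  } else as.matrix(x)
  m <- nrow(ca)
  if (is.null(m) || m < 6L) stop("need at least 6 CA positions for a helix fit")
  d <- ca[-1L, , drop = FALSE] - ca[-m, , drop = FALSE]          # bond vectors
  A <- d[-nrow(d), , drop = FALSE] - d[-1L, , drop = FALSE]      # second differences
  if (any(sqrt(rowSums(A^2)) < 1e-8))
    stop("degenerate (collinear) CA trace: helix fit undefined")
  e <- ca[m, ] - ca[1L, ]                                        # chain direction
  acc <- c(0, 0, 0)
  for (i in seq_len(nrow(A) - 1L)) {
    ci <- .cross3(A[i, ], A[i + 1L, ])
    s <- sum(ci * e)
    if (abs(s) > 1e-10) acc <- acc + sign(s) * ci
  }
  u <- if (sqrt(sum(acc^2)) > 1e-8) .unit3(acc, "helix axis") else .unit3(e, "helix axis")
  rise <- mean(d %*% u)
  if (rise < 0) { u <- -u; rise <- -rise }
  # signed rotation of the radial second-difference vectors about the axis
  proj <- A - (A %*% u) %*% t(u)
  tw <- numeric(nrow(proj) - 1L)
  for (i in seq_along(tw)) {
    a1 <- proj[i, ]; a2 <- proj[i + 1L, ]
    tw[i] <- atan2(sum(.cross3(a1, a2) * u), sum(a1 * a2))
  }
  twist <- atan2(mean(sin(tw)), mean(cos(tw))) * 180 / pi
  if (abs(twist) < 1e-9) stop("zero twist: CA trace is not helical")
  list(twist = twist, rise = rise,
       residues_per_turn = 360 / abs(twist),
       handedness = if (twist < 0) "left" else "right")
}
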
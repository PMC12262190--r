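#' Backbone coordinate trajectory
#'
#' Container for per-frame Cartesian coordinates of the backbone heavy
#' atoms (N, CA, C, O) of a peptide. Frames share one atom table and one
#' set of atomic masses.
#'
#' @param coords Numeric array, dim = (n_frames, n_atoms, 3), Angstrom.
#' @param residues Data frame with columns \code{number}, \code{type},
#'   \code{glycosylated} (one row per residue).
#' @param geometry \code{backbone_geometry} supplying atomic masses.
#' @param time_ns Optional per-frame times (ns), strictly increasing.
#' @return Object of class \code{backbone_trajectory} with fields
#'   \code{coords}, \code{atoms}, \code{residues}, \code{masses},
#'   \code{time_ns}.
#' @export
backbone_trajectory <- function(coords, residues,
                                geometry = backbone_geometry(),
                                time_ns = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3L] != 3L)
    stop("coords must be an array of dim (n_frames, n_atoms, 3)")
  atoms <- .atom_table(residues)
  if (dim(coords)[2L] != nrow(atoms))
    stop("coords has ", dim(coords)[2L], " atoms; atom table expects ",
         nrow(atoms))
  if (!is.null(time_ns)) {
    if (length(time_ns) != dim(coords)[1L])
      stop("time_ns length must equal n_frames")
    if (any(diff(time_ns) <= 0)) stop("time_ns must be strictly increasing")
  }
  structure(list(coords = coords, atoms = atoms, residues = residues,
                 masses = geometry$masses, time_ns = time_ns),
            class = "backbone_trajectory")
}

#' @export
print.backbone_trajectory <- function(x, ...) {
  cat("backbone_trajectory:", dim(x$coords)[1L], "frame(s),",
      nrow(x$residues), "residues,", dim(x$coords)[2L], "atoms\n")
  invisible(x)
}

#' Dihedral-angle trajectory
#'
#' The package's central exchange object: per-frame, per-residue backbone
#' (phi, psi) pairs in degrees, wrapped to [-180, 180). Chain termini
#' carry NA where a dihedral is undefined (phi of the first residue, psi
#' of the last).
#'
#' @param phi,psi Numeric matrices (n_frames x n_residues), degrees.
#' @param residues Data frame with columns \code{number}, \code{type},
#'   \code{glycosylated}.
#' @param time_ns Optional strictly increasing per-frame times (ns).
#' @return Object of class \code{dihedral_trajectory}.
#' @export
dihedral_trajectory <- function(phi, psi, residues, time_ns = NULL) {
  phi <- as.matrix(phi); psi <- as.matrix(psi)
  if (!identical(dim(phi), dim(psi)))
    stop("phi and psi must have identical dimensions")
  if (ncol(phi) != nrow(residues))
    stop("number of residue columns does not match the residue table")
  if (!is.null(time_ns)) {
    if (length(time_ns) != nrow(phi)) stop("time_ns length must equal n_frames")
    if (any(diff(time_ns) <= 0)) stop("time_ns must be strictly increasing")
  }
  structure(list(phi = wrap180(phi), psi = wrap180(psi),
                 residues = residues, time_ns = time_ns),
            class = "dihedral_trajectory")
}

#' @export
print.dihedral_trajectory <- function(x, ...) {
  cat("dihedral_trajectory:", nrow(x$phi), "frames x",
      ncol(x$phi), "residues",
      if (!is.null(x$time_ns)) sprintf("(%.4g-%.4g ns)", min(x$time_ns),
                                       max(x$time_ns)) else "", "\n")
  invisible(x)
}

#' @export
summary.dihedral_trajectory <- function(object, ...) {
  cat("dihedral_trajectory:", nrow(object$phi), "frames,",
      ncol(object$phi), "residues\n")
  cat("circular mean phi/psi per residue:\n")
  cmean <- function(m) wrap180(atan2(colMeans(sin(m * pi / 180), na.rm = TRUE),
                                     colMeans(cos(m * pi / 180), na.rm = TRUE)) * 180 / pi)
  print(data.frame(residue = object$residues$number,
                   type = object$residues$type,
                   glycosylated = object$residues$glycosylated,
                   phi = round(cmean(object$phi), 1),
                   psi = round(cmean(object$psi), 1)), row.names = FALSE)
  invisible(object)
}

#' Measure backbone dihedrals from Cartesian coordinates
#'
#' Computes phi_i from C(i-1)-N(i)-CA(i)-C(i) and psi_i from
#' N(i)-CA(i)-C(i)-N(i+1) for every frame. Termini lacking a neighbour get
#' NA; downstream histograms drop those entries.
#'
#' @param traj A \code{backbone_trajectory} with at least 2 residues.
#' @return A \code{dihedral_trajectory}.
#' @export
compute_dihedrals <- function(traj) {
  stopifnot(inherits(traj, "backbone_trajectory"))
  n_res <- nrow(traj$residues)
  if (n_res < 2L) stop("need at least 2 residues to define dihedrals")
  n_frames <- dim(traj$coords)[1L]
  iN <- which(traj$atoms$atom == "N")
  iCA <- which(traj$atoms$atom == "CA")
  iC <- which(traj$atoms$atom == "C")
  phi <- matrix(NA_real_, n_frames, n_res)
  psi <- matrix(NA_real_, n_frames, n_res)
  for (f in seq_len(n_frames)) {
    x <- traj$coords[f, , ]
    for (i in seq_len(n_res)) {
      if (i > 1L)
        phi[f, i] <- dihedral_angle(x[iC[i - 1L], ], x[iN[i], ],
                                    x[iCA[i], ], x[iC[i], ])
      if (i < n_res)
        psi[f, i] <- dihedral_angle(x[iN[i], ], x[iCA[i], ],
                                    x[iC[i], ], x[iN[i + 1L], ])
    }
  }
  dihedral_trajectory(phi, psi, traj$residues, time_ns = traj$time_ns)
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the atoms from their centre
#' of mass: Rg = sqrt[(1/M) * sum_i m_i * |r_i - R|^2], with R the
#' mass-weighted centroid and M the total mass. Computed over the backbone
#' heavy atoms N, CA, C, O with standard atomic masses.
#'
#' @param coords Numeric matrix (n_atoms x 3), Angstrom.
#' @param masses Positive atomic masses (Da), recycled to n_atoms.
#' @return Rg in Angstrom.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)))  # 1.0
#' @export
radius_of_gyration <- function(coords, masses = 1) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least 2 atoms")
  m <- rep_len(masses, nrow(coords))
  if (any(m <= 0) || sum(m) <= 0) stop("masses must be positive")
  ctr <- colSums(coords * m) / sum(m)
  dev <- sweep(coords, 2L, ctr)
  sqrt(sum(m * rowSums(dev^2)) / sum(m))
}

#' Per-frame radius-of-gyration series from a backbone trajectory
#'
#' @param traj A \code{backbone_trajectory}.
#' @return Object of class \code{rg_series}: list with numeric \code{rg}
#'   (Angstrom, one value per frame) and optional \code{time_ns}.
#' @export
rg_series <- function(traj) {
  stopifnot(inherits(traj, "backbone_trajectory"))
  m <- traj$masses[traj$atoms$atom]
  rg <- vapply(seq_len(dim(traj$coords)[1L]), function(f)
    radius_of_gyration(traj$coords[f, , ], m), numeric(1))
  structure(list(rg = rg, time_ns = traj$time_ns), class = "rg_series")
}

#' @export
print.rg_series <- function(x, ...) {
  cat("rg_series:", length(x$rg), "frames, Rg",
      sprintf("%.2f-%.2f Angstrom (mean %.2f)\n",
              min(x$rg), max(x$rg), mean(x$rg)))
  invisible(x)
}

.dihedral_table_cols <- c("frame", "time_ns", "residue_number",
                          "residue_type", "glycosylated", "phi", "psi")

#' Read and write tabular dihedral trajectories
#'
#' Tab-separated text, one row per (frame, residue), columns
#' \code{frame, time_ns, residue_number, residue_type, glycosylated, phi,
#' psi}, with a mandatory header. Angles are written at full double
#' precision so that a write/read cycle round-trips exactly; on read,
#' angles are normalised into [-180, 180).
#'
#' @param traj A \code{dihedral_trajectory}.
#' @param path File path.
#' @return \code{write_dihedral_table} returns \code{path} invisibly;
#'   \code{read_dihedral_table} returns a \code{dihedral_trajectory}.
#' @export
write_dihedral_table <- function(traj, path) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  n_frames <- nrow(traj$phi); n_res <- ncol(traj$phi)
  tab <- data.frame(
    frame = rep(seq_len(n_frames), each = n_res),
    time_ns = if (is.null(traj$time_ns)) NA_real_
              else rep(traj$time_ns, each = n_res),
    residue_number = rep(traj$residues$number, n_frames),
    residue_type = rep(traj$residues$type, n_frames),
    glycosylated = rep(traj$residues$glycosylated, n_frames),
    phi = sprintf("%.17g", as.vector(t(traj$phi))),
    psi = sprintf("%.17g", as.vector(t(traj$psi))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dihedral_table
#' @export
read_dihedral_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.dihedral_table_cols, names(tab))
  if (length(missing))
    stop("dihedral table is missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(is.na(tab$frame) | is.na(tab$residue_number) |
                 is.na(suppressWarnings(as.numeric(tab$phi))) |
                 is.na(suppressWarnings(as.numeric(tab$psi))))
  if (length(bad))
    stop("malformed dihedral table row(s) at line(s): ",
         paste(bad[seq_len(min(5, length(bad)))] + 1L, collapse = ", "))
  frames <- sort(unique(tab$frame))
  tab <- tab[order(tab$frame, match(tab$residue_number,
                                    unique(tab$residue_number))), ]
  first <- tab[tab$frame == frames[1L], ]
  residues <- data.frame(number = first$residue_number,
                         type = first$residue_type,
                         glycosylated = as.logical(first$glycosylated))
  n_res <- nrow(residues)
  if (nrow(tab) != n_res * length(frames))
    stop("dihedral table is ragged: frames carry unequal residue counts")
  phi <- matrix(wrap180(as.numeric(tab$phi)), ncol = n_res, byrow = TRUE)
  psi <- matrix(wrap180(as.numeric(tab$psi)), ncol = n_res, byrow = TRUE)
  tns <- tab$time_ns[match(frames, tab$frame)]
  dihedral_trajectory(phi, psi, residues,
                      time_ns = if (all(is.na(tns))) NULL else tns)
}
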
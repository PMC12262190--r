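#' 2D dihedral histogram over the full (phi, psi) torus
#'
#' Partitions the sampled (phi, psi) pairs into uniform bins covering
#' [-180, 180) x [-180, 180) and normalises counts to probabilities.
#' Pairs are pooled over frames and residues (NA termini dropped) unless a
#' residue filter is given.
#'
#' @param traj A \code{dihedral_trajectory}.
#' @param n_bins Bins per axis (default 72, i.e. 5-degree bins).
#' @param residues Optional residue numbers to pool over.
#' @return List with \code{P} (n_bins x n_bins probability matrix, rows =
#'   phi bins), \code{phi_edges}, \code{psi_edges}, \code{n_samples}.
#' @export
histogram2d <- function(traj, n_bins = 72L, residues = NULL) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  if (n_bins < 2L) stop("n_bins must be >= 2")
  keep <- if (is.null(residues)) seq_len(ncol(traj$phi))
          else which(traj$residues$number %in% residues)
  if (!length(keep)) stop("no residues selected")
  phi <- as.vector(traj$phi[, keep]); psi <- as.vector(traj$psi[, keep])
  ok <- !is.na(phi) & !is.na(psi)
  phi <- phi[ok]; psi <- psi[ok]
  if (!length(phi)) stop("trajectory contains no defined (phi, psi) pairs")
  ix <- pmin(floor((phi + 180) / 360 * n_bins) + 1L, n_bins)
  iy <- pmin(floor((psi + 180) / 360 * n_bins) + 1L, n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  tab <- table(factor(ix, levels = seq_len(n_bins)),
               factor(iy, levels = seq_len(n_bins)))
  counts[] <- as.integer(tab)
  edges <- seq(-180, 180, length.out = n_bins + 1L)
  list(P = counts / length(phi), phi_edges = edges, psi_edges = edges,
       n_samples = length(phi))
}

#' Ramachandran-like free-energy surface by Boltzmann inversion
#'
#' Converts a binned probability distribution P(phi, psi) into free
#' energies relative to the global minimum:
#' \deqn{\Delta G(\phi, \psi) = -k_B T \ln[P(\phi, \psi) / P_{max}]}
#' where P_max is the probability of the most occupied bin. The modal bin
#' has Delta-G exactly 0; empty bins are undefined and reported as +Inf.
#'
#' @param P Probability matrix from \code{\link{histogram2d}}, or a
#'   \code{dihedral_trajectory} (then binned first).
#' @param T Temperature in K (> 0; default 300, the analysis replica).
#' @param n_bins,residues Passed to \code{\link{histogram2d}} when
#'   \code{P} is a trajectory.
#' @return Object of class \code{free_energy_surface}: \code{P},
#'   \code{dG} (kcal/mol), \code{phi_edges}, \code{psi_edges}, \code{T},
#'   \code{k_B}, \code{P_max}, \code{n_samples}.
#' @examples
#' traj <- sample_ensemble(residue_ensemble_spec(c(PPII = 1)), 2000, seed = 1)
#' fes <- free_energy_surface(traj, T = 300)
#' summary(fes)
#' @export
free_energy_surface <- function(P, T = 300, n_bins = 72L, residues = NULL) {
  if (T <= 0) stop("temperature must be positive")
  if (inherits(P, "dihedral_trajectory")) {
    h <- histogram2d(P, n_bins = n_bins, residues = residues)
  } else {
    P <- as.matrix(P)
    if (abs(sum(P) - 1) > 1e-9) stop("P must be normalised (sum to 1)")
    edges <- seq(-180, 180, length.out = nrow(P) + 1L)
    h <- list(P = P, phi_edges = edges,
              psi_edges = seq(-180, 180, length.out = ncol(P) + 1L),
              n_samples = NA_integer_)
  }
  if (all(h$P == 0)) stop("all histogram bins are empty")
  P_max <- max(h$P)
  dG <- -k_boltzmann * T * log(h$P / P_max)   # empty bins -> +Inf
  dG[which(h$P == P_max)] <- 0                # exact zero at the mode
  structure(list(P = h$P, dG = dG, phi_edges = h$phi_edges,
                 psi_edges = h$psi_edges, T = T, k_B = k_boltzmann,
                 P_max = P_max, n_samples = h$n_samples),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("free_energy_surface: %dx%d bins at %g K, P_max = %.3g\n",
              nrow(x$P), ncol(x$P), x$T, x$P_max))
  cat(sprintf("  occupied bins: %d of %d; max defined dG = %.3f kcal/mol\n",
              sum(x$P > 0), length(x$P), max(x$dG[is.finite(x$dG)])))
  invisible(x)
}

#' @export
summary.free_energy_surface <- function(object, ...) {
  print(object)
  mid <- function(e) (e[-1] + e[-length(e)]) / 2
  imax <- which(object$P == object$P_max, arr.ind = TRUE)[1L, ]
  cat(sprintf("  global minimum bin centre: phi %.1f, psi %.1f -> %s\n",
              mid(object$phi_edges)[imax[1L]], mid(object$psi_edges)[imax[2L]],
              classify(mid(object$phi_edges)[imax[1L]],
                       mid(object$psi_edges)[imax[2L]])))
  invisible(object)
}

#' Plot a free-energy surface as a Ramachandran heat map
#'
#' @param x A \code{free_energy_surface}.
#' @param max_dG Cap for the colour scale (kcal/mol).
#' @param ... Passed to \code{\link[graphics]{image}}.
#' @export
plot.free_energy_surface <- function(x, max_dG = 5, ...) {
  mid <- function(e) (e[-1] + e[-length(e)]) / 2
  z <- pmin(x$dG, max_dG)
  z[!is.finite(z)] <- max_dG
  graphics::image(mid(x$phi_edges), mid(x$psi_edges), z,
                  col = grDevices::hcl.colors(64, "viridis", rev = TRUE),
                  xlab = expression(phi ~ "(deg)"),
                  ylab = expression(psi ~ "(deg)"),
                  main = sprintf("Free-energy surface (%g K)", x$T), ...)
  invisible(x)
}

#' Export a free-energy surface
#'
#' \code{write_fes_table} writes a tab-separated grid (phi_lo, phi_hi,
#' psi_lo, psi_hi, P, dG; empty bins carry dG = Inf). \code{write_fes_json}
#' writes the same content as JSON.
#'
#' @param fes A \code{free_energy_surface}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fes_table <- function(fes, path) {
  stopifnot(inherits(fes, "free_energy_surface"))
  nb_phi <- nrow(fes$P); nb_psi <- ncol(fes$P)
  tab <- data.frame(
    phi_lo = rep(fes$phi_edges[-(nb_phi + 1L)], nb_psi),
    phi_hi = rep(fes$phi_edges[-1L], nb_psi),
    psi_lo = rep(fes$psi_edges[-(nb_psi + 1L)], each = nb_phi),
    psi_hi = rep(fes$psi_edges[-1L], each = nb_phi),
    P = as.vector(fes$P), dG = as.vector(fes$dG))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fes_table
#' @export
write_fes_json <- function(fes, path) {
  stopifnot(inherits(fes, "free_energy_surface"))
  obj <- list(T = fes$T, k_B = fes$k_B, P_max = fes$P_max,
              phi_edges = fes$phi_edges, psi_edges = fes$psi_edges,
              P = fes$P, dG = ifelse(is.finite(fes$dG), fes$dG, NA))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}
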
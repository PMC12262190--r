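# Independent oracles used across the suite. These deliberately take a
# different route from the implementation they check.

# Brute-force torsion: explicit Gram-Schmidt projection onto the plane
# perpendicular to the central bond, then atan2 of the signed rotation.
oracle_dihedral <- function(p1, p2, p3, p4) {
  u <- p3 - p2
  u <- u / sqrt(sum(u^2))
  v1 <- (p1 - p2) - sum((p1 - p2) * u) * u
  v2 <- (p4 - p3) - sum((p4 - p3) * u) * u
  crossp <- c(u[2] * v1[3] - u[3] * v1[2],
              u[3] * v1[1] - u[1] * v1[3],
              u[1] * v1[2] - u[2] * v1[1])
  atan2(sum(crossp * v2), sum(v1 * v2)) * 180 / pi
}

# Closed-form probability that a wrapped normal (mean mu, sd in degrees)
# falls in the open circular interval (lo, hi), hi possibly > 180.
oracle_wrapnorm_interval <- function(mu, sd, lo, hi, K = 6) {
  p <- 0
  for (k in -K:K)
    p <- p + stats::pnorm(hi, mu + 360 * k, sd) - stats::pnorm(lo, mu + 360 * k, sd)
  p
}

# Exact region probabilities of a residue_ensemble_spec under a region
# set: per basin, the product of independent phi/psi interval masses.
oracle_region_probs <- function(spec, regions = region_set()) {
  labs <- region_labels(regions)
  out <- setNames(numeric(length(labs)), labs)
  for (b in spec$basins) {
    sd <- (180 / pi) / sqrt(b$kappa)
    for (r in seq_len(nrow(regions))) {
      out[regions$name[r]] <- out[regions$name[r]] + b$weight *
        oracle_wrapnorm_interval(b$center[1], sd, regions$phi_lo[r], regions$phi_hi[r]) *
        oracle_wrapnorm_interval(b$center[2], sd, regions$psi_lo[r], regions$psi_hi[r])
    }
  }
  out["coil"] <- 1 - sum(out[regions$name])
  out
}

# Grid quadrature of the mixture density over coarse (phi, psi) bins:
# the Boltzmann-weight oracle for the fixed-temperature sampler.
oracle_boltzmann_bins <- function(spec, n_bins = 12L, grid_step = 2) {
  grid <- seq(-180 + grid_step / 2, 180 - grid_step / 2, by = grid_step)
  g <- expand.grid(phi = grid, psi = grid)
  dens <- mixture_density(g$phi, g$psi, spec)
  bin <- function(x) pmin(floor((x + 180) / 360 * n_bins) + 1L, n_bins)
  po <- tapply(dens, list(factor(bin(g$phi), seq_len(n_bins)),
                          factor(bin(g$psi), seq_len(n_bins))), sum)
  po[is.na(po)] <- 0
  po / sum(po)
}

# Empirical coarse-bin probabilities of one residue of a trajectory.
empirical_bins <- function(traj, residue = 1L, n_bins = 12L, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(nrow(traj$phi))
  bin <- function(x) pmin(floor((x + 180) / 360 * n_bins) + 1L, n_bins)
  tab <- table(factor(bin(traj$phi[frames, residue]), seq_len(n_bins)),
               factor(bin(traj$psi[frames, residue]), seq_len(n_bins)))
  tab / sum(tab)
}

tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

# Small random rigid-body motion applied to an n x 3 coordinate matrix.
random_rigid_motion <- function(coords, seed) {
  set.seed(seed)
  ang <- stats::runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3, 3)
  Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                 sin(ang[2]), 0, cos(ang[2])), 3, 3)
  Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]),
                 cos(ang[3]), 0, 0, 0, 1), 3, 3)
  sweep(coords %*% (Rx %*% Ry %*% Rz), 2, stats::rnorm(3, 0, 10), `+`)
}
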
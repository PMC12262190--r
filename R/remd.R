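#' Geometric replica-exchange temperature ladder
#'
#' Temperatures distributed in a geometric progression between T_min and
#' T_max: T_k = T_min * (T_max/T_min)^(k/(n-1)), k = 0, ..., n-1, so that
#' consecutive ratios are constant. The two protocol-scale presets are 64
#' replicas spanning 300-455.95 K (mucin 18-mer) and 32 replicas spanning
#' 300-452.32 K (threonine tetrapeptide); the desk-scale default used by
#' the toy sampler is 8 replicas.
#'
#' @param T_min,T_max Temperature bounds (K), \code{T_max > T_min > 0}.
#' @param n_replicas Number of replicas (>= 2).
#' @return Object of class \code{replica_ladder} with field
#'   \code{temperatures}.
#' @examples
#' make_ladder(300, 455.95, 64)
#' @export
make_ladder <- function(T_min, T_max, n_replicas) {
  if (!(T_max > T_min && T_min > 0)) stop("need T_max > T_min > 0")
  n_replicas <- as.integer(n_replicas)
  if (n_replicas < 2L) stop("need at least 2 replicas")
  k <- seq_len(n_replicas) - 1L
  temps <- T_min * (T_max / T_min)^(k / (n_replicas - 1L))
  temps[1L] <- T_min
  temps[n_replicas] <- T_max
  structure(list(T_min = T_min, T_max = T_max, n_replicas = n_replicas,
                 temperatures = temps),
            class = "replica_ladder")
}

#' @export
print.replica_ladder <- function(x, ...) {
  cat(sprintf("replica_ladder: %d replicas, %.4g-%.4g K (ratio %.6f)\n",
              x$n_replicas, x$T_min, x$T_max,
              (x$T_max / x$T_min)^(1 / (x$n_replicas - 1))))
  invisible(x)
}

#' Ladder presets used by the analysis protocol
#'
#' @param name "mucin64" (64 replicas, 300-455.95 K), "tttt32"
#'   (32 replicas, 300-452.32 K) or "toy8" (8 replicas, 300-455.95 K,
#'   the desk-scale default for the toy sampler).
#' @return A \code{replica_ladder}.
#' @export
ladder_preset <- function(name = c("toy8", "mucin64", "tttt32")) {
  switch(match.arg(name),
         mucin64 = make_ladder(300, 455.95, 64L),
         tttt32 = make_ladder(300, 452.32, 32L),
         toy8 = make_ladder(300, 455.95, 8L))
}

#' Metropolis exchange probability for neighbouring replicas
#'
#' Probability of accepting a configuration swap between replicas at
#' temperatures T_i and T_j holding configurations with potential energies
#' U_i and U_j: min(1, exp[(1/kB T_i - 1/kB T_j) (U_i - U_j)]). Depends on
#' both the temperatures and the configurations; equal energies or equal
#' temperatures always exchange.
#'
#' @param U_i,U_j Potential energies (kcal/mol).
#' @param T_i,T_j Temperatures (K), positive.
#' @return Probability in [0, 1] (vectorised).
#' @export
exchange_probability <- function(U_i, U_j, T_i, T_j) {
  if (any(c(T_i, T_j) <= 0)) stop("temperatures must be positive")
  d_beta <- 1 / (k_boltzmann * T_i) - 1 / (k_boltzmann * T_j)
  pmin(1, exp(d_beta * (U_i - U_j)))
}

# total landscape energy of one configuration (n_res x 2 matrix of angles)
.config_energy <- function(phi, psi, specs, T_ref) {
  e <- 0
  for (j in seq_along(specs))
    e <- e + mixture_energy(phi[j], psi[j], specs[[j]], T_ref)
  e
}

#' Toy replica-exchange Monte Carlo sampler
#'
#' Runs parallel Metropolis samplers, one per ladder temperature, on the
#' basin-mixture energy landscape \code{\link{mixture_energy}} (fixed at
#' \code{T_ref}; temperature enters only through the Metropolis factor).
#' Each sweep proposes a wrapped-Gaussian move of width
#' \code{proposal_step} for every angle of every replica (symmetric
#' proposal, no Hastings correction). Every \code{exchange_interval}
#' sweeps, configuration swaps are attempted between neighbouring
#' temperatures on alternating even/odd pairs using
#' \code{\link{exchange_probability}}; trajectories are recorded per
#' temperature slot, i.e. after any swap, so each output trajectory
#' samples one fixed temperature.
#'
#' @param specs List of \code{residue_ensemble_spec} defining the
#'   landscape (residues evolve independently).
#' @param ladder A \code{replica_ladder}.
#' @param n_sweeps Number of sweeps.
#' @param exchange_interval Sweeps between exchange attempts (>= 1).
#' @param proposal_step Proposal width in degrees (> 0; default 25).
#' @param seed Explicit RNG seed.
#' @param T_ref Landscape reference temperature (K); at the ladder
#'   temperature equal to \code{T_ref} the stationary density is exactly
#'   the basin-mixture density.
#' @param record_interval Record every k-th sweep (default 1).
#' @param init Optional n_res x 2 matrix of starting angles (default: the
#'   canonical PPII point (-75, 145) for every residue of every replica).
#' @return Object of class \code{remd_run}: \code{trajectories} (list of
#'   \code{dihedral_trajectory}, one per temperature), \code{ladder},
#'   \code{exchanges} (data frame: sweep, pair_i, U_i, U_j, accepted),
#'   \code{exchange_rates} (mean acceptance per neighbour pair) and
#'   \code{move_acceptance} (per-replica single-angle acceptance rate).
#' @export
remd_run <- function(specs, ladder, n_sweeps, exchange_interval = 10L,
                     proposal_step = 25, seed, T_ref = 300,
                     record_interval = 1L, init = NULL) {
  if (inherits(specs, "residue_ensemble_spec")) specs <- list(specs)
  stopifnot(inherits(ladder, "replica_ladder"))
  if (missing(seed)) stop("an explicit seed is required")
  if (proposal_step <= 0) stop("proposal_step must be positive")
  if (exchange_interval < 1L) stop("exchange_interval must be >= 1")
  set.seed(seed)
  n_rep <- ladder$n_replicas
  n_res <- length(specs)
  temps <- ladder$temperatures
  beta <- 1 / (k_boltzmann * temps)
  phi <- matrix(if (is.null(init)) -75 else init[, 1L], n_rep, n_res,
                byrow = TRUE)
  psi <- matrix(if (is.null(init)) 145 else init[, 2L], n_rep, n_res,
                byrow = TRUE)
  # per-replica, per-residue landscape energies, kept incrementally
  eres <- matrix(NA_real_, n_rep, n_res)
  for (j in seq_len(n_res))
    eres[, j] <- mixture_energy(phi[, j], psi[, j], specs[[j]], T_ref)
  n_rec <- n_sweeps %/% record_interval
  rec_phi <- array(NA_real_, dim = c(n_rec, n_rep, n_res))
  rec_psi <- array(NA_real_, dim = c(n_rec, n_rep, n_res))
  moves_acc <- numeric(n_rep)
  moves_tot <- 0
  exch <- list()
  n_exch <- 0L
  parity <- 0L
  for (sweep in seq_len(n_sweeps)) {
    for (j in seq_len(n_res)) {
      for (ang in 1:2) {
        cur <- if (ang == 1L) phi[, j] else psi[, j]
        prop <- wrap180(cur + stats::rnorm(n_rep, 0, proposal_step))
        e_new <- if (ang == 1L)
          mixture_energy(prop, psi[, j], specs[[j]], T_ref)
        else
          mixture_energy(phi[, j], prop, specs[[j]], T_ref)
        acc <- stats::runif(n_rep) < exp(-beta * (e_new - eres[, j]))
        if (any(acc)) {
          if (ang == 1L) phi[acc, j] <- prop[acc] else psi[acc, j] <- prop[acc]
          eres[acc, j] <- e_new[acc]
        }
        moves_acc <- moves_acc + acc
      }
    }
    moves_tot <- moves_tot + 2L * n_res
    if (sweep %% exchange_interval == 0L && n_rep >= 2L) {
      first <- 1L + parity
      parity <- (parity + 1L) %% 2L
      pairs <- if (first <= n_rep - 1L) seq(first, n_rep - 1L, by = 2L)
               else integer()
      if (length(pairs)) {
        U <- rowSums(eres)
        p <- exchange_probability(U[pairs], U[pairs + 1L],
                                  temps[pairs], temps[pairs + 1L])
        do_swap <- stats::runif(length(pairs)) < p
        n_exch <- n_exch + 1L
        exch[[n_exch]] <- data.frame(sweep = sweep, pair_i = pairs,
                                     U_i = U[pairs], U_j = U[pairs + 1L],
                                     accepted = do_swap)
        for (k in which(do_swap)) {
          i <- pairs[k]
          sw <- function(m) { tmp <- m[i, ]; m[i, ] <- m[i + 1L, ]; m[i + 1L, ] <- tmp; m }
          phi <- sw(phi); psi <- sw(psi); eres <- sw(eres)
        }
      }
    }
    if (sweep %% record_interval == 0L) {
      r <- sweep %/% record_interval
      rec_phi[r, , ] <- phi
      rec_psi[r, , ] <- psi
    }
  }
  exchanges <- if (n_exch) do.call(rbind, exch)
               else data.frame(sweep = integer(), pair_i = integer(),
                               U_i = numeric(), U_j = numeric(),
                               accepted = logical())
  rates <- if (nrow(exchanges))
    tapply(exchanges$accepted, exchanges$pair_i, mean)
  else numeric()
  residues <- data.frame(number = seq_len(n_res), type = "A",
                         glycosylated = vapply(specs, `[[`, logical(1),
                                               "glycosylated"))
  trajs <- lapply(seq_len(n_rep), function(r)
    dihedral_trajectory(rec_phi[, r, , drop = FALSE][, 1L, , drop = TRUE],
                        rec_psi[, r, , drop = FALSE][, 1L, , drop = TRUE],
                        residues))
  names(trajs) <- sprintf("T%.2fK", temps)
  structure(list(trajectories = trajs, ladder = ladder,
                 exchanges = exchanges, exchange_rates = rates,
                 move_acceptance = moves_acc / (moves_tot * 1),
                 T_ref = T_ref),
            class = "remd_run")
}

#' @export
print.remd_run <- function(x, ...) {
  cat("remd_run:", x$ladder$n_replicas, "replicas,",
      nrow(x$trajectories[[1L]]$phi), "recorded sweeps\n")
  if (length(x$exchange_rates)) {
    cat("  exchange acceptance per neighbour pair:\n")
    print(round(x$exchange_rates, 3))
  }
  invisible(x)
}
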
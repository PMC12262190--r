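#' Boltzmann constant in kcal/(mol K)
#' @export
k_boltzmann <- 0.0019872041

#' Secondary-structure basin specification
#'
#' A basin is a localized mode of the (phi, psi) distribution standing for
#' one named secondary-structure region. Angles are drawn from independent
#' wrapped-normal (von-Mises-like) distributions about the basin centre;
#' the concentration kappa maps to an angular standard deviation of
#' (180/pi)/sqrt(kappa) degrees, matching the large-kappa von Mises limit.
#'
#' @param name One of "PPII", "alphaR", "beta", "alphaL".
#' @param center Length-2 numeric, (phi, psi) centre in degrees.
#' @param kappa Concentration, > 0.
#' @param weight Mixture weight in [0, 1].
#' @return Object of class \code{basin_spec}.
#' @export
basin_spec <- function(name, center, kappa, weight) {
  if (!name %in% c("PPII", "alphaR", "beta", "alphaL"))
    stop("unknown basin name: ", name)
  if (length(center) != 2L) stop("center must be (phi, psi)")
  if (kappa <= 0) stop("kappa must be > 0")
  if (weight < 0 || weight > 1) stop("weight must lie in [0, 1]")
  structure(list(name = name, center = wrap180(as.numeric(center)),
                 kappa = kappa, weight = weight),
            class = "basin_spec")
}

#' Default basin centres
#'
#' PPII at the canonical (-75, 145); beta, alphaR and alphaL centres placed
#' inside the corresponding classification rectangles.
#'
#' @return Named list of (phi, psi) centres.
#' @export
default_basin_centers <- function() {
  list(PPII = c(-75, 145), beta = c(-135, 135),
       alphaR = c(-63, -60), alphaL = c(60, 45))
}

#' Per-residue basin-mixture specification
#'
#' Describes the conformational ensemble of one residue as a weighted
#' mixture of secondary-structure basins, plus the residue's glycosylation
#' state. When \code{glycosylated = TRUE}, \code{glyco_weight_shift} of
#' probability mass is moved from the alphaR basin into the PPII basin,
#' emulating the destabilisation of compact alphaR conformations by the
#' bulky O-linked glycan and the resulting gain in PPII population.
#'
#' @param weights Named numeric vector over basins (subset of PPII, beta,
#'   alphaR, alphaL); must sum to 1 within 1e-9.
#' @param kappa Concentration shared by all basins, or named per basin.
#' @param glycosylated Logical.
#' @param glyco_weight_shift Weight moved alphaR -> PPII when glycosylated
#'   (capped at the available alphaR weight).
#' @param centers Basin centres (default \code{default_basin_centers()}).
#' @return Object of class \code{residue_ensemble_spec}: list of
#'   \code{basin_spec} plus the glycosylation flag.
#' @export
residue_ensemble_spec <- function(weights, kappa = 12,
                                  glycosylated = FALSE,
                                  glyco_weight_shift = 0.3,
                                  centers = default_basin_centers()) {
  if (is.null(names(weights)) || any(!names(weights) %in% names(centers)))
    stop("weights must be named after basins: ",
         paste(names(centers), collapse = ", "))
  if (abs(sum(weights) - 1) > 1e-9)
    stop("basin weights must sum to 1 (got ", sum(weights), ")")
  if (glycosylated && glyco_weight_shift > 0) {
    from <- min(glyco_weight_shift, weights["alphaR"] %||% 0, na.rm = TRUE)
    if (!is.na(weights["alphaR"]) && from > 0) {
      weights["alphaR"] <- weights["alphaR"] - from
      weights["PPII"] <- (weights["PPII"] %||% 0) + from
    }
  }
  weights <- weights[weights > 0]
  kap <- if (is.null(names(kappa))) rep_len(kappa, length(weights))
         else kappa[names(weights)]
  basins <- mapply(function(nm, w, k) basin_spec(nm, centers[[nm]], k, w),
                   names(weights), weights, kap, SIMPLIFY = FALSE)
  structure(list(basins = basins, glycosylated = glycosylated),
            class = "residue_ensemble_spec")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Default ensemble specification for a peptide model
#'
#' Builds one \code{residue_ensemble_spec} per residue of a peptide model.
#' Default mixtures are PPII-dominant, reflecting the proline-rich
#' mucin-repeat composition: prolines are nearly pure PPII/beta, while
#' threonines keep an appreciable alphaR component that the glycosylation
#' shift removes. Glycosylated residues (per the model's site flags) have
#' \code{glyco_weight_shift} of weight moved alphaR -> PPII.
#'
#' @param model A \code{peptide_model}.
#' @param kappa Basin concentration (default 12, about 16.5 degrees sd).
#' @param glyco_weight_shift Weight moved alphaR -> PPII at glycosylated
#'   sites (default 0.3).
#' @return List of \code{residue_ensemble_spec}, one per residue.
#' @export
ensemble_spec_for_model <- function(model, kappa = 12,
                                    glyco_weight_shift = 0.3) {
  stopifnot(inherits(model, "peptide_model"))
  base_weights <- function(type) {
    switch(type,
      "P" = c(PPII = 0.80, beta = 0.15, alphaR = 0.05),
      "T" = c(PPII = 0.45, beta = 0.15, alphaR = 0.35, alphaL = 0.05),
      "S" = c(PPII = 0.45, beta = 0.15, alphaR = 0.35, alphaL = 0.05),
      "A" = c(PPII = 0.60, beta = 0.15, alphaR = 0.20, alphaL = 0.05),
      "K" = c(PPII = 0.55, beta = 0.20, alphaR = 0.20, alphaL = 0.05),
      "E" = c(PPII = 0.50, beta = 0.20, alphaR = 0.25, alphaL = 0.05),
      c(PPII = 0.40, beta = 0.25, alphaR = 0.30, alphaL = 0.05))
  }
  lapply(seq_len(nrow(model$residues)), function(i)
    residue_ensemble_spec(base_weights(model$residues$type[i]),
                          kappa = kappa,
                          glycosylated = model$residues$glycosylated[i],
                          glyco_weight_shift = glyco_weight_shift))
}

# wrapped-normal density on the circle (degrees, period 360), summed over
# 2K+1 images; K = 6 keeps the truncation error far below 1e-12 for the
# spreads used here
.dwrapnorm <- function(x, mu, sd, K = 6L) {
  out <- 0
  for (k in -K:K) out <- out + stats::dnorm(x - mu + 360 * k, 0, sd)
  out
}

.kappa_to_sd <- function(kappa) (180 / pi) / sqrt(kappa)

#' Mixture density and energy of a residue ensemble spec
#'
#' \code{mixture_density} evaluates the wrapped-normal basin-mixture
#' probability density (per square degree) at (phi, psi);
#' \code{mixture_energy} converts it into the energy landscape
#' U(phi, psi) = -kB * T_ref * ln(density) on which the toy
#' replica-exchange sampler runs. Both are smooth and periodic with
#' period 360 in each angle; energies are defined up to an additive
#' constant (the density normalisation), so only differences matter.
#'
#' @param phi,psi Numeric vectors of angles (degrees), recycled.
#' @param spec A \code{residue_ensemble_spec}.
#' @param T_ref Reference temperature (K) fixing the landscape scale.
#' @return Density (deg^-2) or energy (kcal/mol) vector.
#' @export
mixture_density <- function(phi, psi, spec) {
  stopifnot(inherits(spec, "residue_ensemble_spec"))
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  dens <- 0
  for (b in spec$basins) {
    sd <- .kappa_to_sd(b$kappa)
    dens <- dens + b$weight *
      .dwrapnorm(phi, b$center[1L], sd) * .dwrapnorm(psi, b$center[2L], sd)
  }
  dens
}

#' @rdname mixture_density
#' @export
mixture_energy <- function(phi, psi, spec, T_ref = 300) {
  if (T_ref <= 0) stop("T_ref must be positive")
  -k_boltzmann * T_ref * log(mixture_density(phi, psi, spec))
}

#' Sample a synthetic dihedral ensemble
#'
#' Draws i.i.d. frames: per residue, a basin is chosen by weight, then phi
#' and psi are drawn from independent wrapped-normal distributions about
#' the basin centre. This emulates the per-residue (phi, psi) statistics of
#' an equilibrated 300 K replica trajectory (no temporal autocorrelation).
#'
#' @param specs List of \code{residue_ensemble_spec} (one per residue), or
#'   a single spec for a one-residue system.
#' @param n_frames Number of frames (>= 1).
#' @param seed Explicit RNG seed (required: ensembles are reproducible).
#' @param residues Optional residue table; defaults to generic alanines
#'   (glycosylated flag taken from each spec).
#' @param time_step_ns Optional uniform frame spacing to attach times.
#' @return A \code{dihedral_trajectory}.
#' @examples
#' spec <- residue_ensemble_spec(c(PPII = 0.7, alphaR = 0.3))
#' traj <- sample_ensemble(list(spec, spec), n_frames = 100, seed = 1)
#' @export
sample_ensemble <- function(specs, n_frames, seed, residues = NULL,
                            time_step_ns = NULL) {
  if (inherits(specs, "residue_ensemble_spec")) specs <- list(specs)
  if (missing(seed)) stop("an explicit seed is required")
  if (n_frames < 1L) stop("n_frames must be >= 1")
  set.seed(seed)
  n_res <- length(specs)
  phi <- matrix(NA_real_, n_frames, n_res)
  psi <- matrix(NA_real_, n_frames, n_res)
  for (j in seq_len(n_res)) {
    sp <- specs[[j]]
    w <- vapply(sp$basins, `[[`, numeric(1), "weight")
    pick <- sample.int(length(w), n_frames, replace = TRUE, prob = w)
    mu_phi <- vapply(sp$basins, function(b) b$center[1L], numeric(1))[pick]
    mu_psi <- vapply(sp$basins, function(b) b$center[2L], numeric(1))[pick]
    sd <- .kappa_to_sd(vapply(sp$basins, `[[`, numeric(1), "kappa"))[pick]
    phi[, j] <- wrap180(stats::rnorm(n_frames, mu_phi, sd))
    psi[, j] <- wrap180(stats::rnorm(n_frames, mu_psi, sd))
  }
  if (is.null(residues))
    residues <- data.frame(
      number = seq_len(n_res), type = "A",
      glycosylated = vapply(specs, `[[`, logical(1), "glycosylated"))
  dihedral_trajectory(phi, psi, residues,
                      time_ns = if (is.null(time_step_ns)) NULL
                                else time_step_ns * (seq_len(n_frames) - 1L))
}
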
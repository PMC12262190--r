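# label code matrix (n_frames x n_res, integer codes into labels) -- the
# shared workhorse behind all population estimators
.label_codes <- function(traj, regions) {
  labs <- region_labels(regions)
  lab <- classify(as.vector(traj$phi), as.vector(traj$psi), regions)
  matrix(match(lab, labs), nrow(traj$phi), ncol(traj$phi))
}

.fractions_from_codes <- function(codes, rows, n_labels) {
  sub <- codes[rows, , drop = FALSE]
  apply(sub, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(rep(NA_real_, n_labels))   # all-NA terminus
    tabulate(col, nbins = n_labels) / length(col)
  })                                   # n_labels x n_res
}

#' Per-residue secondary-structure populations
#'
#' Fraction of frames each residue spends in every named region (and
#' coil). Per residue the fractions sum to 1; terminal residues with an
#' undefined dihedral are assessed on their defined frames only.
#'
#' @param traj A \code{dihedral_trajectory}.
#' @param regions A \code{region_set}.
#' @return Object of class \code{population_table}: data frame with
#'   columns \code{residue_number, residue_type, glycosylated, region,
#'   fraction} (attribute \code{n_frames} records the sample size).
#' @examples
#' spec <- residue_ensemble_spec(c(PPII = 0.7, alphaR = 0.3))
#' residue_populations(sample_ensemble(spec, 1000, seed = 1))
#' @export
residue_populations <- function(traj, regions = region_set()) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  if (nrow(traj$phi) < 1L) stop("empty trajectory")
  labs <- region_labels(regions)
  codes <- .label_codes(traj, regions)
  fr <- .fractions_from_codes(codes, seq_len(nrow(codes)), length(labs))
  n_res <- ncol(traj$phi)
  out <- data.frame(
    residue_number = rep(traj$residues$number, each = length(labs)),
    residue_type = rep(traj$residues$type, each = length(labs)),
    glycosylated = rep(traj$residues$glycosylated, each = length(labs)),
    region = rep(labs, n_res),
    fraction = as.vector(fr))
  structure(out, class = c("population_table", "data.frame"),
            n_frames = nrow(traj$phi))
}

#' @export
print.population_table <- function(x, digits = 3, ...) {
  cat("population_table (", attr(x, "n_frames"), "frames )\n")
  wide <- stats::reshape(as.data.frame(x), direction = "wide",
                         idvar = c("residue_number", "residue_type",
                                   "glycosylated"),
                         timevar = "region")
  names(wide) <- sub("^fraction\\.", "", names(wide))
  num <- vapply(wide, is.numeric, logical(1)) &
    !names(wide) %in% "residue_number"
  wide[num] <- lapply(wide[num], round, digits)
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

# moving-block bootstrap index resampler: contiguous blocks of length L,
# uniform random starts, concatenated and trimmed to n
.mbb_indices <- function(n, block_length) {
  n_blocks <- ceiling(n / block_length)
  starts <- sample.int(n - block_length + 1L, n_blocks, replace = TRUE)
  idx <- as.vector(outer(0:(block_length - 1L), starts, `+`))
  idx[seq_len(n)]
}

#' Block-bootstrap confidence intervals for region populations
#'
#' Percentile intervals from a moving-block bootstrap over frames; blocks
#' of contiguous frames preserve temporal autocorrelation, so the
#' intervals remain honest for correlated (e.g. Monte Carlo) trajectories.
#' With \code{block_length = 1} this reduces to an ordinary i.i.d.
#' bootstrap.
#'
#' @param traj A \code{dihedral_trajectory}.
#' @param regions A \code{region_set}.
#' @param block_length Block length in frames (>= 1, < n_frames).
#' @param n_boot Bootstrap replicates (>= 200).
#' @param seed Explicit RNG seed.
#' @param level Confidence level (default 0.95).
#' @return A \code{population_table} with extra columns \code{ci_low},
#'   \code{ci_high}.
#' @export
population_ci <- function(traj, regions = region_set(), block_length = 1L,
                          n_boot = 500L, seed, level = 0.95) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  if (missing(seed)) stop("an explicit seed is required")
  n <- nrow(traj$phi)
  if (block_length < 1L) stop("block_length must be >= 1")
  if (block_length >= n) stop("block_length must be smaller than n_frames")
  if (n_boot < 200L) stop("n_boot must be >= 200")
  set.seed(seed)
  labs <- region_labels(regions)
  codes <- .label_codes(traj, regions)
  point <- residue_populations(traj, regions)
  boot <- array(NA_real_, dim = c(n_boot, length(labs), ncol(codes)))
  for (b in seq_len(n_boot))
    boot[b, , ] <- .fractions_from_codes(codes, .mbb_indices(n, block_length),
                                         length(labs))
  a <- (1 - level) / 2
  qs <- apply(boot, c(2L, 3L), stats::quantile, probs = c(a, 1 - a),
              names = FALSE)
  point$ci_low <- as.vector(qs[1L, , ])
  point$ci_high <- as.vector(qs[2L, , ])
  attr(point, "level") <- level
  point
}

#' Compare region populations between two ensembles
#'
#' Per residue and region, estimates the population difference
#' (B minus A) with a percentile bootstrap CI formed by independently
#' block-resampling both trajectories; the difference is significant at
#' level alpha when the (1 - alpha) CI excludes zero. No multiplicity
#' correction is applied across residues: calls are reported per residue,
#' per region.
#'
#' @param traj_a,traj_b \code{dihedral_trajectory} objects over the same
#'   residue numbering (e.g. non-glycosylated vs glycosylated peptide).
#' @param regions A \code{region_set}.
#' @param alpha Significance level (default 0.05).
#' @param block_length,n_boot,seed As in \code{\link{population_ci}}.
#' @return Object of class \code{population_comparison}: data frame with
#'   \code{residue_number, residue_type, region, fraction_a, fraction_b,
#'   delta, ci_low, ci_high, significant, direction}.
#' @export
compare_populations <- function(traj_a, traj_b, regions = region_set(),
                                alpha = 0.05, block_length = 1L,
                                n_boot = 500L, seed) {
  stopifnot(inherits(traj_a, "dihedral_trajectory"),
            inherits(traj_b, "dihedral_trajectory"))
  if (missing(seed)) stop("an explicit seed is required")
  if (!identical(traj_a$residues$number, traj_b$residues$number) ||
      !identical(traj_a$residues$type, traj_b$residues$type))
    stop("trajectories must share the same residue numbering and types")
  na <- nrow(traj_a$phi); nb <- nrow(traj_b$phi)
  if (block_length >= min(na, nb)) stop("block_length too large")
  if (n_boot < 200L) stop("n_boot must be >= 200")
  set.seed(seed)
  labs <- region_labels(regions)
  ca <- .label_codes(traj_a, regions)
  cb <- .label_codes(traj_b, regions)
  fa <- .fractions_from_codes(ca, seq_len(na), length(labs))
  fb <- .fractions_from_codes(cb, seq_len(nb), length(labs))
  boot <- array(NA_real_, dim = c(n_boot, length(labs), ncol(ca)))
  for (b in seq_len(n_boot)) {
    ba <- .fractions_from_codes(ca, .mbb_indices(na, block_length), length(labs))
    bb <- .fractions_from_codes(cb, .mbb_indices(nb, block_length), length(labs))
    boot[b, , ] <- bb - ba
  }
  qs <- apply(boot, c(2L, 3L), stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  delta <- fb - fa
  out <- data.frame(
    residue_number = rep(traj_a$residues$number, each = length(labs)),
    residue_type = rep(traj_a$residues$type, each = length(labs)),
    region = rep(labs, ncol(ca)),
    fraction_a = as.vector(fa), fraction_b = as.vector(fb),
    delta = as.vector(delta),
    ci_low = as.vector(qs[1L, , ]), ci_high = as.vector(qs[2L, , ]))
  out$significant <- out$ci_low > 0 | out$ci_high < 0
  out$direction <- ifelse(out$delta > 0, "increase",
                          ifelse(out$delta < 0, "decrease", "none"))
  structure(out, class = c("population_comparison", "data.frame"),
            alpha = alpha)
}

#' @export
print.population_comparison <- function(x, digits = 3, ...) {
  cat("population_comparison (alpha =", attr(x, "alpha"), ")\n")
  sig <- x[x$significant, , drop = FALSE]
  if (!nrow(sig)) {
    cat("  no significant differences\n")
  } else {
    sig <- as.data.frame(sig)
    num <- vapply(sig, is.numeric, logical(1)) &
      !names(sig) %in% "residue_number"
    sig[num] <- lapply(sig[num], round, digits)
    print(sig, row.names = FALSE)
  }
  invisible(x)
}
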
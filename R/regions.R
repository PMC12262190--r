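#' Named secondary-structure regions of the Ramachandran plot
#'
#' Rectangular (phi, psi) regions with circular-angle semantics, following
#' the literature classification used for mucin-peptide ensembles:
#' \itemize{
#'   \item alphaR: -160 < phi < -20 and -120 < psi < -50
#'   \item beta:   -180 < phi < -90 and   50 < psi < 240
#'   \item PPII:    -90 < phi <  20 and   50 < psi < 240
#'   \item alphaL:   30 < phi < 100 and    0 < psi <  80
#' }
#' plus the catch-all label "coil". Bounds exceeding 180 wrap around the
#' circle (psi < 240 admits psi in (50, 180] union [-180, -120) on the
#' reported scale); all inequalities are strict, so angles exactly on a
#' bound fall to coil (a measure-zero set).
#'
#' @param regions Optional data frame overriding the defaults; columns
#'   \code{name, phi_lo, phi_hi, psi_lo, psi_hi}.
#' @return Object of class \code{region_set} (a validated data frame).
#' @export
region_set <- function(regions = NULL) {
  if (is.null(regions))
    regions <- data.frame(
      name = c("alphaR", "beta", "PPII", "alphaL"),
      phi_lo = c(-160, -180, -90, 30),
      phi_hi = c(-20, -90, 20, 100),
      psi_lo = c(-120, 50, 50, 0),
      psi_hi = c(-50, 240, 240, 80))
  need <- c("name", "phi_lo", "phi_hi", "psi_lo", "psi_hi")
  if (!all(need %in% names(regions))) stop("regions need columns: ",
                                           paste(need, collapse = ", "))
  if (any(regions$phi_hi <= regions$phi_lo) ||
      any(regions$psi_hi <= regions$psi_lo))
    stop("region bounds must satisfy lo < hi")
  if (any(regions$phi_hi - regions$phi_lo >= 360) ||
      any(regions$psi_hi - regions$psi_lo >= 360))
    stop("region spans must be < 360 degrees")
  if ("coil" %in% regions$name) stop("'coil' is reserved for the catch-all")
  rs <- structure(regions, class = c("region_set", "data.frame"))
  # pairwise disjointness on the torus (open rectangles)
  ov <- function(lo1, hi1, lo2, hi2) {       # open circular intervals
    for (s in c(-360, 0, 360))
      if (max(lo1, lo2 + s) < min(hi1, hi2 + s)) return(TRUE)
    FALSE
  }
  n <- nrow(regions)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    if (ov(regions$phi_lo[i], regions$phi_hi[i],
           regions$phi_lo[j], regions$phi_hi[j]) &&
        ov(regions$psi_lo[i], regions$psi_hi[i],
           regions$psi_lo[j], regions$psi_hi[j]))
      stop("regions '", regions$name[i], "' and '", regions$name[j],
           "' overlap on the torus")
  }
  rs
}

# strict membership of wrapped angle x in open circular interval (lo, hi)
.in_circ <- function(x, lo, hi) {
  y <- lo + ((x - lo) %% 360)
  y > lo & y < hi
}

#' Classify (phi, psi) pairs into secondary-structure regions
#'
#' Total and single-valued: every finite angle pair maps to exactly one
#' label (the named regions are pairwise disjoint; anything unmatched is
#' "coil"). NA input yields NA.
#'
#' @param phi,psi Numeric vectors (degrees), recycled to a common length.
#' @param regions A \code{region_set} (default \code{region_set()}).
#' @return Character vector of labels.
#' @examples
#' classify(-75, 145)   # "PPII"
#' classify(0, 0)       # "coil"
#' @export
classify <- function(phi, psi, regions = region_set()) {
  n <- max(length(phi), length(psi))
  phi <- wrap180(rep_len(phi, n)); psi <- wrap180(rep_len(psi, n))
  out <- rep("coil", n)
  for (r in seq_len(nrow(regions))) {
    hit <- .in_circ(phi, regions$phi_lo[r], regions$phi_hi[r]) &
           .in_circ(psi, regions$psi_lo[r], regions$psi_hi[r])
    out[which(hit)] <- regions$name[r]
  }
  out[is.na(phi) | is.na(psi)] <- NA_character_
  out
}

#' All labels of a region set, catch-all included
#' @param regions A \code{region_set}.
#' @return Character vector of labels, "coil" last.
#' @export
region_labels <- function(regions = region_set()) c(regions$name, "coil")
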
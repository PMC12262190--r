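#' Wrap angles into [-180, 180)
#'
#' All dihedral angles in this package live on the circle and are reported
#' in degrees in the half-open interval \code{[-180, 180)} (IUPAC sign
#' convention). This helper maps any finite angle onto that interval.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, wrapped into \code{[-180, 180)}.
#' @examples
#' wrap180(c(200, -190, 180, 360))
#' @export
wrap180 <- function(x) {
  if (!is.numeric(x)) stop("angles must be numeric")
  ((x + 180) %% 360) - 180
}

# 3-vector cross product; no input checks, internal hot path
.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.unit3 <- function(v, what = "vector") {
  n <- sqrt(sum(v * v))
  if (n < 1e-10) stop("degenerate geometry: zero-length ", what)
  v / n
}

#' Dihedral (torsion) angle of four points
#'
#' Signed torsion about the p2--p3 axis, in degrees, IUPAC convention:
#' looking from p2 towards p3, a clockwise rotation of the p3-p4 bond
#' relative to the p1-p2 bond is positive.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees in \code{[-180, 180)}.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2 * b2)))
  wrap180(-atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi)
}

# Natural-extension (NeRF) placement: returns the point d with
# |c-d| = bond, angle(b,c,d) = angle_deg and torsion(a,b,c,d) = torsion_deg.
.place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  bc <- .unit3(c - b, "bond")
  n <- .unit3(.cross3(b - a, bc), "plane normal (collinear reference atoms)")
  m <- .cross3(n, bc)
  th <- angle_deg * pi / 180
  ph <- torsion_deg * pi / 180
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}
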
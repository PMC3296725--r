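# Elementary vector geometry on 3D coordinates.  These primitives back the
# hydrogen-bond criteria, torsion-window checks and the fixture builders;
# they operate on bare numeric(3) vectors rather than whole-structure
# objects so they can be unit-tested against hand computations.

vnorm <- function(v) sqrt(sum(v * v))

vdist <- function(a, b) vnorm(a - b)

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at vertex b formed by points a-b-c
#'
#' @param a,b,c numeric(3) coordinates in Angstrom.
#' @return Angle in degrees, in \[0, 180\].
#' @export
vec_angle <- function(a, b, c) {
  u <- a - b
  w <- c - b
  ct <- sum(u * w) / (vnorm(u) * vnorm(w))
  ct <- max(-1, min(1, ct))
  acos(ct) * 180 / pi
}

#' Dihedral angle of four points
#'
#' Signed torsion a-b-c-d using the IUPAC convention (cis = 0, trans =
#' +/-180).
#'
#' @param a,b,c,d numeric(3) coordinates.
#' @return Angle in degrees, in (-180, 180\].
#' @export
vec_dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Place a new atom D given three reference atoms A-B-C, the bond length
# C-D, the angle B-C-D (degrees) and the torsion A-B-C-D (degrees).
# Standard internal-to-Cartesian construction used by the fixture builders.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- vcross(ab, bc)
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
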
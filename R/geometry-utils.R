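# Low-level vector geometry shared by every module.  All coordinates are
# orthogonal Angstroms; all angles are degrees unless a helper says otherwise.

DEG <- 180 / pi

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into the interval (-180, 180].
#' @export
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Circular difference between two angles
#'
#' Smallest signed difference `a - b` on the circle, in degrees.  Used for
#' every angular comparison in the package; raw subtraction is never safe for
#' torsions that wrap near +/-180.
#'
#' @param a,b angles in degrees.
#' @return signed difference in (-180, 180].
#' @export
circ_diff <- function(a, b) wrap180(a - b)

angle3 <- function(p1, p2, p3) {
  v1 <- unitv(p1 - p2)
  v2 <- unitv(p3 - p2)
  d <- sum(v1 * v2)
  acos(max(-1, min(1, d))) * DEG
}

#' Torsion angle of four points
#'
#' Standard IUPAC sign convention: looking from `p2` toward `p3`, the torsion
#' is positive when the far bond p3->p4 is rotated clockwise relative to the
#' near bond p2->p1.  A cis arrangement gives 0, trans gives 180.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstroms.
#' @return torsion in degrees, in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("undefined dihedral: coincident consecutive points")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("undefined dihedral: collinear points")
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * unitv(b2))
  wrap180(atan2(y, x) * DEG)
}

# Rotation matrix for a right-handed rotation by `theta` degrees about unit
# axis `u` (Rodrigues).
rotation_about_axis <- function(u, theta) {
  u <- unitv(u)
  th <- theta / DEG
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * (u %o% u)
}

rot_z <- function(theta) rotation_about_axis(c(0, 0, 1), theta)

# NeRF atom placement: position a new atom bonded to `c` at distance `bond`,
# with angle(new, c, b) = `ang` degrees and dihedral(new, c, b, a) = `tor`
# degrees.  The workhorse of internal-coordinate model building.
place_atom <- function(a, b, c, bond, ang, tor) {
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  ang_r <- ang / DEG
  tor_r <- tor / DEG
  d2 <- c(-bond * cos(ang_r),
          bond * sin(ang_r) * cos(tor_r),
          bond * sin(ang_r) * sin(tor_r))
  # local frame: bc, m, n -- chosen so that dihedral(d, c, b, a) == tor under
  # the package's sign convention (checked by the torsion round-trip tests)
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Complete a tetrahedral centre: given centre `c` and two known substituent
# positions `s1`, `s2`, return the two remaining substituent directions as a
# 2 x 3 matrix of unit vectors (rows).  `sep` is the angle each remaining
# bond makes with the bisector plane normal; 109.47 deg geometry by default.
tetrahedral_directions <- function(c, s1, s2) {
  a <- unitv(s1 - c)
  b <- unitv(s2 - c)
  bis <- -unitv(a + b)          # in-plane component, away from s1/s2
  nrm <- unitv(cross3(a, b))    # out-of-plane component
  half <- acos(max(-1, min(1, sum(a * b)))) / 2
  # components (x along bis, z along nrm) chosen so both remaining bonds make
  # 109.47 deg with each known substituent: dot(a, d) = -x cos(half)
  ct <- cos(109.47 / DEG)
  x <- -ct / cos(half)
  x <- max(-1, min(1, x))
  z <- sqrt(max(0, 1 - x^2))
  rbind(x * bis + z * nrm,
        x * bis - z * nrm)
}

# Pearson correlation robust to zero variance (returns NA there).
safe_cor <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}
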
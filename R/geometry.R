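# Vector geometry primitives: cross products, dihedrals, NeRF atom placement,
# and the virtual C-beta construction shared by featurization and fixtures.

.vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.vnorm <- function(a) sqrt(rowSums(a * a))

.vunit <- function(a) {
  n <- .vnorm(a)
  n[n == 0] <- 1
  a / n
}

#' Virtual C-beta position from backbone N, CA, C
#'
#' Places a pseudo C-beta from local backbone geometry so that every residue
#' (including glycine) has a sidechain-direction reference point:
#' `Cb = -0.5827 (b x c) + 0.5680 b - 0.5407 c + Ca` with `b = Ca - N`,
#' `c = C - Ca`. Degenerate geometry (coincident atoms) collapses to `Ca`.
#'
#' @param n,ca,c numeric matrices `[L x 3]` (or length-3 vectors).
#' @return numeric matrix `[L x 3]` of virtual C-beta coordinates.
#' @export
virtual_cbeta <- function(n, ca, c) {
  if (is.null(dim(n))) { n <- rbind(n); ca <- rbind(ca); c <- rbind(c) }
  b <- ca - n
  cc <- c - ca
  a <- .vcross(b, cc)
  -0.5827 * a + 0.5680 * b - 0.5407 * cc + ca
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric matrices `[n x 3]` or length-3 vectors.
#' @return angle in radians in `(-pi, pi]`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  if (is.null(dim(p1))) { p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3); p4 <- rbind(p4) }
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .vunit(b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  atan2(y, x)
}

#' Place an atom from three reference atoms and internal coordinates (NeRF)
#'
#' Given positions `a`, `b`, `c`, places `d` such that `|c-d| = length`,
#' the angle b-c-d equals `angle`, and the dihedral a-b-c-d equals `dihedral`.
#'
#' @param a,b,c length-3 numeric vectors.
#' @param length bond length in Angstrom.
#' @param angle bond angle in radians.
#' @param dihedral torsion in radians.
#' @return length-3 numeric vector.
#' @export
place_atom <- function(a, b, c, length, angle, dihedral) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) {            # colinear reference: pick any perpendicular
    n <- c(bc[3], 0, -bc[1])
    if (sum(n^2) < 1e-12) n <- c(0, bc[3], -bc[2])
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-length * cos(angle),
          length * sin(angle) * cos(dihedral),
          -length * sin(angle) * sin(dihedral))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Random rigid transform (rotation + translation)
#'
#' @param seed integer RNG seed.
#' @param max_shift maximum translation magnitude per axis, Angstrom.
#' @return list with `R` (3x3 rotation) and `t` (length-3 translation).
#' @export
random_rigid_transform <- function(seed = NULL, max_shift = 50) {
  if (!is.null(seed)) set.seed(seed)
  # QR of a Gaussian matrix gives a Haar-random rotation (fix sign/det)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = stats::runif(3, -max_shift, max_shift))
}

#' Apply a rigid transform to an n x 3 coordinate matrix
#' @param coords numeric matrix `[n x 3]` (rows with NA pass through).
#' @param transform list with `R` and `t` from [random_rigid_transform()].
#' @return transformed matrix.
#' @export
apply_rigid_transform <- function(coords, transform) {
  out <- coords %*% t(transform$R)
  out <- sweep(out, 2, transform$t, "+")
  out
}

# wrap angles into (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}
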
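# Vector geometry shared by all analysis modules. Coordinates are N x 3
# matrices in nm throughout the package; periodic boxes are length-3 vectors.

#' Pairwise distances between two coordinate sets
#'
#' Computes the full |A| x |B| distance matrix, applying the minimum-image
#' convention per axis when an orthorhombic `box` is supplied. Dense and
#' vectorized; intended for the desk-scale systems this package targets
#' (correctness on larger systems is pinned to an exhaustive oracle in the
#' test suite).
#'
#' @param a,b numeric matrices (N x 3, nm).
#' @param box optional length-3 box vector (nm) for minimum-image wrapping.
#' @return |A| x |B| numeric matrix of distances (nm).
#' @export
pair_distances <- function(a, b, box = NULL) {
  a <- coord_matrix(a)
  b <- coord_matrix(b)
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    if (!is.null(box) && is.finite(box[k]) && box[k] > 0) {
      dk <- dk - box[k] * round(dk / box[k])
    }
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

# Coerce to an N x 3 double matrix; a bare length-3 vector is one point.
coord_matrix <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3L)
    x <- matrix(as.numeric(x), 1L, 3L)
  }
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("coordinates must be an N x 3 matrix")
  x
}

#' Dihedral angle defined by four points
#'
#' Signed torsion p1-p2-p3-p4 in degrees, in (-180, 180], using the
#' standard atan2 formulation (IUPAC sign convention: looking down the
#' p2->p3 bond, clockwise rotation of p4 relative to p1 is positive).
#'
#' @param p1,p2,p3,p4 length-3 numeric vectors (nm).
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Rotation matrix for angle theta (radians) about unit axis (Rodrigues).
rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  c0 <- cos(theta); s0 <- sin(theta); t0 <- 1 - c0
  matrix(c(
    t0 * x * x + c0,     t0 * x * y - s0 * z, t0 * x * z + s0 * y,
    t0 * x * y + s0 * z, t0 * y * y + c0,     t0 * y * z - s0 * x,
    t0 * x * z - s0 * y, t0 * y * z + s0 * x, t0 * z * z + c0
  ), 3L, 3L, byrow = TRUE)
}

# Rotate rows of xyz about the axis through `origin` with direction `axis`.
rotate_about_axis <- function(xyz, origin, axis, theta) {
  r <- rotation_matrix(axis, theta)
  shifted <- sweep(coord_matrix(xyz), 2L, origin, "-")
  sweep(shifted %*% t(r), 2L, origin, "+")
}

# Natural extension of reference frame: place a new point at `bond` nm from
# c3, with angle (c2, c3, new) = `angle` deg and dihedral (c1, c2, c3, new) =
# `dihedral` deg. Standard internal-coordinate chain building.
nerf_place <- function(c1, c2, c3, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- -dihedral * pi / 180  # sign matched to dihedral_angle's convention
  d <- c(bond * cos(pi - ang),
         bond * sin(pi - ang) * cos(dih),
         bond * sin(pi - ang) * sin(dih))
  bc <- c3 - c2
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(c2 - c1, bc)
  n <- n / sqrt(sum(n^2))
  m <- cbind(bc, cross3(n, bc), n)
  c(m %*% d) + c3
}
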
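# Internal 3D geometry helpers. Coordinates are plain numeric 3-vectors or
# n x 3 matrices, always in Angstrom.

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) v / vec_norm(v)

#' @noRd
angle_deg <- function(a, b, c) {
  # angle at b, in degrees
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Place atom X given three reference positions using internal coordinates
# (NeRF construction): |X - c| = bond, angle(X, c, b) = ang (deg),
# dihedral(X, c, b, a) = dih (deg).
place_atom <- function(a, b, c, bond, ang, dih) {
  ang <- ang * pi / 180
  dih <- dih * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(
    -bond * cos(ang),
    bond * sin(ang) * cos(dih),
    bond * sin(ang) * sin(dih)
  )
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Random rotation matrix, uniform over SO(3), from the current RNG stream.
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- vec_norm(q)
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Apply rotation R (3x3) then translation t (3-vector) to the coordinate
# columns of a structure tibble.
transform_structure <- function(structure, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  structure$x <- xyz[, 1] + translation[1]
  structure$y <- xyz[, 2] + translation[2]
  structure$z <- xyz[, 3] + translation[3]
  structure
}

# Pairwise Euclidean distances between rows of two n x 3 matrices.
cross_dist <- function(m1, m2) {
  if (nrow(m1) == 0L || nrow(m2) == 0L) {
    return(matrix(numeric(0), nrow = nrow(m1), ncol = nrow(m2)))
  }
  s1 <- rowSums(m1^2)
  s2 <- rowSums(m2^2)
  d2 <- outer(s1, s2, "+") - 2 * (m1 %*% t(m2))
  d2[d2 < 0] <- 0
  sqrt(d2)
}
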
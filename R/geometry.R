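# Small 3-D geometry utilities shared across modules. All lengths in
# Angstrom, angles in degrees unless noted.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180

rad2deg <- function(x) x * 180 / pi

# Angle a-b-c at vertex b, degrees.
angle3 <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# Place atom D given bonded reference A, angle reference B and torsion
# reference C: |D-A| = bond, angle D-A-B = ang, dihedral D-A-B-C = tor.
# Standard internal-coordinate (NeRF-style) construction.
place_atom <- function(a, b, c, bond, ang, tor) {
  ang <- deg2rad(ang)
  tor <- deg2rad(tor)
  ab <- unitv(a - b)
  cb <- b - c
  n <- cross3(cb, ab)
  if (vnorm(n) < 1e-10) {
    # torsion reference collinear; pick any perpendicular
    aux <- if (abs(ab[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- cross3(aux, ab)
  }
  n <- unitv(n)
  m <- cross3(n, ab)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  a + d[1L] * ab + d[2L] * m + d[3L] * n
}

# Rotation matrix taking unit vector u onto unit vector v (Rodrigues).
rotation_between <- function(u, v) {
  u <- unitv(u); v <- unitv(v)
  w <- cross3(u, v)
  s <- vnorm(w)
  cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to u
    aux <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    k <- unitv(cross3(u, aux))
    return(2 * outer(k, k) - diag(3))
  }
  k <- w / s
  kx <- matrix(c(0, k[3L], -k[2L], -k[3L], 0, k[1L], k[2L], -k[1L], 0), 3L, 3L)
  diag(3) + s * kx + (1 - cth) * (kx %*% kx)
}

# Rotation by angle theta (radians) about unit axis k.
rotation_about <- function(k, theta) {
  k <- unitv(k)
  kx <- matrix(c(0, k[3L], -k[2L],
                 -k[3L], 0, k[1L],
                 k[2L], -k[1L], 0), 3L, 3L)
  diag(3) + sin(theta) * kx + (1 - cos(theta)) * (kx %*% kx)
}

# Uniformly distributed random proper rotation (QR of a Gaussian matrix
# with sign fix); consumes the current RNG stream.
random_rotation <- function() {
  m <- matrix(stats::rnorm(9L), 3L, 3L)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Deterministic spread of n unit vectors over the sphere (Fibonacci
# lattice); used to lay residues around a ligand without collisions.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
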
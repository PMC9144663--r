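# Low-level vector geometry shared by the structure model and the builder.
# All distances in Angstrom, all angles in degrees unless noted.

DEG <- pi / 180

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vhat <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  a / n
}

#' Wrap an angle into the interval (-180, 180]
#'
#' @param x angle(s) in degrees.
#' @return wrapped angle(s) in degrees, in `(-180, 180]`.
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * round(x / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

# Signed IUPAC torsion p1-p2-p3-p4 in degrees, (-180, 180].
torsion4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("undefined torsion: three consecutive atoms are collinear")
  m1 <- vcross(n1, vhat(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) / DEG
  wrap_angle(ang)
}

# Bond angle at b (a-b-c), degrees.
angle3 <- function(a, b, c) {
  u <- vhat(a - b)
  v <- vhat(c - b)
  acos(max(-1, min(1, sum(u * v)))) / DEG
}

# Place atom D given reference atoms A (bond), B (angle), C (torsion) so that
# |D-A| = r, angle(D,A,B) = theta and torsion(D,A,B,C) = phi (degrees).
# Standard internal-to-Cartesian (NeRF-style) construction.
place_atom <- function(A, B, C, r, theta, phi) {
  th <- theta * DEG
  ph <- phi * DEG
  ab <- vhat(A - B)
  n <- vcross(B - C, A - B)
  if (vnorm(n) < 1e-9) stop("degenerate reference frame for atom placement")
  n <- vhat(n)
  m <- vcross(n, ab)
  d <- r * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  A + d[1] * ab + d[2] * m + d[3] * n
}

# Optimal superposition (Kabsch) of moving onto fixed; both n x 3 matrices.
# Returns list(rmsd, rotation, translation, moved).
kabsch_superpose <- function(moving, fixed) {
  stopifnot(nrow(moving) == nrow(fixed), ncol(moving) == 3, ncol(fixed) == 3)
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  X <- sweep(moving, 2, cm)
  Y <- sweep(fixed, 2, cf)
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- X %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Y)^2)))
  list(rmsd = rmsd, rotation = R, translation = cf - cm,
       moved = sweep(moved, 2, cf, "+"))
}

# Heavy-atom RMSD after optimal superposition of two conformers with the
# same atom ordering.
heavy_atom_rmsd <- function(conf_a, conf_b) {
  ha <- which(conf_a$atoms$element != "H")
  hb <- which(conf_b$atoms$element != "H")
  if (length(ha) != length(hb))
    stop("conformers have different heavy-atom counts")
  A <- as.matrix(conf_a$atoms[ha, c("x", "y", "z")])
  B <- as.matrix(conf_b$atoms[hb, c("x", "y", "z")])
  kabsch_superpose(A, B)$rmsd
}
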
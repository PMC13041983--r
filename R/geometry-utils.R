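# Internal vector geometry: cross products, torsions, NeRF atom placement,
# deterministic sphere point sets. All coordinates in Angstrom, angles in
# degrees unless noted.

DEG <- pi / 180

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize zero-length vector")
  a / n
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention; returns degrees in (-180, 180]. Returns `NA` (with a
#' warning) for degenerate (collinear) geometry where the torsion is undefined.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees, or `NA_real_` if undefined.
#' @keywords internal
torsion_angle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b2 <- p4 - p3
  if (vnorm(vcross(b0, b1)) < 1e-9 || vnorm(vcross(b1, b2)) < 1e-9) {
    warning("degenerate (collinear) atoms: torsion undefined")
    return(NA_real_)
  }
  b1 <- vunit(b1)
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(vcross(b1, v) * w)
  ang <- atan2(y, x) / DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

bond_angle <- function(p1, p2, p3) {
  v1 <- vunit(p1 - p2)
  v2 <- vunit(p3 - p2)
  acos(max(-1, min(1, sum(v1 * v2)))) / DEG
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given positions of three chained atoms A-B-C, places D such that
#' |C-D| = `bond`, angle B-C-D = `angle` and torsion A-B-C-D = `dihedral`.
#'
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * DEG
  ph <- dihedral * DEG
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Deterministic Fibonacci sphere lattice: n approximately equal-area unit
# vectors. Used by the SASA sampler so results are bit-reproducible.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of `coords_a` onto `coords_b` via SVD with a
#' proper-rotation (det +1) correction. The returned transform applies as
#' `sweep(coords_a, 2, ta) %*% rotation + tb`, i.e. rows of A are rotated about
#' their centroid and translated onto B's centroid.
#'
#' @param coords_a,coords_b n x 3 matrices of matched points, n >= 3.
#' @return list with `rotation` (3x3, det +1), `translation` (3-vector such
#'   that `coords_a %*% rotation + translation` superposes onto B), and `rmsd`
#'   in Angstrom.
#' @export
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' kabsch_superpose(a, a)$rmsd  # 0
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b))
    stop("coordinate sets must have equal length")
  if (nrow(coords_a) < 3) stop("need at least 3 points for superposition")
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca)
  B <- sweep(coords_b, 2, cb)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  rot <- t(R)  # row-vector convention: x %*% rot
  Arot <- A %*% rot
  rmsd <- sqrt(mean(rowSums((Arot - B)^2)))
  list(rotation = rot, translation = as.numeric(cb - ca %*% rot), rmsd = rmsd)
}

# Apply a kabsch_superpose() transform to an n x 3 matrix.
apply_transform <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% fit$rotation, 2, fit$translation, `+`)
}
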
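#' Optimal rigid-body superposition of two matched coordinate sets
#'
#' Computes the least-squares optimal rigid superposition (rotation +
#' translation) of \code{coords_b} onto \code{coords_a} using the Kabsch
#' algorithm, enforcing a proper rotation (det = +1, no reflection).
#'
#' @param coords_a Fixed coordinates: numeric matrix, n x 3 (Angstrom).
#' @param coords_b Moving coordinates: numeric matrix, n x 3, matched row by
#'   row with \code{coords_a}.
#' @return An object of class \code{"superposition"}: a list with elements
#'   \code{rotation} (3 x 3 orthonormal matrix, det +1), \code{translation}
#'   (length-3 vector), \code{rmsd} (minimised root-mean-square deviation in
#'   Angstrom) and the two centroids. The transform maps a moving point x to
#'   \code{rotation \%*\% (x - centroid_b) + centroid_a}.
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' b <- a %*% t(rotation_matrix(c(0, 0, 1), 90)) + 5
#' sp <- superpose(a, b)
#' sp$rmsd  # ~0: a rigid motion is recovered exactly
#' @export
superpose <- function(coords_a, coords_b) {
  coords_a <- as_coord_matrix(coords_a)
  coords_b <- as_coord_matrix(coords_b)
  n <- nrow(coords_a)
  if (nrow(coords_b) != n)
    stop_lrr("geometry_error", "superpose: coordinate sets differ in length (",
             n, " vs ", nrow(coords_b), ")")
  if (n < 3)
    stop_lrr("geometry_error", "superpose needs at least 3 matched points, got ", n)
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  P <- sweep(coords_b, 2, cb)  # moving, centred
  Q <- sweep(coords_a, 2, ca)  # fixed, centred
  if (is_collinear(P) || is_collinear(Q))
    stop_lrr("geometry_error", "superpose: degenerate (collinear) point set")
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = ca - as.vector(R %*% cb),
                 centroid_a = ca, centroid_b = cb, rmsd = rmsd, n = n),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#'
#' @param sp A \code{"superposition"} object from [superpose()].
#' @param coords Numeric matrix, m x 3.
#' @return Transformed m x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  stopifnot(inherits(sp, "superposition"))
  coords <- as_coord_matrix(coords)
  sweep(coords, 2, sp$centroid_b) %*% t(sp$rotation) +
    matrix(sp$centroid_a, nrow(coords), 3, byrow = TRUE)
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation about a (not necessarily unit) axis through the origin.
#'
#' @param axis Length-3 axis vector.
#' @param angle_deg Rotation angle in degrees.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Rigid superposition of %d matched points: rmsd %.4f A\n",
              x$n, x$rmsd))
  invisible(x)
}

## ---- internal geometry helpers ----------------------------------------

as_coord_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop_lrr("geometry_error", "coordinates must be n x 3")
  if (!all(is.finite(x))) stop_lrr("geometry_error", "non-finite coordinates")
  storage.mode(x) <- "double"
  x
}

# TRUE when centred points have essentially no extent in a second direction
is_collinear <- function(centred, tol = 1e-8) {
  s <- svd(centred, nu = 0, nv = 0)$d
  s[2] < tol * max(s[1], 1)
}

# Place atom D given positions of A, B, C, the C-D bond length, the B-C-D
# angle (degrees) and the A-B-C-D dihedral (degrees). Natural-extension
# reference frame construction used to build ideal backbones.
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  tor <- dihedral_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

vec_angle_deg <- function(u, v) {
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

# rmsd between matched coordinate sets after optimal superposition
superposed_rmsd <- function(coords_a, coords_b) superpose(coords_a, coords_b)$rmsd

## ---- error helpers -----------------------------------------------------

stop_lrr <- function(class, ...) {
  stop(structure(class = c(paste0("lrr_", class), "lrr_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
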
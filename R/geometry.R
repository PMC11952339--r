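#' Wrap angles onto (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles folded onto the half-open interval (-180, 180].
#' @export
wrapAngle <- function(x) {
  r <- x %% 360
  r[r > 180] <- r[r > 180] - 360
  # %% can yield exactly -180 via floating error on negative inputs
  r[r <= -180] <- r[r <= -180] + 360
  r
}

.rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.rowdot <- function(a, b) rowSums(a * b)

.rownorm <- function(a) sqrt(rowSums(a * a))

#' Dihedral angles from four point sets
#'
#' Row-wise signed dihedral (torsion) angle for quadruples of 3D points,
#' using the standard atan2 formulation; right-handed, degrees in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 n x 3 matrices (or length-3 vectors).
#' @return numeric vector of n dihedral angles in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  if (is.null(dim(p1))) { p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3); p4 <- rbind(p4) }
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .rowcross(b1, b2)
  n2 <- .rowcross(b2, b3)
  m1 <- .rowcross(n1, b2 / .rownorm(b2))
  wrapAngle(atan2(.rowdot(m1, n2), .rowdot(n1, n2)) * 180 / pi)
}

#' Bond angle at the middle point
#'
#' @param p1,p2,p3 n x 3 matrices (or length-3 vectors); the angle is at p2.
#' @return numeric vector of angles in degrees, in [0, 180].
#' @export
bondAngle <- function(p1, p2, p3) {
  if (is.null(dim(p1))) { p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3) }
  u <- p1 - p2; v <- p3 - p2
  cosang <- .rowdot(u, v) / (.rownorm(u) * .rownorm(v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three reference positions a-b-c, returns the position d such that
#' |c-d| = length, angle(b,c,d) = angle and torsion(a,b,c,d) = dihedral.
#'
#' @param a,b,c length-3 reference positions.
#' @param length bond length c-d in Angstrom.
#' @param angle bond angle b-c-d in degrees.
#' @param dihedral torsion a-b-c-d in degrees.
#' @return length-3 position of the new atom.
#' @export
placeAtom <- function(a, b, c, length, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-length * cos(th), length * sin(th) * cos(ph), -length * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Superposes \code{mobile} onto \code{reference} by the least-squares rigid
#' transform (rotation + translation, no reflection) computed over the atom
#' selection, and reports the minimized RMSD over that selection.
#'
#' @param mobile n x 3 coordinate matrix to transform.
#' @param reference n x 3 coordinate matrix (same atom order).
#' @param selection integer vector of atom indices used for the fit
#'   (default: all atoms). At least 3 indices are required.
#' @return list with \code{coords} (the transformed mobile conformation) and
#'   \code{rmsd} (Angstrom, over the selection).
#' @export
superpose <- function(mobile, reference, selection = seq_len(nrow(mobile))) {
  if (length(selection) < 3)
    stop("superposition needs at least 3 atoms in the selection (rotation under-determined)")
  if (max(selection) > nrow(mobile) || max(selection) > nrow(reference))
    stop("selection indices outside conformation")
  X <- mobile[selection, , drop = FALSE]
  Y <- reference[selection, , drop = FALSE]
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  out <- sweep(mobile, 2, cx) %*% t(R)
  out <- sweep(out, 2, cy, FUN = "+")
  fitted <- out[selection, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  list(coords = out, rmsd = rmsd)
}

# random rigid motion used by property tests and fixtures
.randomRigid <- function(coords) {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  t <- stats::runif(3, -20, 20)
  sweep(coords %*% t(R), 2, t, FUN = "+")
}
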
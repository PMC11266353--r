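# Geometric primitives shared by all analyses: minimum-image distances,
# centers of mass, best-fit ring plane normals, Kabsch superposition.

#' Minimum-image distance between two points
#'
#' Without a box this is the Euclidean distance; with an orthorhombic box the
#' displacement is wrapped to the nearest periodic image component-wise, which
#' is equivalent to (and cheaper than) minimising over the 27 neighbouring
#' images.
#'
#' @param a,b numeric(3) positions in Angstrom.
#' @param box optional numeric(3) positive box lengths.
#' @return distance in Angstrom.
#' @export
minimum_image_distance <- function(a, b, box = NULL) {
  d <- as.numeric(a) - as.numeric(b)
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (any(box <= 0)) stop("box lengths must be positive")
    d <- d - box * round(d / box)
  }
  sqrt(sum(d * d))
}

# Vectorised minimum-image pairwise distance matrix between two coordinate
# sets (or one set against itself). Used by contact and energy code.
.pair_dist_matrix <- function(xa, xb, box = NULL) {
  D2 <- matrix(0, nrow(xa), nrow(xb))
  for (k in 1:3) {
    dk <- outer(xa[, k], xb[, k], "-")
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    D2 <- D2 + dk * dk
  }
  sqrt(D2)
}

#' Mass-weighted center of mass
#'
#' @param coords k x 3 coordinate matrix (Angstrom).
#' @param masses numeric(k) non-negative weights; default equal weights.
#' @return numeric(3) center of mass.
#' @export
center_of_mass <- function(coords, masses = NULL) {
  coords <- rbind(coords)
  k <- nrow(coords)
  if (k < 1L) stop("need at least one atom")
  if (is.null(masses)) masses <- rep(1, k)
  if (length(masses) != k || any(masses < 0)) stop("invalid masses")
  tot <- sum(masses)
  if (tot <= 0) stop("total mass must be positive")
  as.numeric(crossprod(coords, masses) / tot)
}

#' Best-fit plane normal of a ring
#'
#' The unit normal is the singular vector of the centered coordinates with the
#' smallest singular value (the smallest principal axis), which is robust to
#' ring puckering. Its sign is arbitrary; consumers fold angles to [0, 90]
#' degrees.
#'
#' @param coords k x 3 matrix, k >= 3.
#' @return numeric(3) unit normal.
#' @export
ring_plane_normal <- function(coords) {
  coords <- rbind(coords)
  if (nrow(coords) < 3L) stop("need at least 3 atoms for a plane")
  cc <- sweep(coords, 2, colMeans(coords))
  sv <- svd(cc)
  d <- sv$d
  if (d[2] < 1e-12 || d[3] / d[2] > 0.99)
    stop("degenerate (collinear) ring coordinates: no unique plane")
  n <- sv$v[, 3]
  n / sqrt(sum(n * n))
}

# Unsigned angle between two plane normals, folded to [0, 90] degrees.
.interplanar_angle <- function(n1, n2) {
  c1 <- abs(sum(n1 * n2)) / sqrt(sum(n1^2) * sum(n2^2))
  acos(min(1, c1)) * 180 / pi
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the (weighted) RMSD of
#' `mobile` onto `reference`, with the reflection corrected by flipping the
#' sign of the smallest singular vector when needed. The transformed
#' coordinates are `mobile %*% rotation + translation` (row vectors).
#'
#' @param mobile,reference k x 3 coordinate matrices with correspondence by
#'   row index, k >= 3.
#' @param weights optional numeric(k) non-negative weights (default equal).
#' @return a list of class `"kabsch_fit"` with elements `rotation` (3 x 3,
#'   det = +1), `translation` (numeric(3)) and `rmsd` (Angstrom, after fit).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- rbind(mobile); reference <- rbind(reference)
  k <- nrow(mobile)
  if (nrow(reference) != k) stop("point sets must have equal size")
  if (k < 3L) stop("need at least 3 points")
  if (is.null(weights)) weights <- rep(1, k)
  if (length(weights) != k || any(weights < 0) || sum(weights) <= 0)
    stop("invalid weights")
  w <- weights / sum(weights)
  cm <- as.numeric(crossprod(mobile, w))
  cr <- as.numeric(crossprod(reference, w))
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  H <- crossprod(A * w, B)   # 3x3 covariance
  if (sum(H^2) < 1e-24) {    # all points (effectively) coincident
    R <- diag(3)
  } else {
    sv <- svd(H)
    s <- sign(det(sv$v %*% t(sv$u)))
    D <- diag(c(1, 1, s))
    R <- sv$u %*% D %*% t(sv$v)
  }
  tr <- cr - as.numeric(cm %*% R)
  fit <- A %*% R - B
  rmsd <- sqrt(sum(w * rowSums(fit^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "kabsch_fit")
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("kabsch_fit: rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a Kabsch fit to coordinates
#' @param fit a `kabsch_fit`.
#' @param coords k x 3 coordinates to transform.
#' @return transformed k x 3 coordinates.
#' @export
apply_fit <- function(fit, coords) {
  stopifnot(inherits(fit, "kabsch_fit"))
  sweep(rbind(coords) %*% fit$rotation, 2, -fit$translation)
}
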
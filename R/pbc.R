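#' Minimum-image displacement along one periodic axis
#'
#' @param d numeric vector of raw displacements (nm).
#' @param L box length (nm) along the axis.
#' @return displacements mapped into (-L/2, L/2].
#' @keywords internal
pbc_disp1 <- function(d, L) d - L * round(d / L)

#' Wrap coordinates into the primary box image
#'
#' @param x numeric vector of coordinates (nm).
#' @param L box length (nm).
#' @keywords internal
pbc_wrap1 <- function(x, L) x - L * floor(x / L)

#' Minimum-image distance between two points in an orthorhombic box
#'
#' Computes the Euclidean distance between the closest periodic images of
#' `p` and `q`. Axes flagged non-periodic use the raw displacement.
#'
#' @param p,q numeric length-3 positions (nm).
#' @param box numeric length-3 box lengths (nm), all > 0.
#' @param periodic logical length-3; which axes are periodic.
#' @return distance in nm, at most half the box diagonal over periodic axes.
#' @examples
#' minimum_image_distance(c(0.5, 0, 0), c(99.5, 0, 0), c(100, 100, 100))
#' @export
minimum_image_distance <- function(p, q, box, periodic = c(TRUE, TRUE, TRUE)) {
  if (!all(is.finite(p)) || !all(is.finite(q))) {
    stop("minimum_image_distance: non-finite coordinates")
  }
  if (!all(is.finite(box)) || any(box <= 0)) {
    stop("minimum_image_distance: box lengths must be finite and > 0")
  }
  d <- q - p
  for (a in 1:3) if (periodic[a]) d[a] <- pbc_disp1(d[a], box[a])
  sqrt(sum(d * d))
}

#' Minimum-image displacement matrix
#'
#' Row-wise displacements `P - q0` with the minimum-image convention applied
#' per periodic axis.
#'
#' @param P n x 3 coordinate matrix.
#' @param q0 length-3 reference point.
#' @param box,periodic as in [minimum_image_distance()].
#' @keywords internal
pbc_disp_mat <- function(P, q0, box, periodic = c(TRUE, TRUE, TRUE)) {
  D <- sweep(P, 2, q0, "-")
  for (a in 1:3) if (periodic[a]) D[, a] <- pbc_disp1(D[, a], box[a])
  D
}

#' Squared minimum-image distances between two point sets
#'
#' @param P n x 3, Q m x 3 coordinate matrices.
#' @param dims axes to include (e.g. `c(1, 3)` for lateral XZ distance).
#' @return n x m matrix of squared distances over the selected axes.
#' @keywords internal
pbc_dist2_cross <- function(P, Q, box, periodic = c(TRUE, TRUE, TRUE),
                            dims = 1:3) {
  n <- nrow(P)
  m <- nrow(Q)
  D2 <- matrix(0, n, m)
  for (a in dims) {
    d <- outer(P[, a], Q[, a], "-")
    if (periodic[a]) d <- pbc_disp1(d, box[a])
    D2 <- D2 + d * d
  }
  D2
}

#' Circular-mean centroid of points on a periodic axis
#'
#' Centroid computed via the angular mean, invariant under wrapping of any
#' subset of the points.
#'
#' @keywords internal
pbc_centroid <- function(P, box, periodic = c(TRUE, TRUE, TRUE)) {
  vapply(1:3, function(a) {
    x <- P[, a]
    if (!periodic[a]) return(mean(x))
    th <- 2 * pi * x / box[a]
    ang <- atan2(mean(sin(th)), mean(cos(th)))
    pbc_wrap1(ang * box[a] / (2 * pi), box[a])
  }, numeric(1))
}
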
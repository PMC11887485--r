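#' Radius of an (n,m) carbon nanotube
#'
#' Closed-form radius of the roll-up construction,
#' \eqn{r = a\sqrt{n^2 + nm + m^2}/(2\pi)} with graphene lattice constant
#' `a` = 2.461 Angstrom. The (9,4) species modeled here has r ~ 4.52 A.
#'
#' @param n,m Chirality integers (n >= m >= 0, n > 0).
#' @param a Graphene lattice constant in Angstrom.
#' @return Radius in Angstrom.
#' @examples
#' swcnt_radius(9, 4)
#' @export
swcnt_radius <- function(n, m, a = 2.461) {
  if (n <= 0 || m < 0 || m > n) abort("nonphysical chirality: need n >= m >= 0, n > 0")
  a * sqrt(n^2 + n * m + m^2) / (2 * pi)
}

#' Fit a cylinder to nanotube coordinates
#'
#' Axis = principal axis of the coordinate cloud (largest-variance
#' eigenvector of the covariance); radius = mean perpendicular distance of
#' the atoms to that axis. Assumes the nanotube is whole (unwrapped across
#' periodic boundaries). Errors on a near-spherical cloud where no
#' principal axis is defined.
#'
#' @param coords Numeric matrix (n x 3) of SWCNT atom coordinates in
#'   Angstrom; n >= 10.
#' @return List of class `nanosar_cylinder`: `axis_point` (centroid),
#'   `axis_dir` (unit vector), `radius` (Angstrom).
#' @export
fit_cylinder <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 10) abort("need >= 10 atoms to fit a cylinder")
  if (!all(is.finite(coords)) || ncol(coords) != 3) {
    abort("coords must be a finite n x 3 matrix")
  }
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  if (ev$values[1] < 1.5 * ev$values[2]) {
    abort("degenerate point cloud: no dominant principal axis")
  }
  axis <- ev$vectors[, 1]
  axis <- axis / sqrt(sum(axis^2))
  if (axis[which.max(abs(axis))] < 0) axis <- -axis   # sign convention
  perp <- perp_distance(coords, ctr, axis)
  structure(list(axis_point = ctr, axis_dir = axis, radius = mean(perp)),
            class = "nanosar_cylinder")
}

#' @export
print.nanosar_cylinder <- function(x, ...) {
  cat(sprintf("Cylinder: radius %.3f A, axis (%.3f, %.3f, %.3f)\n",
              x$radius, x$axis_dir[1], x$axis_dir[2], x$axis_dir[3]))
  invisible(x)
}

# perpendicular distance of points (n x 3) to the line (point, unit dir)
perp_distance <- function(points, point, dir) {
  points <- matrix(points, ncol = 3)
  rel <- sweep(points, 2, point)
  proj <- as.vector(rel %*% dir)
  sqrt(pmax(rowSums(rel^2) - proj^2, 0))
}

#' Distance from a point to the nanotube surface
#'
#' Cylindrical-coordinate surface distance
#' \eqn{d(t) = r_{analyte}(t) - r_{SWNT}}: the radial distance of the
#' point from the tube axis minus the tube radius. Negative inside the
#' wall radius.
#'
#' @param points Numeric vector of length 3 or n x 3 matrix.
#' @param cylinder A [fit_cylinder()] model.
#' @return Numeric vector of surface distances in Angstrom.
#' @export
surface_distance <- function(points, cylinder) {
  stopifnot(inherits(cylinder, "nanosar_cylinder"))
  points <- matrix(points, ncol = 3)
  if (!all(is.finite(points))) abort("points must be finite")
  perp_distance(points, cylinder$axis_point, cylinder$axis_dir) -
    cylinder$radius
}
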
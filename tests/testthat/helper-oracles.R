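# Independent oracles used to check the package's geometric and
# statistical primitives. These deliberately share no code with the
# implementation paths they verify.

# Monte-Carlo surface-integration SASA: random points on each expanded
# sphere, accessible if outside every other expanded sphere.
mc_sasa <- function(coords, radii, probe = 1.4, n_mc = 2e5, seed = 42) {
  set.seed(seed)
  coords <- matrix(coords, ncol = 3)
  er <- radii + probe
  total <- 0
  for (i in seq_len(nrow(coords))) {
    z <- runif(n_mc, -1, 1)
    phi <- runif(n_mc, 0, 2 * pi)
    rho <- sqrt(1 - z^2)
    pts <- cbind(coords[i, 1] + er[i] * rho * cos(phi),
                 coords[i, 2] + er[i] * rho * sin(phi),
                 coords[i, 3] + er[i] * z)
    outside <- rep(TRUE, n_mc)
    for (j in seq_len(nrow(coords))) {
      if (j == i) next
      d2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
        (pts[, 3] - coords[j, 3])^2
      outside <- outside & d2 >= er[j]^2
    }
    total <- total + 4 * pi * er[i]^2 * mean(outside)
  }
  total
}

mc_contact_area <- function(ca, ra, cb, rb, probe = 1.4, n_mc = 2e5) {
  (mc_sasa(ca, ra, probe, n_mc, seed = 1) +
     mc_sasa(cb, rb, probe, n_mc, seed = 2) -
     mc_sasa(rbind(matrix(ca, ncol = 3), matrix(cb, ncol = 3)),
             c(ra, rb), probe, n_mc, seed = 3)) / 2
}

# analytic SASA of two overlapping spheres (expanded radii R1, R2 at
# center distance d): each loses a spherical cap 2*pi*R*h
two_sphere_sasa <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h1 + 4 * pi * R2^2 - 2 * pi * R2 * h2
}

# brute-force Pearson r / p from the textbook definitions
brute_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# run-length oracle for event segmentation of a boolean trace
brute_events <- function(bound) {
  runs <- list()
  i <- 1
  while (i <= length(bound)) {
    if (bound[i]) {
      j <- i
      while (j < length(bound) && bound[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(start = i, end = j)
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

# tiny trajectory bundle around hand-placed coordinates
toy_bundle <- function(coords, elements = NULL, box = c(60, 60, 60),
                       dt = 1, groups = NULL) {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (is.null(elements)) elements <- rep("C", n)
  atoms <- tibble::tibble(atom_id = seq_len(n), element = elements)
  if (is.null(groups)) {
    groups <- list(swcnt = 1L, dna = list(all = 2L),
                   analytes = list(list(atoms = setdiff(seq_len(n), 1:2),
                                        aryl_ring = setdiff(seq_len(n), 1:2),
                                        polar_groups = list())))
  }
  trajectory_bundle(atoms, groups, array(coords, c(1, n, 3)), box, dt)
}

# ideal cylinder point cloud
make_cylinder_points <- function(radius, length = 40, n_ring = 24,
                                 n_z = 25) {
  th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  zs <- seq(-length / 2, length / 2, length.out = n_z)
  do.call(rbind, lapply(zs, function(z) {
    cbind(radius * cos(th), radius * sin(th), z)
  }))
}

# rotation matrix about a unit axis
rot_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
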
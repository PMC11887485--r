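# shared small simulation used across trajectory-metric tests
sim_cache <- local({
  w <- build_world(seed = 2)
  s <- c("free", "stack_swcnt", "stack_dna", "inserted")
  R <- matrix(0, 4, 4, dimnames = list(s, s))
  R["free", "stack_swcnt"] <- 1.2
  R["stack_swcnt", "free"] <- 0.8
  kin <- kinetic_params(R, dt = 0.05, n_frames = 50, seed = 17)
  sim <- simulate_trajectory(w, kin)
  cyl <- fit_cylinder(sim$traj$coords[1, w$groups$swcnt, ])
  list(w = w, sim = sim, cyl = cyl)
})

test_that("trajectory bundle validation rejects broken input", {
  w <- sim_cache$w
  expect_error(trajectory_bundle(w$atoms, w$groups,
                                 w$init_coords * NA, w$box, 1), "finite")
  bad_groups <- w$groups
  bad_groups$analytes[[1]]$atoms <- w$groups$swcnt[1:9]
  expect_error(trajectory_bundle(w$atoms, bad_groups, w$init_coords,
                                 w$box, 1), "disjoint")
  expect_error(trajectory_bundle(w$atoms, w$groups, w$init_coords,
                                 w$box, 0), "dt")
})

test_that("contact series agrees with direct contact_area calls", {
  traj <- sim_cache$sim$traj
  cs <- contact_series(traj, "conjugate", n_sphere_points = 128)
  tgt <- c(traj$groups$swcnt, traj$groups$dna$all)
  radii <- traj$atoms$radius
  for (row in c(5, 100, 200)) {
    fr <- cs$frame[row]; m <- cs$molecule[row]
    mi <- traj$groups$analytes[[m]]$atoms
    a <- traj$coords[fr, mi, , drop = TRUE]
    b <- traj$coords[fr, tgt, , drop = TRUE]
    sep <- min(sqrt(outer(rowSums(a^2), rowSums(b^2), "+") -
                      2 * tcrossprod(a, b)))
    direct <- if (sep > 2 * max(radii) + 2.8) 0 else
      contact_area(a, radii[mi], b, radii[tgt], n_sphere_points = 128)
    expect_equal(cs$area[row], direct, tolerance = 1e-9)
  }
})

test_that("contact areas separate bound from free ground-truth frames", {
  cs <- contact_series(sim_cache$sim$traj, "conjugate")
  st <- sim_cache$sim$truth$states
  joined <- merge(as.data.frame(cs), as.data.frame(st),
                  by = c("frame", "molecule"))
  expect_true(all(joined$area[joined$state == "free"] < 1))
  bound_areas <- joined$area[joined$state == "stack_swcnt"]
  expect_gt(length(bound_areas), 0)
  expect_true(all(bound_areas > 30))
})

test_that("stacking distance recovers the generator offset", {
  sdist <- stacking_distance(sim_cache$sim$traj, sim_cache$cyl)
  # conditional mean over frames < 10 A, averaged over molecules
  st <- sim_cache$sim$truth$states
  n_bound <- sum(st$state == "stack_swcnt")
  se <- 0.2 / sqrt(n_bound)
  expect_lt(abs(attr(sdist, "overall") - 3.4), 3 * se + 0.05)

  # hand-checked conditional mean: {3, 5, 12} with cutoff 10 -> 4
  w <- sim_cache$w
  aryl1 <- w$groups$analytes[[1]]$aryl_ring
  co <- array(rep(w$init_coords, 3), c(dim(w$init_coords), 3))
  co <- aperm(co, c(3, 1, 2))
  r <- sim_cache$cyl$radius
  for (fr in 1:3) {
    d_target <- c(3, 5, 12)[fr]
    ring <- w$init_coords[aryl1, ]
    ring_com <- colMeans(ring)
    new_com <- c(r + d_target, 0, 0)
    co[fr, aryl1, ] <- sweep(ring, 2, ring_com - new_com)
  }
  tr3 <- trajectory_bundle(w$atoms, w$groups, co, w$box, 1)
  s3 <- stacking_distance(tr3, sim_cache$cyl)
  expect_equal(s3$mean_distance[1], 4, tolerance = 0.02)
})

test_that("polar distance distribution pools hydroxy groups near the surface", {
  pd <- polar_distance_distribution(sim_cache$sim$traj, "hydroxy",
                                    sim_cache$cyl)
  expect_gt(attr(pd, "n_samples"), 0)
  expect_equal(sum(pd$density * (pd$bin_right - pd$bin_left)), 1,
               tolerance = 1e-6)
  # hydroxys ride at the aryl offset in this template: mass near 3.4 A
  expect_gt(auc_below(pd, 5), 0.9)

  aucs <- polar_auc(sim_cache$sim$traj, "hydroxy", sim_cache$cyl, x = 4)
  expect_equal(nrow(aucs), 2L)   # two vicinal hydroxys
  expect_equal(attr(aucs, "class_sum"), sum(aucs$auc))
})

test_that("binding-mode assignment round-trips generator ground truth", {
  w <- sim_cache$w
  s <- c("free", "stack_swcnt", "stack_dna", "inserted")
  mk <- function(tgt) {
    R <- matrix(0, 4, 4, dimnames = list(s, s))
    R["free", tgt] <- 2; R[tgt, "free"] <- 0.5
    kinetic_params(R, dt = 0.05, n_frames = 26, seed = 33)
  }
  for (want in c("stack_swcnt", "stack_dna", "inserted")) {
    sim <- simulate_trajectory(w, mk(want))
    cyl <- fit_cylinder(sim$traj$coords[1, w$groups$swcnt, ])
    mode <- classify_binding_mode(sim$traj, cyl)
    got <- mode$mode[mode$n_bound_frames > 0]
    expect_gt(length(got), 0)
    label <- if (want == "inserted") "insertion" else want
    expect_true(all(got == label))
  }

  # constructed 50/50 alternation between the stacking states -> both
  kin <- mk("stack_swcnt")
  paths <- replicate(6, rep(c("stack_swcnt", "stack_dna"), 13),
                     simplify = FALSE)
  simb <- simulate_trajectory(w, kin, state_paths = paths)
  cylb <- fit_cylinder(simb$traj$coords[1, w$groups$swcnt, ])
  modeb <- classify_binding_mode(simb$traj, cylb)
  expect_true(all(modeb$mode == "both"))

  # never-bound molecules are reported unbound
  pathsf <- replicate(6, rep("free", 26), simplify = FALSE)
  simf <- simulate_trajectory(w, kin, state_paths = pathsf)
  modef <- classify_binding_mode(simf$traj, cylb)
  expect_true(all(modef$mode == "unbound"))
})

test_that("PDB text round trip preserves topology for the reader", {
  w <- build_world(seed = 12)
  tmp <- tempfile(fileext = ".pdb")
  xyz <- w$init_coords
  n <- nrow(xyz)
  bio3d::write.pdb(file = tmp, xyz = as.vector(t(xyz)),
                   elety = w$atoms$name, eleno = seq_len(n),
                   resno = rep(1L, n), resid = rep("MOL", n))
  tr <- read_trajectory(tmp, groups = w$groups, box = w$box, dt = 1)
  expect_equal(dim(tr$coords), c(1, nrow(xyz), 3))
  expect_equal(tr$coords[1, , ], unname(xyz), tolerance = 1e-3)
  com1 <- colMeans(tr$coords[1, w$groups$swcnt, ])
  expect_equal(com1, unname(colMeans(xyz[w$groups$swcnt, ])),
               tolerance = 1e-3)
})
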
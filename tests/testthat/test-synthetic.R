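test_that("world construction is deterministic and satisfies invariants", {
  w1 <- build_world(seed = 6)
  w2 <- build_world(seed = 6)
  expect_identical(w1$init_coords, w2$init_coords)
  expect_identical(w1$atoms, w2$atoms)

  # groups disjoint and complete enough to build a bundle
  tr <- trajectory_bundle(w1$atoms, w1$groups, w1$init_coords, w1$box, 1)
  expect_s3_class(tr, "trajectory_bundle")
  expect_equal(length(w1$groups$analytes), 6L)
  # backbone tags present
  for (nm in c("P", "O1P", "O2P", "O3'", "O4'", "O5'")) {
    expect_gt(length(w1$groups$dna[[nm]]), 0)
  }
  # monotone radius in chirality norm
  expect_gt(build_world(chirality = c(10, 10), seed = 1)$radius, w1$radius)
  expect_error(build_world(chirality = c(4, 9)), "chirality")
})

test_that("simulated trajectories are seed-reproducible with consistent truth", {
  w <- build_world(seed = 3)
  kin <- two_state_kinetics(k_on = 0.5, k_off = 1, dt = 0.05,
                            n_frames = 40, seed = 21)
  s1 <- simulate_trajectory(w, kin)
  s2 <- simulate_trajectory(w, kin)
  expect_identical(s1$traj$coords, s2$traj$coords)
  expect_identical(s1$truth$states, s2$truth$states)

  # free frames really sit >= 12 A from the surface; bound frames near it
  cyl <- fit_cylinder(s1$traj$coords[1, w$groups$swcnt, ])
  st <- s1$truth$states
  for (m in 1:2) {
    aryl <- w$groups$analytes[[m]]$aryl_ring
    d <- vapply(seq_len(nanosar::n_frames(s1$traj)), function(fr) {
      ring <- matrix(s1$traj$coords[fr, aryl, ], ncol = 3)
      surface_distance(colMeans(ring), cyl)
    }, numeric(1))
    states_m <- st$state[st$molecule == m]
    expect_true(all(d[states_m == "free"] > 11))
    if (any(states_m == "stack_swcnt")) {
      expect_true(all(abs(d[states_m == "stack_swcnt"] - 3.4) < 1.2))
    }
  }
})

test_that("kinetic parameter guards reject unstable discretization", {
  expect_error(two_state_kinetics(5, 5, dt = 0.05, n_frames = 10),
               "dt")
  k <- two_state_kinetics(0.5, 1, dt = 0.05, n_frames = 10)
  expect_s3_class(k, "kinetic_params")
  expect_error(kinetic_params(matrix(-1, 2, 2), 0.1, 10), "nonnegative")
})

test_that("absorbing and unreachable states behave as limits demand", {
  w <- build_world(seed = 5)
  # k_off = 0: once bound, a single event spans the remainder
  s <- c("free", "stack_swcnt")
  R <- matrix(c(0, 2, 0, 0), 2, 2, byrow = TRUE, dimnames = list(s, s))
  sim <- simulate_trajectory(w, kinetic_params(R, 0.05, 50, seed = 2))
  st <- sim$truth$states
  for (m in seq_len(6)) {
    sm <- st$state[st$molecule == m]
    if (any(sm == "stack_swcnt")) {
      first <- which(sm == "stack_swcnt")[1]
      expect_true(all(sm[first:length(sm)] == "stack_swcnt"))
    }
  }
  # k_on = 0: never binds
  R0 <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE, dimnames = list(s, s))
  sim0 <- simulate_trajectory(w, kinetic_params(R0, 0.05, 30, seed = 3))
  expect_true(all(sim0$truth$states$state == "free"))
})

test_that("markov contact generator is seeded and hits its stationary point", {
  a <- simulate_markov_contacts(0.03, 0.03, 3000, seed = 9)
  b <- simulate_markov_contacts(0.03, 0.03, 3000, seed = 9)
  expect_identical(a$series$area, b$series$area)
  # symmetric chain occupies ~ 1/2
  big <- simulate_markov_contacts(0.05, 0.05, 20000, n_molecules = 6,
                                  seed = 19)
  bf <- bound_fraction(big$series)
  se <- stats::sd(bf$pct_bound) / sqrt(nrow(bf))
  expect_lt(abs(attr(bf, "pooled") - 50), 3 * se + 0.5)
  # truth states agree with the emitted areas at the 30 A^2 level
  expect_lt(mean((big$series$area > 30) != big$truth$bound), 0.001)
})

test_that("spectrum generator honors dff, noise and validation rules", {
  sp0 <- generate_spectrum(0, noise_sd = 0)
  expect_equal(sp0$F$intensity, sp0$F0$intensity, tolerance = 1e-12)
  sp <- generate_spectrum(0.25, noise_sd = 0)
  expect_equal(compute_dff(integrate_spectrum(sp$F0),
                           integrate_spectrum(sp$F)), 0.25,
               tolerance = 1e-12)
  expect_error(generate_spectrum(
    0.1, peaks = tibble::tibble(center = 1100, width = 10,
                                amplitude = -1)), "amplitude")
  s1 <- generate_spectrum(0.1, noise_sd = 0.01, seed = 4)
  s2 <- generate_spectrum(0.1, noise_sd = 0.01, seed = 4)
  expect_identical(s1$F$intensity, s2$F$intensity)
})

test_that("screen dataset generation requires the DA reference", {
  lib <- tibble::tibble(analyte_id = "T", true_normalized = 0.208)
  expect_error(generate_screen_dataset(lib), "DA")
  lib2 <- tibble::tibble(analyte_id = c("DA", "T"),
                         true_normalized = c(0.9, 0.2))
  expect_error(generate_screen_dataset(lib2), "DA")
})

test_that("packaged fixtures carry the printed reference values", {
  fx <- compound_fixture()
  expect_equal(fx$normalized_dff[fx$analyte_id == "DA"], 1.00)
  expect_equal(fx$normalized_dff[fx$analyte_id == "T"], 0.208)
  expect_equal(fx$normalized_dff[fx$analyte_id == "1"], -0.056)
  # printed values map onto the printed categories
  tcat <- as.character(classify_response(
    fx$normalized_dff[fx$analyte_id == "T"]))
  expect_equal(tcat, fx$category[fx$analyte_id == "T"])
  expect_equal(as.character(classify_response(
    fx$normalized_dff[fx$analyte_id == "1"])), "IV")

  pk <- pka_fixture()
  expect_equal(pk$pKa[pk$analyte_id == "DA"], 9.31)
  expect_equal(pk$pKa[pk$analyte_id == "F"], 4.96)
  expect_true(all(pk$site_class == "base"))
})
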
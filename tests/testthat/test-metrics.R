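test_that("bound fraction counts threshold crossings per molecule and pooled", {
  s <- as_contact_series(frame = rep(1:4, 2), molecule = rep(1:2, each = 4),
                         area = c(5, 5, 5, 5, 0, 0, 0, 5), dt = 1)
  bf <- bound_fraction(s, threshold = 1)
  expect_equal(bf$pct_bound, c(100, 25))
  expect_equal(attr(bf, "pooled"), 62.5)
  expect_equal(bound_fraction(s, threshold = 10)$pct_bound, c(0, 0))
})

test_that("event segmentation matches a run-length oracle on boolean traces", {
  # 000111100110 with dt = 1 -> events of durations 4 and 2
  trace <- c(0, 0, 0, 1, 1, 1, 1, 0, 0, 1, 1, 0)
  s <- as_contact_series(frame = seq_along(trace), molecule = 1L,
                         area = trace * 40, dt = 1)
  ev <- segment_binding_events(s, area_threshold = 30)
  expect_equal(ev$duration, c(4, 2))
  expect_equal(ev$start_frame, c(4, 10))
  expect_equal(ev$end_frame, c(7, 11))

  # all-bound trace is a single full-length event
  s2 <- as_contact_series(1:7, rep(1L, 7), rep(50, 7), dt = 0.5)
  ev2 <- segment_binding_events(s2)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$duration, 7 * 0.5)

  # random boolean traces against the oracle
  set.seed(14)
  for (i in 1:8) {
    b <- runif(60) < 0.4
    s3 <- as_contact_series(1:60, rep(1L, 60), ifelse(b, 45, 0), dt = 1)
    ev3 <- segment_binding_events(s3)
    runs <- brute_events(b)
    expect_equal(nrow(ev3), length(runs))
    if (length(runs)) {
      expect_equal(ev3$start_frame, vapply(runs, `[[`, 0, "start"))
      expect_equal(ev3$end_frame, vapply(runs, `[[`, 0, "end"))
    }
  }
})

test_that("the amine-distance condition splits events frame-wise", {
  area <- rep(50, 10)
  dist <- c(5, 5, 5, 12, 12, 5, 5, 5, 5, 5)  # fails on 2 interior frames
  s <- as_contact_series(1:10, rep(1L, 10), area, dt = 1)
  amine <- tibble::tibble(frame = 1:10, molecule = 1L, distance = dist)
  ev <- segment_binding_events(s, amine)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$duration, c(3, 5))

  # molecules without amine groups ignore the distance criterion
  s2 <- as_contact_series(rep(1:10, 2), rep(1:2, each = 10),
                          rep(area, 2), dt = 1)
  amine1 <- tibble::tibble(frame = 1:10, molecule = 1L, distance = dist)
  ev2 <- segment_binding_events(s2, amine1)
  expect_equal(nrow(ev2[ev2$molecule == 2, ]), 1L)

  # misaligned distance series is an error
  expect_error(segment_binding_events(s, amine[1:5, ]), "misaligned")
})

test_that("gap tolerance bridges short interior dropouts only", {
  b <- c(1, 1, 0, 1, 1, 0, 0, 0, 1)
  s <- as_contact_series(1:9, rep(1L, 9), b * 40, dt = 1)
  strict <- segment_binding_events(s)
  expect_equal(strict$duration, c(2, 2, 1))
  bridged <- segment_binding_events(s, gap_tolerance = 1)
  expect_equal(bridged$duration, c(5, 1))
})

test_that("residence time is the pooled mean event duration", {
  expect_equal(residence_time(10)$tau_R, 10)
  rt <- residence_time(c(2, 2, 6))
  expect_equal(rt$tau_R, 10 / 3)
  expect_equal(rt$n_events, 3L)
  # identity: total bound time / number of events
  set.seed(31)
  d <- rexp(50, 0.2)
  expect_equal(residence_time(d)$tau_R, sum(d) / 50)
  expect_error(residence_time(numeric(0)), "never bound")
})

test_that("Markov contact series recover kinetics across a rate grid", {
  # stationary occupancy and mean dwell across a small (p_on, p_off) grid
  for (ps in list(c(0.02, 0.05), c(0.05, 0.02), c(0.03, 0.03))) {
    sim <- simulate_markov_contacts(ps[1], ps[2], n_frames = 8000,
                                    n_molecules = 6, dt = 1,
                                    seed = 1000 + round(1e3 * ps[1]))
    bf <- bound_fraction(sim$series, threshold = 1)
    occ_hat <- attr(bf, "pooled") / 100
    occ <- ps[1] / (ps[1] + ps[2])
    se <- stats::sd(bf$pct_bound / 100) / sqrt(nrow(bf))
    expect_lt(abs(occ_hat - occ), 3 * se + 0.01)

    ev <- segment_binding_events(sim$series, area_threshold = 30, dt = 1)
    rt <- residence_time(ev)
    expect_gt(rt$n_events, 100)
    expect_equal(rt$tau_R, 1 / ps[2], tolerance = 0.15)
  }
})

test_that("frame-stride thinning preserves expected occupancy", {
  sim <- simulate_markov_contacts(0.02, 0.04, n_frames = 20000,
                                  n_molecules = 4, dt = 1, seed = 77)
  full <- attr(bound_fraction(sim$series), "pooled")
  thin <- sim$series[sim$series$frame %% 2 == 0, ]
  half <- attr(bound_fraction(thin), "pooled")
  expect_equal(half, full, tolerance = 0.02)
})

test_that("distance distributions integrate to 1 with correct AUC behavior", {
  # single occupied bin
  d1 <- distance_distribution(rep(3.0, 50))
  expect_equal(sum(d1$density * (d1$bin_right - d1$bin_left)), 1)
  expect_equal(sum(d1$density > 0), 1L)

  # exactly uniform samples give a flat 0.1/A density and AUC(4) = 0.4
  u <- rep(seq(0.05, 9.95, by = 0.1), each = 3)
  du <- distance_distribution(u)
  expect_equal(du$density, rep(0.1, 100), tolerance = 1e-12)
  expect_equal(auc_below(du, 4), 0.4, tolerance = 1e-12)
  expect_equal(auc_below(du, 10), 1, tolerance = 1e-12)

  # monotone nondecreasing in x; partial bins interpolate
  xs <- seq(0, 10, by = 0.37)
  aucs <- vapply(xs, function(x) auc_below(du, x), numeric(1))
  expect_true(all(diff(aucs) >= -1e-12))
  expect_error(auc_below(du, 12), "outside")

  # everything below 4 A
  d4 <- distance_distribution(runif(100, 0, 3.9))
  expect_equal(auc_below(d4, 4), 1, tolerance = 1e-12)

  # samples at the closed upper bound are kept
  db <- distance_distribution(c(1, 10))
  expect_equal(attr(db, "n_samples"), 2L)
  expect_equal(sum(db$density * (db$bin_right - db$bin_left)), 1)

  expect_warning(distance_distribution(numeric(0)), "empty")
})

test_that("g(r) is flat for ideal-gas points and respects exclusions", {
  set.seed(8)
  n <- 500; nf <- 10; box <- c(30, 30, 30)
  coords <- array(runif(nf * n * 3, 0, 30), c(nf, n, 3))
  atoms <- tibble::tibble(atom_id = 1:n, element = "C")
  groups <- list(swcnt = 1:10, dna = list(all = 11:20),
                 analytes = list(list(atoms = 21:30, aryl_ring = 21:30,
                                      polar_groups = list())))
  tr <- trajectory_bundle(atoms, groups, coords, box, dt = 1)
  g <- radial_distribution(tr, 1:250, 251:500, r_max = 12, bin_width = 0.5)
  expect_equal(mean(g$g[g$r > 2]), 1, tolerance = 0.05)

  # single fixed pair occupies exactly one bin
  pair <- rbind(c(15, 15, 15), c(15 + 4.3, 15, 15))
  filler <- cbind(4 + (3:22), 1, 1)
  tr2 <- toy_bundle(rbind(pair, filler),
                    groups = list(swcnt = 3:12, dna = list(all = 13:22),
                                  analytes = list(list(atoms = 1:2,
                                                       aryl_ring = 1:2,
                                                       polar_groups = list()))))
  g2 <- radial_distribution(tr2, 1L, 2L, r_max = 8, bin_width = 0.1)
  expect_equal(sum(g2$g > 0), 1L)
  expect_lt(abs(g2$r[g2$g > 0] - 4.3), 0.1)

  expect_error(radial_distribution(tr, 1:10, 11:20, r_max = 20), "half")
})

test_that("hydrogen bonds require both distance and near-linear geometry", {
  mk <- function(coords) {
    n <- nrow(coords)
    toy_bundle(coords, elements = c("O", "H", "O", rep("C", n - 3))[1:n])
  }
  # ideal linear O-H...O at 2.8 A
  lin <- rbind(c(0, 0, 0), c(0.97, 0, 0), c(2.8, 0, 0))
  hb <- count_hbonds(mk(lin), tibble::tibble(d_idx = 1L, h_idx = 2L), 3L)
  expect_equal(hb$n_hbonds, 1L)

  # same geometry stretched beyond the cutoff
  far <- rbind(c(0, 0, 0), c(0.97, 0, 0), c(4.5, 0, 0))
  expect_equal(count_hbonds(mk(far), tibble::tibble(d_idx = 1L, h_idx = 2L),
                            3L)$n_hbonds, 0L)

  # bent geometry fails the angle criterion
  bent <- rbind(c(0, 0, 0), c(0.97, 0, 0), c(0.97, 2.6, 0))
  expect_equal(count_hbonds(mk(bent), tibble::tibble(d_idx = 1L, h_idx = 2L),
                            3L)$n_hbonds, 0L)

  expect_error(count_hbonds(mk(lin),
                            tibble::tibble(d_idx = 1L, h_idx = NA_integer_),
                            3L), "missing")
})

test_that("hydrogen-bond counts equal exhaustive pair enumeration", {
  set.seed(23)
  co <- matrix(runif(10 * 3, 0, 6), 10, 3)
  tr <- toy_bundle(co, elements = c("O", "H", "O", "H", "N", "H",
                                    "O", "O", "C", "C"))
  donors <- tibble::tibble(d_idx = c(1L, 3L, 5L), h_idx = c(2L, 4L, 6L))
  acceptors <- c(7L, 8L)
  got <- count_hbonds(tr, donors, acceptors, d_cut = 3.5, angle_cut = 30)
  brute <- 0L
  for (i in 1:3) for (a in acceptors) {
    D <- co[donors$d_idx[i], ]; H <- co[donors$h_idx[i], ]; A <- co[a, ]
    if (sqrt(sum((D - A)^2)) > 3.5) next
    v1 <- D - H; v2 <- A - H
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    if (ang >= 150) brute <- brute + 1L
  }
  expect_equal(got$n_hbonds, brute)
})
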
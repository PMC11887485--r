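#' Per-frame analyte contact areas
#'
#' Computes, for every stored frame (or every `stride`-th frame) and every
#' analyte molecule, the buried-surface contact area against either the
#' bare nanotube (`target = "swcnt"`) or the whole DNA-wrapped conjugate
#' (`"conjugate"`, the union of nanotube and DNA atoms). A cheap
#' minimum-distance prefilter skips the SASA evaluation for frames where
#' the molecule is beyond occlusion range, so far-away frames cost almost
#' nothing.
#'
#' @param traj A [trajectory_bundle()].
#' @param target `"swcnt"` or `"conjugate"`.
#' @param stride Evaluate every `stride`-th frame (default 1; recorded in
#'   the output attributes so downstream percentages state their sampling).
#' @inheritParams sasa
#' @return Tibble of class `contact_series`: `frame`, `molecule`, `area`
#'   (Angstrom^2), with attributes `dt` (ns per evaluated step) and
#'   `target`.
#' @export
contact_series <- function(traj, target = c("conjugate", "swcnt"),
                           stride = 1, probe = 1.4, n_sphere_points = 128) {
  target <- match.arg(target)
  stopifnot(inherits(traj, "trajectory_bundle"))
  tgt_idx <- switch(target,
                    swcnt = traj$groups$swcnt,
                    conjugate = c(traj$groups$swcnt, traj$groups$dna$all))
  if (length(tgt_idx) == 0) abort(sprintf("group '%s' is empty", target))
  mols <- traj$groups$analytes
  if (length(mols) == 0) abort("no analyte molecules defined")
  frames <- seq(1, n_frames(traj), by = stride)
  radii <- traj$atoms$radius
  reach <- 2 * max(radii) + 2 * probe   # beyond this nothing is buried

  out <- purrr::map_dfr(frames, function(fr) {
    tgt_xyz <- frame_coords(traj, fr, tgt_idx)
    purrr::map_dfr(seq_along(mols), function(m) {
      mi <- mols[[m]]$atoms
      mol_xyz <- frame_coords(traj, fr, mi)
      area <- if (min(proxy_min_dist(mol_xyz, tgt_xyz)) > reach) 0 else {
        contact_area(mol_xyz, radii[mi], tgt_xyz, radii[tgt_idx],
                     probe = probe, n_sphere_points = n_sphere_points)
      }
      tibble(frame = fr, molecule = m, area = area)
    })
  })
  structure(out, class = c("contact_series", class(out)),
            dt = traj$dt * stride, target = target)
}

# build a contact_series tibble from raw columns (used by the simulator)
as_contact_series <- function(frame, molecule, area, dt, target = "conjugate") {
  structure(tibble(frame = frame, molecule = molecule, area = area),
            class = c("contact_series", "tbl_df", "tbl", "data.frame"),
            dt = dt, target = target)
}

#' Percentage of time bound
#'
#' Fraction of frames (as a percentage) in which a molecule's contact area
#' with the target exceeds the threshold - the criterion for "in the
#' proximity of the conjugate" is a contact area greater than 1 Angstrom^2.
#'
#' @param series A [contact_series()] result (or any data frame with
#'   `frame`, `molecule`, `area`).
#' @param threshold Contact-area threshold in Angstrom^2 (default 1).
#' @return Tibble with one row per molecule (`molecule`, `n_frames`,
#'   `n_bound`, `pct_bound`) plus attribute `"pooled"`, the percentage
#'   over all molecule-frames.
#' @export
bound_fraction <- function(series, threshold = 1) {
  check_columns(series, c("frame", "molecule", "area"), "series")
  if (nrow(series) == 0) abort("empty contact series")
  out <- series %>%
    group_by(.data$molecule) %>%
    summarise(n_frames = dplyr::n(),
              n_bound = sum(.data$area > threshold),
              pct_bound = 100 * .data$n_bound / .data$n_frames,
              .groups = "drop")
  attr(out, "pooled") <- 100 * sum(out$n_bound) / sum(out$n_frames)
  out
}

#' Segment a contact series into binding events
#'
#' A binding event is a maximal run of consecutive frames in which the
#' contact area with the target exceeds `area_threshold` (30 Angstrom^2)
#' and - for molecules carrying amine/ammonium groups - the amine-group
#' distance to the nanotube surface stays below `amine_cutoff` (10.5
#' Angstrom). Predicates are applied strictly frame-wise: a single failing
#' frame ends an event, unless `gap_tolerance` > 0 allows short interior
#' dropouts to be bridged.
#'
#' @param series A [contact_series()] result.
#' @param amine_distance Optional data frame `frame`, `molecule`,
#'   `distance` (Angstrom), aligned with `series`; rows of `series` with
#'   no matching distance row are an error for molecules that have the
#'   constraint. Molecules absent from `amine_distance` are treated as
#'   amine-free (area criterion only).
#' @param area_threshold Contact-area threshold, Angstrom^2 (default 30).
#' @param amine_cutoff Amine-surface distance cutoff, Angstrom (10.5).
#' @param dt Time per frame step in ns; defaults to the series attribute.
#' @param gap_tolerance Bridge interior unbound runs of up to this many
#'   frames (default 0, strict).
#' @return Tibble of binding events: `molecule`, `start_frame`,
#'   `end_frame` (inclusive), `n_frames`, `duration` (ns).
#' @export
segment_binding_events <- function(series, amine_distance = NULL,
                                   area_threshold = 30, amine_cutoff = 10.5,
                                   dt = attr(series, "dt"),
                                   gap_tolerance = 0) {
  check_columns(series, c("frame", "molecule", "area"), "series")
  if (is.null(dt)) abort("dt not supplied and not carried by the series")
  work <- as_tibble(series)
  if (!is.null(amine_distance)) {
    check_columns(amine_distance, c("frame", "molecule", "distance"),
                  "amine_distance")
    constrained <- unique(amine_distance$molecule)
    work <- left_join(work, as_tibble(amine_distance),
                      by = c("frame", "molecule"))
    bad <- work$molecule %in% constrained & is.na(work$distance)
    if (any(bad)) {
      abort("amine_distance is misaligned with the contact series")
    }
  } else {
    work$distance <- NA_real_
  }
  work$bound <- work$area > area_threshold &
    (is.na(work$distance) | work$distance < amine_cutoff)

  work %>%
    group_by(.data$molecule) %>%
    arrange(.data$frame, .by_group = TRUE) %>%
    dplyr::group_modify(function(df, key) {
      b <- df$bound
      if (gap_tolerance > 0) {
        r <- rle(b)
        interior <- !r$values & r$lengths <= gap_tolerance &
          seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
        r$values[interior] <- TRUE
        b <- inverse.rle(r)
      }
      r <- rle(b)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- r$values
      tibble(start_frame = df$frame[starts[keep]],
             end_frame = df$frame[ends[keep]],
             n_frames = r$lengths[keep],
             duration = r$lengths[keep] * dt)
    }) %>%
    ungroup()
}

#' Residence time from binding events
#'
#' The residence time \eqn{\tau_R} is the inverse of the dissociation rate
#' \eqn{k_{off}}, estimated as the mean binding-event duration pooled over
#' all molecules of an analyte:
#' \deqn{\tau_R = \frac{\sum_i t_i n_i}{\sum_j n_j},}
#' where \eqn{n_i} events have duration \eqn{t_i} - algebraically the
#' total bound time divided by the number of events.
#'
#' @param events Event table from [segment_binding_events()], or a
#'   numeric vector of event durations (ns).
#' @return Object of class `residence_time`: `tau_R` (ns), `n_events`,
#'   `durations`. [glance()] gives a one-row tibble.
#' @export
residence_time <- function(events) {
  durations <- if (is.data.frame(events)) {
    check_columns(events, "duration", "events")
    events$duration
  } else as.numeric(events)
  if (length(durations) == 0) {
    abort("no binding events: the molecule never bound under the criteria")
  }
  structure(list(tau_R = mean(durations), n_events = length(durations),
                 durations = durations),
            class = "residence_time")
}

#' @export
glance.residence_time <- function(x, ...) {
  tibble(tau_R = x$tau_R, n_events = x$n_events,
         total_bound = sum(x$durations))
}

#' @export
print.residence_time <- function(x, ...) {
  cat(sprintf("Residence time tau_R = %.3g ns over %d events\n",
              x$tau_R, x$n_events))
  invisible(x)
}

#' Aryl stacking distance
#'
#' Mean surface distance of the aryl-ring center of mass, conditioned on
#' stacking frames (surface distance below `cutoff`, default 10 Angstrom),
#' per molecule and averaged over molecules. Molecules with no qualifying
#' frame are reported as `NA` (undefined, distinct from zero).
#'
#' @param traj A [trajectory_bundle()].
#' @param cylinder Nanotube [fit_cylinder()] model.
#' @param cutoff Qualifying-frame distance cutoff in Angstrom.
#' @return Tibble per molecule (`molecule`, `n_qualifying`,
#'   `mean_distance`) with attribute `"overall"`, the mean of the
#'   per-molecule means over molecules that qualified.
#' @export
stacking_distance <- function(traj, cylinder, cutoff = 10) {
  stopifnot(inherits(traj, "trajectory_bundle"))
  mols <- traj$groups$analytes
  per <- purrr::map_dfr(seq_along(mols), function(m) {
    aryl <- mols[[m]]$aryl_ring
    if (is.null(aryl) || length(aryl) == 0) {
      abort(sprintf("molecule %d has no aryl_ring group", m))
    }
    d <- vapply(seq_len(n_frames(traj)), function(fr) {
      surface_distance(group_com(traj, fr, aryl), cylinder)
    }, numeric(1))
    q <- d[d < cutoff]
    tibble(molecule = m, n_qualifying = length(q),
           mean_distance = if (length(q)) mean(q) else NA_real_)
  })
  ok <- !is.na(per$mean_distance)
  attr(per, "overall") <- if (any(ok)) mean(per$mean_distance[ok]) else NA_real_
  per
}

#' Polar-group distance distribution
#'
#' Normalized histogram of the surface distance of a polar group's center
#' of mass, pooled over all analyte molecules, restricted to frames where
#' the distance is within `r_max` (10 Angstrom, closed upper bound). The
#' density integrates to 1 over \[0, r_max\] whenever any frame qualifies.
#'
#' @param traj A [trajectory_bundle()].
#' @param polar_class Polar group class to pool (`"hydroxy"`, `"amine"`,
#'   `"ammonium"`, `"alkoxide"`) or a specific group name.
#' @param cylinder Nanotube cylinder model.
#' @param r_max Upper distance bound in Angstrom (default 10).
#' @param bin_width Histogram bin width in Angstrom (default 0.1).
#' @param group_index Within class, which group per molecule (default all
#'   pooled into one distribution; see [polar_auc()] for per-group sums).
#' @return Object of class `distance_distribution`: tibble `bin_left`,
#'   `bin_mid`, `bin_right`, `density` (per Angstrom) with attributes
#'   `n_samples`, `r_max`, `bin_width`. Zero qualifying samples give an
#'   all-zero density flagged by `n_samples = 0` (with a warning).
#' @export
polar_distance_distribution <- function(traj, polar_class, cylinder,
                                        r_max = 10, bin_width = 0.1,
                                        group_index = NULL) {
  samples <- polar_surface_distances(traj, polar_class, cylinder,
                                     group_index)
  distance_distribution(samples[samples >= 0 & samples <= r_max],
                        r_max = r_max, bin_width = bin_width)
}

# surface distances of polar-group COMs over all frames and molecules
polar_surface_distances <- function(traj, polar_class, cylinder,
                                    group_index = NULL) {
  mols <- traj$groups$analytes
  samples <- numeric(0)
  for (m in seq_along(mols)) {
    pgs <- mols[[m]]$polar_groups
    sel <- which(vapply(pgs, function(g) {
      g$class == polar_class || g$name == polar_class
    }, logical(1)))
    if (!is.null(group_index)) sel <- intersect(sel, group_index)
    for (gi in sel) {
      idx <- pgs[[gi]]$indices
      d <- vapply(seq_len(n_frames(traj)), function(fr) {
        surface_distance(group_com(traj, fr, idx), cylinder)
      }, numeric(1))
      samples <- c(samples, d)
    }
  }
  samples
}

#' Normalized distance distribution from samples
#'
#' Histogram of distance samples on \[0, r_max\] as a probability density
#' (per Angstrom): bins are left-closed with the last bin closed on both
#' ends, so samples at exactly `r_max` are kept. The density integrates
#' to 1 whenever there is at least one sample.
#'
#' @param samples Numeric distance samples in Angstrom (values outside
#'   \[0, r_max\] should be filtered by the caller).
#' @param r_max Upper bound of the support (default 10).
#' @param bin_width Bin width (default 0.1).
#' @return A `distance_distribution` object; see
#'   [polar_distance_distribution()].
#' @export
distance_distribution <- function(samples, r_max = 10, bin_width = 0.1) {
  edges <- seq(0, r_max, by = bin_width)
  if (abs(edges[length(edges)] - r_max) > 1e-12) edges <- c(edges, r_max)
  n <- length(samples)
  if (n == 0) {
    warning("no samples within range: empty distance distribution")
    counts <- rep(0L, length(edges) - 1)
  } else {
    # [a, b) bins, with the last bin closed so samples at r_max are kept
    counts <- graphics::hist(samples, breaks = edges, plot = FALSE,
                             include.lowest = TRUE, right = FALSE)$counts
  }
  widths <- diff(edges)
  density <- if (n == 0) rep(0, length(counts)) else
    counts / (n * widths)
  structure(
    tibble(bin_left = utils::head(edges, -1),
           bin_right = utils::tail(edges, -1),
           bin_mid = (utils::head(edges, -1) + utils::tail(edges, -1)) / 2,
           density = density),
    class = c("distance_distribution", "tbl_df", "tbl", "data.frame"),
    n_samples = n, r_max = r_max, bin_width = bin_width)
}

#' Area under a distance distribution below a cutoff
#'
#' Integral of the normalized distance density over \[0, x\]; the 4
#' Angstrom AUC is the headline proximity statistic for polar groups.
#' Monotone nondecreasing in `x`; equals 1 at `x = r_max`.
#'
#' @param dist A `distance_distribution`.
#' @param x Upper integration bound in Angstrom (default 4), within
#'   \[0, r_max\].
#' @return Cumulative probability in \[0, 1\].
#' @export
auc_below <- function(dist, x = 4) {
  stopifnot(inherits(dist, "distance_distribution"))
  r_max <- attr(dist, "r_max")
  if (x < 0 || x > r_max) {
    abort(sprintf("x = %g is outside [0, %g]", x, r_max))
  }
  full <- dist$bin_right <= x
  partial <- dist$bin_left < x & dist$bin_right > x
  sum(dist$density[full] * (dist$bin_right[full] - dist$bin_left[full])) +
    sum(dist$density[partial] * (x - dist$bin_left[partial]))
}

#' Class-summed polar-group AUC
#'
#' Computes, for one class of polar groups (e.g. hydroxy), the per-group
#' 4 Angstrom AUCs and returns their sum: when a molecule carries several
#' groups of a class, the reported AUC is the sum over groups.
#'
#' @inheritParams polar_distance_distribution
#' @param x AUC cutoff in Angstrom (default 4).
#' @return Tibble: `group`, `auc`, plus attribute `"class_sum"`.
#' @export
polar_auc <- function(traj, polar_class, cylinder, x = 4,
                      r_max = 10, bin_width = 0.1) {
  pgs <- traj$groups$analytes[[1]]$polar_groups
  sel <- which(vapply(pgs, function(g) g$class == polar_class, logical(1)))
  if (length(sel) == 0) {
    abort(sprintf("no polar groups of class '%s'", polar_class))
  }
  out <- purrr::map_dfr(sel, function(gi) {
    d <- polar_distance_distribution(traj, pgs[[gi]]$name, cylinder,
                                     r_max = r_max, bin_width = bin_width)
    tibble(group = pgs[[gi]]$name, auc = auc_below(d, x))
  })
  attr(out, "class_sum") <- sum(out$auc)
  out
}

#' Radial distribution function
#'
#' Pair-distance distribution g(r) between two atom sets under the
#' minimum-image convention, normalized by the ideal-gas expectation at
#' the B-set box density: \eqn{g(r) = n(r) / (N_A N_B \, 4\pi r^2 \Delta r
#' / V)} averaged over frames, so uncorrelated uniform points give
#' g(r) = 1.
#'
#' @param traj A [trajectory_bundle()].
#' @param atoms_a,atoms_b Integer index vectors of the two sets.
#' @param r_max Maximum distance; must be below half the smallest box
#'   length.
#' @param bin_width Bin width in Angstrom (default 0.1).
#' @return Tibble: `r` (bin centers), `g`.
#' @export
radial_distribution <- function(traj, atoms_a, atoms_b, r_max,
                                bin_width = 0.1) {
  stopifnot(inherits(traj, "trajectory_bundle"))
  if (length(atoms_a) == 0 || length(atoms_b) == 0) {
    abort("both atom sets must be nonempty")
  }
  box <- traj$box
  if (r_max >= min(box) / 2) {
    abort(sprintf("r_max = %g must be < half the smallest box length (%g)",
                  r_max, min(box) / 2))
  }
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  counts <- rep(0, length(edges) - 1)
  nf <- n_frames(traj)
  shared <- intersect(atoms_a, atoms_b)
  n_pairs_tot <- length(atoms_a) * length(atoms_b) - length(shared)
  for (fr in seq_len(nf)) {
    a <- frame_coords(traj, fr, atoms_a)
    b <- frame_coords(traj, fr, atoms_b)
    d <- min_image_dist(a, b, box)
    if (length(shared)) {
      ia <- match(shared, atoms_a); ib <- match(shared, atoms_b)
      d[cbind(ia, ib)] <- NA
    }
    d <- d[!is.na(d) & d < r_max]
    counts <- counts + graphics::hist(d, breaks = edges,
                                      plot = FALSE)$counts
  }
  vol <- prod(box)
  shell <- 4 / 3 * pi * (utils::tail(edges, -1)^3 - utils::head(edges, -1)^3)
  expected <- nf * n_pairs_tot * shell / vol
  tibble(r = (utils::head(edges, -1) + utils::tail(edges, -1)) / 2,
         g = ifelse(expected > 0, counts / expected, 0))
}

# minimum-image distances between coordinate sets in an orthorhombic box
min_image_dist <- function(a, b, box) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

#' Geometric hydrogen-bond counts per frame
#'
#' Counts donor-acceptor pairs satisfying the geometric criterion:
#' donor-acceptor distance at or below `d_cut` and D-H...A angle at least
#' `180 - angle_cut` degrees (i.e. within `angle_cut` of linear).
#'
#' @param traj A [trajectory_bundle()].
#' @param donors Data frame with integer columns `d_idx` (heavy donor
#'   atom) and `h_idx` (its hydrogen).
#' @param acceptors Integer vector of acceptor atom indices.
#' @param d_cut Donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_cut Allowed deviation from linearity, degrees (default 30).
#' @return Tibble: `frame`, `n_hbonds`.
#' @export
count_hbonds <- function(traj, donors, acceptors, d_cut = 3.5,
                         angle_cut = 30) {
  check_columns(donors, c("d_idx", "h_idx"), "donors")
  if (any(is.na(donors$h_idx))) {
    abort("donor hydrogens missing: every donor needs an h_idx")
  }
  if (length(acceptors) == 0) abort("no acceptor atoms given")
  min_angle <- 180 - angle_cut
  purrr::map_dfr(seq_len(n_frames(traj)), function(fr) {
    xyz <- frame_coords(traj, fr)
    cnt <- 0L
    for (i in seq_len(nrow(donors))) {
      D <- xyz[donors$d_idx[i], ]
      H <- xyz[donors$h_idx[i], ]
      for (a in acceptors) {
        if (a == donors$d_idx[i]) next
        A <- xyz[a, ]
        if (sqrt(sum((D - A)^2)) > d_cut) next
        v1 <- D - H; v2 <- A - H
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(max(-1, min(1, cosang))) * 180 / pi
        if (ang >= min_angle) cnt <- cnt + 1L
      }
    }
    tibble(frame = fr, n_hbonds = cnt)
  })
}

#' Assign a predominant binding mode per molecule
#'
#' Operationalizes the visual binding-mode taxonomy. Each bound frame
#' (contact with nanotube or DNA above `area_threshold`) is labeled:
#' `stack_swcnt` when the aryl ring sits within `stack_cutoff` of the
#' nanotube surface and nanotube contact dominates; `stack_dna` when DNA
#' contact dominates with the aryl ring beyond the stacking cutoff;
#' `insertion` when the aryl ring is at the surface under a dominant DNA
#' contact while an ammonium group projects out past the DNA shell. The
#' molecule's mode is the state occupying more than `occupancy` of its
#' bound frames; an even split between the two stacking states is
#' `"both"`, any other split is `"mixed"`, and a molecule that never binds
#' is `"unbound"`.
#'
#' @param traj A [trajectory_bundle()].
#' @param cylinder Nanotube cylinder model.
#' @param series_swcnt,series_dna Contact series against the bare
#'   nanotube and the DNA strands respectively (computed if omitted,
#'   `series_dna` from DNA atoms only).
#' @param area_threshold Bound-frame contact threshold, Angstrom^2 (30).
#' @param stack_cutoff Aryl-surface stacking cutoff, Angstrom (5).
#' @param dna_shell Surface distance of the DNA shell, Angstrom (7);
#'   an ammonium beyond it marks insertion geometry.
#' @param occupancy Predominance fraction of bound frames (0.5).
#' @return Tibble: `molecule`, `mode`, `n_bound_frames`, and the bound
#'   occupancy of each frame state.
#' @export
classify_binding_mode <- function(traj, cylinder,
                                  series_swcnt = NULL, series_dna = NULL,
                                  area_threshold = 30, stack_cutoff = 5,
                                  dna_shell = 7, occupancy = 0.5) {
  stopifnot(inherits(traj, "trajectory_bundle"))
  if (is.null(series_swcnt)) {
    series_swcnt <- contact_series(traj, "swcnt")
  }
  if (is.null(series_dna)) series_dna <- dna_contact_series(traj)
  mols <- traj$groups$analytes

  purrr::map_dfr(seq_along(mols), function(m) {
    sw <- series_swcnt[series_swcnt$molecule == m, ]
    dn <- series_dna[series_dna$molecule == m, ]
    if (nrow(sw) == 0 || nrow(dn) == 0 || !all(sw$frame == dn$frame)) {
      abort("contact series for SWCNT and DNA are misaligned")
    }
    aryl <- mols[[m]]$aryl_ring
    ammonium <- purrr::keep(mols[[m]]$polar_groups,
                            function(g) g$class == "ammonium")
    frames <- sw$frame
    aryl_d <- vapply(frames, function(fr) {
      surface_distance(group_com(traj, fr, aryl), cylinder)
    }, numeric(1))
    amm_d <- if (length(ammonium)) {
      vapply(frames, function(fr) {
        surface_distance(group_com(traj, fr, ammonium[[1]]$indices),
                         cylinder)
      }, numeric(1))
    } else rep(NA_real_, length(frames))

    bound <- sw$area > area_threshold | dn$area > area_threshold
    state <- rep(NA_character_, length(frames))
    ins <- dn$area > area_threshold & aryl_d < stack_cutoff &
      !is.na(amm_d) & amm_d > dna_shell
    state[ins] <- "insertion"
    sw_dom <- sw$area >= dn$area
    state[is.na(state) & bound & sw_dom &
            aryl_d < stack_cutoff] <- "stack_swcnt"
    state[is.na(state) & bound & !sw_dom &
            aryl_d >= stack_cutoff] <- "stack_dna"
    state[bound & is.na(state)] <- "other"

    nb <- sum(bound)
    if (nb == 0) {
      return(tibble(molecule = m, mode = "unbound", n_bound_frames = 0L,
                    f_stack_swcnt = 0, f_stack_dna = 0, f_insertion = 0))
    }
    f <- c(stack_swcnt = sum(state == "stack_swcnt", na.rm = TRUE),
           stack_dna = sum(state == "stack_dna", na.rm = TRUE),
           insertion = sum(state == "insertion", na.rm = TRUE)) / nb
    mode <- if (max(f) > occupancy) names(f)[which.max(f)] else if (
      f["stack_swcnt"] + f["stack_dna"] > occupancy &&
        min(f["stack_swcnt"], f["stack_dna"]) > 0.2) "both" else "mixed"
    tibble(molecule = m, mode = mode, n_bound_frames = nb,
           f_stack_swcnt = unname(f["stack_swcnt"]),
           f_stack_dna = unname(f["stack_dna"]),
           f_insertion = unname(f["insertion"]))
  })
}

# contact series of each molecule against the DNA strands alone
dna_contact_series <- function(traj, probe = 1.4, n_sphere_points = 128) {
  idx <- traj$groups$dna$all
  radii <- traj$atoms$radius
  mols <- traj$groups$analytes
  reach <- 2 * max(radii) + 2 * probe
  out <- purrr::map_dfr(seq_len(n_frames(traj)), function(fr) {
    tgt <- frame_coords(traj, fr, idx)
    purrr::map_dfr(seq_along(mols), function(m) {
      mi <- mols[[m]]$atoms
      mol_xyz <- frame_coords(traj, fr, mi)
      area <- if (min(proxy_min_dist(mol_xyz, tgt)) > reach) 0 else {
        contact_area(mol_xyz, radii[mi], tgt, radii[idx],
                     probe = probe, n_sphere_points = n_sphere_points)
      }
      tibble(frame = fr, molecule = m, area = area)
    })
  })
  structure(out, class = c("contact_series", class(out)),
            dt = traj$dt, target = "dna")
}
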
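#' Build a synthetic sensor world
#'
#' Deterministic pseudo-topology of the simulated sensor: carbon atoms on
#' a cylindrical lattice at the chirality radius
#' \eqn{a\sqrt{n^2+nm+m^2}/(2\pi)} (a 4 nm (9,4) segment by default),
#' three helical (GT)6-like pseudo-DNA strands with labeled backbone
#' beads (P, O1P, O2P, O3', O4', O5'), and six copies of an analyte
#' template with tagged aryl-ring and polar-group pseudo-atoms. The world
#' is a kinematic stand-in whose purpose is estimator validation, not
#' physical realism.
#'
#' @param chirality Integer pair `(n, m)`; default `c(9, 4)`.
#' @param length Tube length in Angstrom (default 40).
#' @param n_molecules Number of analyte molecules (default 6).
#' @param n_dna_strands Number of wrapped strands (default 3).
#' @param analyte Analyte template from [analyte_template()].
#' @param seed Integer seed for the small placement jitter.
#' @return List of class `synthetic_world`: `atoms`, `groups`, `box`,
#'   `radius`, `length`, `dna_shell_radius`, `template`, `init_coords`.
#' @export
build_world <- function(chirality = c(9, 4), length = 40, n_molecules = 6,
                        n_dna_strands = 3,
                        analyte = analyte_template(), seed = 1) {
  r <- swcnt_radius(chirality[1], chirality[2])
  set.seed(as.integer(seed))

  # nanotube pseudo-lattice: rings of carbons, alternate rings offset
  dz <- 1.23
  zs <- seq(-length / 2, length / 2, by = dz)
  n_ring <- max(12L, round(2 * pi * r / 1.42))
  sw <- purrr::map_dfr(seq_along(zs), function(i) {
    th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring +
      (i %% 2) * pi / n_ring
    tibble(x = r * cos(th), y = r * sin(th), z = zs[i], element = "C",
           name = "C", tag = "swcnt")
  })

  # helical DNA strands over the central part of the segment (the corona
  # does not blanket the tube; exposed surface remains near the ends)
  r_dna <- r + 3.3
  nt_per_strand <- 12                      # (GT)6
  turns <- 1.5
  helix <- list(z0 = -0.3 * length, z1 = 0.3 * length, turns = turns)
  bb_names <- c("P", "O1P", "O2P", "O3'", "O4'", "O5'")
  dna <- purrr::map_dfr(seq_len(n_dna_strands), function(s) {
    phase <- 2 * pi * (s - 1) / n_dna_strands
    tpos <- seq(0, 1, length.out = nt_per_strand)
    purrr::map_dfr(seq_len(nt_per_strand), function(k) {
      th <- phase + 2 * pi * turns * tpos[k]
      z <- helix$z0 + tpos[k] * (helix$z1 - helix$z0)
      # small deterministic scatter of beads around the backbone point
      off <- matrix(rnorm(3 * 7, sd = 0.6), ncol = 3)
      base <- c(r_dna * cos(th), r_dna * sin(th), z)
      tibble(x = base[1] + off[, 1], y = base[2] + off[, 2],
             z = base[3] + off[, 3],
             element = c("P", "O", "O", "O", "O", "O", "C"),
             name = c(bb_names, "BASE"), tag = "dna")
    })
  })

  # analyte copies: placed far from the tube; the simulator moves them
  mol <- purrr::map_dfr(seq_len(n_molecules), function(m) {
    mutate(analyte$atoms,
           x = .data$x + 0, y = .data$y + r + 18 + 4 * m, z = .data$z,
           tag = paste0("analyte", m))
  })

  atoms_xyz <- bind_rows(sw, dna, mol)
  atoms <- tibble(atom_id = seq_len(nrow(atoms_xyz)),
                  element = atoms_xyz$element, name = atoms_xyz$name)
  atoms$radius <- vdw_radius(atoms$element)

  idx_sw <- which(atoms_xyz$tag == "swcnt")
  idx_dna <- which(atoms_xyz$tag == "dna")
  dna_group <- c(list(all = idx_dna),
                 setNames(lapply(bb_names, function(nm) {
                   idx_dna[atoms_xyz$name[idx_dna] == nm]
                 }), bb_names))
  n_at <- nrow(analyte$atoms)
  analytes <- lapply(seq_len(n_molecules), function(m) {
    base <- which(atoms_xyz$tag == paste0("analyte", m))[1] - 1
    list(atoms = base + seq_len(n_at),
         aryl_ring = base + analyte$aryl_ring,
         polar_groups = lapply(analyte$polar_groups, function(g) {
           list(name = g$name, indices = base + g$indices,
                class = g$class)
         }))
  })

  box <- rep(max(64, 2 * (r + 26)), 3)
  structure(list(
    atoms = atoms,
    groups = list(swcnt = idx_sw, dna = dna_group, analytes = analytes),
    box = box, radius = r, length = length, dna_shell_radius = r_dna,
    dna_helix = helix,
    template = analyte,
    init_coords = as.matrix(atoms_xyz[, c("x", "y", "z")])),
    class = "synthetic_world")
}

#' Analyte pseudo-molecule template
#'
#' Rigid pseudo-atom template in its local frame (aryl ring in the
#' xy-plane, polar tail along -y): six ring carbons, optional vicinal
#' (ortho) hydroxy oxygens, and an optional ammonium nitrogen on a short
#' tail. The defaults sketch a catecholamine (dopamine-like) analyte.
#'
#' @param name Template name.
#' @param n_hydroxy Number of ring hydroxy groups (0-2, vicinal).
#' @param has_ammonium Attach an ammonium tail nitrogen.
#' @return List with `atoms` (tibble `x`, `y`, `z`, `element`, `name`),
#'   `aryl_ring` indices, and `polar_groups`.
#' @export
analyte_template <- function(name = "catecholamine", n_hydroxy = 2,
                             has_ammonium = TRUE) {
  th <- 2 * pi * (0:5) / 6 + pi / 2
  ring <- tibble(x = 1.39 * cos(th), y = 1.39 * sin(th), z = 0,
                 element = "C", name = paste0("CR", 1:6))
  atoms <- ring
  polar <- list()
  if (n_hydroxy > 0) {
    # hydroxys extend outward from adjacent (ortho) ring carbons
    oh_th <- th[1:n_hydroxy]
    oh <- tibble(x = 2.75 * cos(oh_th), y = 2.75 * sin(oh_th), z = 0,
                 element = "O", name = paste0("OH", seq_len(n_hydroxy)))
    atoms <- bind_rows(atoms, oh)
    polar <- c(polar, lapply(seq_len(n_hydroxy), function(i) {
      list(name = paste0("OH", i), indices = 6L + i, class = "hydroxy")
    }))
  }
  if (has_ammonium) {
    n_idx <- nrow(atoms) + 1L
    atoms <- bind_rows(atoms, tibble(x = 0, y = -3.9, z = 0,
                                     element = "N", name = "NZ"))
    polar <- c(polar, list(list(name = "NZ", indices = n_idx,
                                class = "ammonium")))
  }
  list(name = name, atoms = atoms, aryl_ring = 1:6, polar_groups = polar)
}

#' Kinetic parameters for the binding simulator
#'
#' @param rates Square matrix of per-ns transition rates between states
#'   (rows = from); state names in dimnames. Diagonal ignored.
#' @param dt Time per stored frame in ns.
#' @param n_frames Number of frames to simulate.
#' @param seed Integer seed.
#' @return List of class `kinetic_params`.
#' @export
kinetic_params <- function(rates, dt, n_frames, seed = 1) {
  if (!is.matrix(rates) || nrow(rates) != ncol(rates)) {
    abort("rates must be a square matrix")
  }
  if (any(rates < 0)) abort("rates must be nonnegative")
  diag(rates) <- 0
  exit <- rowSums(rates)
  if (dt * max(exit) > 0.1) {
    abort(sprintf(
      "dt = %g ns too coarse for the fastest exit rate %g /ns (dt*rate must be <= 0.1)",
      dt, max(exit)))
  }
  structure(list(rates = rates, dt = dt, n_frames = as.integer(n_frames),
                 seed = as.integer(seed),
                 states = rownames(rates) %||% paste0("S", seq_len(nrow(rates)))),
            class = "kinetic_params")
}

#' Two-state binding kinetics
#'
#' Convenience wrapper for free <-> stack_swcnt kinetics.
#'
#' @param k_on,k_off Binding / unbinding rates in 1/ns.
#' @inheritParams kinetic_params
#' @export
two_state_kinetics <- function(k_on, k_off, dt, n_frames, seed = 1) {
  rates <- matrix(c(0, k_on, k_off, 0), 2, 2, byrow = TRUE,
                  dimnames = list(c("free", "stack_swcnt"),
                                  c("free", "stack_swcnt")))
  kinetic_params(rates, dt, n_frames, seed)
}

# sample one discrete-time Markov state path
markov_path <- function(rates, dt, n_frames, init = 1) {
  k <- nrow(rates)
  p <- rates * dt
  stay <- 1 - rowSums(p)
  tm <- p
  diag(tm) <- diag(tm) + stay
  states <- integer(n_frames)
  s <- init
  for (i in seq_len(n_frames)) {
    s <- sample.int(k, 1, prob = tm[s, ])
    states[i] <- s
  }
  states
}

#' Simulate a binding trajectory
#'
#' Drives each analyte molecule by an independent discrete-time embedding
#' of the continuous-time Markov chain in `kinetics` and emits coordinates
#' conditional on the state: bound states place the aryl-ring center of
#' mass at a nanotube surface offset of N(3.4, 0.2) Angstrom
#' (`stack_swcnt`, aryl plane tangent to the surface, between DNA
#' strands), N(6.5, 0.3) over a DNA strand (`stack_dna`), or at the
#' surface under a strand with the ammonium tail tilted radially outward
#' past the DNA shell (`inserted`); the free state scatters molecules
#' uniformly in the box shell at least 12 Angstrom from the surface.
#' Within one bound run the angular/axial anchor is held with small
#' jitter, so bound geometry is frame-coherent.
#'
#' @param world A [build_world()] result.
#' @param kinetics A [kinetic_params()] (state names must be among
#'   free, stack_swcnt, stack_dna, inserted; `free` required).
#' @param stack_offset_mean,stack_offset_sd Surface offset of the aryl
#'   ring in stacked/inserted states (Angstrom).
#' @param state_paths Optional list of per-molecule character vectors
#'   (length `n_frames`) overriding the Markov chain with constructed
#'   state sequences.
#' @return List: `traj` (a [trajectory_bundle()]), `truth` (list with
#'   `states` tibble frame x molecule, `params`, per-state
#'   `stationary` occupancies of the chain).
#' @export
simulate_trajectory <- function(world, kinetics,
                                stack_offset_mean = 3.4,
                                stack_offset_sd = 0.2,
                                state_paths = NULL) {
  stopifnot(inherits(world, "synthetic_world"),
            inherits(kinetics, "kinetic_params"))
  st_names <- kinetics$states
  if (!"free" %in% st_names) abort("kinetics must include a 'free' state")
  set.seed(kinetics$seed)
  nf <- kinetics$n_frames
  mols <- world$groups$analytes
  nm <- length(mols)
  r <- world$radius
  half_len <- world$length / 2
  tmpl <- as.matrix(world$template$atoms[, c("x", "y", "z")])
  tmpl <- sweep(tmpl, 2, colMeans(tmpl[world$template$aryl_ring, , drop = FALSE]))
  helix <- world$dna_helix
  strand_phase <- 2 * pi * (seq_len(3) - 1) / 3

  coords <- array(0, c(nf, nrow(world$atoms), 3))
  # static scaffold
  static_idx <- c(world$groups$swcnt, world$groups$dna$all)
  for (fr in seq_len(nf)) {
    coords[fr, static_idx, ] <- world$init_coords[static_idx, ]
  }

  # orientation: rotate template local frame (ex, ey, ez) to world
  place <- function(theta, z, offset, tail_out) {
    radial <- c(cos(theta), sin(theta), 0)
    axial <- c(0, 0, 1)
    tangent <- c(-sin(theta), cos(theta), 0)
    if (tail_out) {
      # tail (-y local) points radially outward; plane contains axis
      ey <- -radial; ez <- tangent; ex <- axial
    } else {
      # aryl plane tangent: normal (local z) radial, tail along axis
      ez <- radial; ex <- tangent; ey <- axial
    }
    rot <- cbind(ex, ey, ez)
    ctr <- (r + offset) * radial + c(0, 0, z)
    sweep(tmpl %*% t(rot), 2, ctr, "+")
  }

  strand_theta <- function(z, s) {
    strand_phase[s] + 2 * pi * helix$turns *
      (z - helix$z0) / (helix$z1 - helix$z0)
  }

  dna_xyz <- world$init_coords[world$groups$dna$all, , drop = FALSE]
  # anchor for SWCNT stacking: a surface patch clear of the DNA helices
  exposed_anchor <- function() {
    best <- NULL; best_d <- -Inf
    for (try in 1:60) {
      th <- runif(1, 0, 2 * pi)
      z <- runif(1, -half_len * 0.8, half_len * 0.8)
      p <- c((r + stack_offset_mean) * cos(th),
             (r + stack_offset_mean) * sin(th), z)
      d <- min(sqrt(colSums((t(dna_xyz) - p)^2)))
      if (d > best_d) { best_d <- d; best <- list(theta = th, z = z) }
      if (d > 7.5) break
    }
    best
  }

  truth_states <- matrix("", nf, nm)
  for (m in seq_len(nm)) {
    path <- if (!is.null(state_paths)) {
      match(state_paths[[m]], st_names)
    } else {
      markov_path(kinetics$rates, kinetics$dt, nf,
                  init = which(st_names == "free"))
    }
    if (any(is.na(path)) || length(path) != nf) {
      abort("state_paths must name known states for every frame")
    }
    truth_states[, m] <- st_names[path]
    anchor <- NULL
    for (fr in seq_len(nf)) {
      st <- st_names[path[fr]]
      new_run <- fr == 1 || path[fr] != path[fr - 1]
      if (st == "free") {
        rad <- runif(1, r + 12, world$box[1] / 2 - 3)
        th <- runif(1, 0, 2 * pi)
        z <- runif(1, -half_len, half_len)
        xyz <- place(th, z, rad - r, tail_out = FALSE)
      } else {
        if (new_run) {
          anchor <- if (st == "stack_swcnt") exposed_anchor() else {
            z0 <- runif(1, helix$z0 + 1, helix$z1 - 1)
            list(z = z0, strand = sample.int(3, 1), theta = NA)
          }
        }
        z <- anchor$z + rnorm(1, sd = 0.3)
        off <- rnorm(1, stack_offset_mean, stack_offset_sd)
        xyz <- switch(st,
          stack_swcnt = place(anchor$theta, z, off, tail_out = FALSE),
          stack_dna = place(strand_theta(z, anchor$strand), z,
                            rnorm(1, 6.5, 0.3), tail_out = FALSE),
          inserted = place(strand_theta(z, anchor$strand), z, off,
                           tail_out = TRUE),
          abort(sprintf("unknown state '%s'", st)))
      }
      coords[fr, mols[[m]]$atoms, ] <- xyz
    }
  }

  traj <- trajectory_bundle(world$atoms, world$groups, coords,
                            world$box, kinetics$dt)
  truth <- list(
    states = as_tibble(as.data.frame(truth_states)) %>%
      setNames(paste0("mol", seq_len(nm))) %>%
      mutate(frame = dplyr::row_number()) %>%
      tidyr::pivot_longer(-"frame", names_to = "molecule",
                          values_to = "state") %>%
      mutate(molecule = as.integer(sub("mol", "", .data$molecule))),
    params = kinetics,
    stationary = markov_stationary(kinetics$rates))
  list(traj = traj, truth = truth)
}

# stationary distribution of the continuous-time chain; isolated states
# (no in- or out-rates) get probability 0
markov_stationary <- function(rates) {
  nm <- rownames(rates) %||% paste0("S", seq_len(nrow(rates)))
  live <- rowSums(rates) > 0 | colSums(rates) > 0
  out <- setNames(rep(0, nrow(rates)), nm)
  q <- rates[live, live, drop = FALSE]
  diag(q) <- -rowSums(q)
  k <- nrow(q)
  a <- rbind(t(q), rep(1, k))
  pi_ <- qr.solve(a, c(rep(0, k), 1))
  out[live] <- pmax(pi_, 0) / sum(pmax(pi_, 0))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a contact-area series with known kinetics
#'
#' Emits a per-frame, per-molecule contact series directly from a
#' two-state Markov chain with per-frame transition probabilities `p_on`
#' and `p_off`, without generating coordinates: bound frames draw areas
#' from N(`bound_mean`, `bound_sd`) Angstrom^2, unbound frames sit near
#' zero. This idealized series (complete separation of the two area
#' populations) is the workhorse for validating the bound-fraction and
#' residence-time estimators at large frame counts, where per-frame SASA
#' evaluation would be gratuitous.
#'
#' Dwell times are geometric with mean `1/p_off` frames bound and
#' `1/p_on` frames free; the stationary bound occupancy is
#' `p_on/(p_on+p_off)`.
#'
#' @param p_on,p_off Per-frame binding / unbinding probabilities.
#' @param n_frames Frames per molecule.
#' @param n_molecules Number of independent molecules (default 6).
#' @param dt ns per frame (default 0.06, i.e. 1e5 frames = 6 us).
#' @param seed Integer seed.
#' @param bound_mean,bound_sd Bound-frame contact area distribution.
#' @return List: `series` (a contact series tibble), `truth` (tibble
#'   `frame`, `molecule`, `bound`).
#' @export
simulate_markov_contacts <- function(p_on, p_off, n_frames,
                                     n_molecules = 6, dt = 0.06, seed = 1,
                                     bound_mean = 60, bound_sd = 8) {
  if (p_on < 0 || p_on > 1 || p_off < 0 || p_off > 1) {
    abort("p_on and p_off must be probabilities in [0, 1]")
  }
  set.seed(as.integer(seed))
  out <- purrr::map(seq_len(n_molecules), function(m) {
    bound <- logical(n_frames)
    s <- FALSE
    u <- runif(n_frames)
    for (i in seq_len(n_frames)) {
      s <- if (s) u[i] >= p_off else u[i] < p_on
      bound[i] <- s
    }
    area <- ifelse(bound, rnorm(n_frames, bound_mean, bound_sd),
                   abs(rnorm(n_frames, 0, 0.1)))
    list(series = tibble(frame = seq_len(n_frames), molecule = m,
                         area = area),
         truth = tibble(frame = seq_len(n_frames), molecule = m,
                        bound = bound))
  })
  series <- bind_rows(purrr::map(out, "series"))
  list(series = as_contact_series(series$frame, series$molecule,
                                  series$area, dt = dt),
       truth = bind_rows(purrr::map(out, "truth")))
}

#' Generate a baseline / response spectrum pair
#'
#' Sum-of-Gaussians emission spectrum with a prescribed response: `F0` is
#' the peak sum plus noise; `F` is the same with the designated peaks
#' scaled by `1 + dff` plus independent noise. With all peaks scaled and
#' no noise, the integrated \eqn{\Delta F/F} is exactly `dff`.
#'
#' @param dff Prescribed relative response.
#' @param peaks Tibble `center`, `width`, `amplitude` (nm, nm, a.u.);
#'   default [default_peaks()].
#' @param scale_peaks Indices of peaks that respond (default all).
#' @param noise_sd Per-point Gaussian noise sd (default 0).
#' @param wavelength Wavelength grid in nm.
#' @param seed Optional integer seed for the noise.
#' @return List with spectra `F0` and `F`.
#' @export
generate_spectrum <- function(dff, peaks = default_peaks(),
                              scale_peaks = seq_len(nrow(peaks)),
                              noise_sd = 0,
                              wavelength = seq(950, 1350, by = 1),
                              seed = NULL) {
  check_columns(peaks, c("center", "width", "amplitude"), "peaks")
  if (any(peaks$amplitude < 0)) abort("peak amplitudes must be nonnegative")
  if (any(peaks$width <= 0)) abort("peak widths must be positive")
  if (any(peaks$center < min(wavelength) | peaks$center > max(wavelength))) {
    abort("peak centers must lie within the wavelength grid")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  gauss <- function(amp_scale) {
    rowSums(vapply(seq_len(nrow(peaks)), function(i) {
      amp_scale[i] * peaks$amplitude[i] *
        exp(-0.5 * ((wavelength - peaks$center[i]) / peaks$width[i])^2)
    }, numeric(length(wavelength))))
  }
  s0 <- rep(1, nrow(peaks))
  s1 <- s0
  s1[scale_peaks] <- 1 + dff
  f0 <- gauss(s0) + rnorm(length(wavelength), 0, noise_sd)
  f1 <- gauss(s1) + rnorm(length(wavelength), 0, noise_sd)
  list(F0 = emission_spectrum(wavelength, f0),
       F = emission_spectrum(wavelength, f1))
}

#' Default emission peaks and (9,4) window
#'
#' Two Gaussian chirality peaks; the first is the (9,4) emission the
#' screen is scored on (center 1128 nm by package convention - peak
#' positions are configurable, and analyses reference the window rather
#' than a hard-coded wavelength).
#'
#' @return `default_peaks()`: tibble of peak parameters.
#' @export
default_peaks <- function() {
  tibble(chirality = c("(9,4)", "(8,6)"),
         center = c(1128, 1195), width = c(16, 18),
         amplitude = c(1, 0.65))
}

#' @rdname default_peaks
#' @return `peak94_window()`: length-2 nm window around the (9,4) peak.
#' @export
peak94_window <- function() c(1096, 1160)

#' Generate a synthetic screening dataset
#'
#' Builds plate-reader data (long format) and a plate map for a compound
#' library with prescribed dopamine-normalized responses: per compound
#' `n_rep` replicate wells, reference (DA) wells and blank wells, each
#' with a baseline read at 0 min and a response read at `timepoint`.
#' A flat background is added to every well so blank subtraction is
#' exercised. With zero noise, [screen_plate()] recovers the prescribed
#' normalized values exactly.
#'
#' @param library Tibble `analyte_id`, `true_normalized`; must contain
#'   the reference `DA` with value 1.
#' @param n_rep Replicate wells per compound (default 3).
#' @param noise_sd Per-point spectral noise sd (default 0).
#' @param dff_reference True \eqn{\Delta F/F} of dopamine (default 0.25).
#' @param timepoint Response read time in min (default 30).
#' @param seed Integer seed.
#' @return List: `plate` (long tibble), `map`, `true_dff` lookup.
#' @export
generate_screen_dataset <- function(library, n_rep = 3, noise_sd = 0,
                                    dff_reference = 0.25, timepoint = 30,
                                    seed = 1) {
  check_columns(library, c("analyte_id", "true_normalized"), "library")
  da <- library$true_normalized[library$analyte_id == "DA"]
  if (length(da) != 1 || abs(da - 1) > 1e-12) {
    abort("library must contain reference 'DA' with true_normalized = 1")
  }
  set.seed(as.integer(seed))
  wl <- seq(1000, 1300, by = 2)
  background <- 5
  peaks <- default_peaks()

  rows <- list(); maps <- list(); widx <- 0
  add_well <- function(analyte_id, role, dff) {
    widx <<- widx + 1
    wid <- sprintf("W%03d", widx)
    sp <- generate_spectrum(dff, peaks = peaks, noise_sd = noise_sd,
                            wavelength = wl)
    rows[[length(rows) + 1]] <<- bind_rows(
      tibble(well_id = wid, timepoint_min = 0, wavelength_nm = wl,
             intensity = sp$F0$intensity + background),
      tibble(well_id = wid, timepoint_min = timepoint, wavelength_nm = wl,
             intensity = sp$F$intensity + background))
    maps[[length(maps) + 1]] <<- tibble(well_id = wid,
                                        analyte_id = analyte_id,
                                        role = role)
  }

  for (i in seq_len(nrow(library))) {
    aid <- library$analyte_id[i]
    role <- if (aid == "DA") "reference" else "sample"
    for (rep in seq_len(n_rep)) {
      add_well(aid, role, library$true_normalized[i] * dff_reference)
    }
  }
  for (rep in seq_len(n_rep)) {
    widx <- widx + 1
    wid <- sprintf("W%03d", widx)
    noise0 <- rnorm(length(wl), 0, noise_sd)
    noise1 <- rnorm(length(wl), 0, noise_sd)
    rows[[length(rows) + 1]] <- bind_rows(
      tibble(well_id = wid, timepoint_min = 0, wavelength_nm = wl,
             intensity = background + noise0),
      tibble(well_id = wid, timepoint_min = timepoint, wavelength_nm = wl,
             intensity = background + noise1))
    maps[[length(maps) + 1]] <- tibble(well_id = wid, analyte_id = "blank",
                                       role = "blank")
  }

  list(plate = bind_rows(rows), map = bind_rows(maps),
       true_dff = setNames(library$true_normalized * dff_reference,
                           library$analyte_id))
}

#' Packaged compound reference values
#'
#' Small fixture of compound-level values printed in the study this
#' pipeline operationalizes: dopamine-normalized responses with SDs where
#' printed, response categories, structural flags used by the response
#' heuristic, and charge states. Fields not printed are `NA`
#' (placeholders to be transcribed from supplementary tables).
#'
#' @return `compound_fixture()`: tibble of compound values.
#' @export
compound_fixture <- function() {
  path <- system.file("extdata", "compound_values.csv",
                      package = "nanosar")
  as_tibble(utils::read.csv(path, check.names = FALSE,
                            stringsAsFactors = FALSE)) %>%
    mutate(across(c("has_vicinal_donors", "conjugated"), as.logical))
}

#' @rdname compound_fixture
#' @return `pka_fixture()`: tibble `analyte_id`, `site_id`, `pKa`,
#'   `site_class` for the printed ammonium pKa values.
#' @export
pka_fixture <- function() {
  path <- system.file("extdata", "pka_sites.csv", package = "nanosar")
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
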
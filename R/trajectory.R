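#' Assemble a trajectory bundle
#'
#' The in-memory container all trajectory metrics operate on: an atom
#' table, named atom-index groups (nanotube, DNA with backbone subtags,
#' analyte molecules with aryl-ring and polar-group subsets), a frame
#' array of coordinates, the orthorhombic box and the time between stored
#' frames.
#'
#' @param atoms Tibble with columns `atom_id`, `element` and optionally
#'   `name`; one row per atom. A `radius` column is added from
#'   [vdw_radius()] if absent.
#' @param groups Named list with elements `swcnt` (integer indices), `dna`
#'   (list with `all` plus backbone tags such as `P`, `O1P`, `O2P`,
#'   `O3'`, `O4'`, `O5'`), and `analytes`: a list, one element per
#'   molecule, each a list with `atoms`, `aryl_ring` and `polar_groups`
#'   (each polar group a list with `name`, `indices`,
#'   `class` in hydroxy/amine/ammonium/alkoxide).
#' @param coords Numeric array `n_frames x n_atoms x 3` (Angstrom), or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param box Orthorhombic box lengths, length-3 numeric (Angstrom).
#' @param dt Time between stored frames in ns.
#' @return Object of class `trajectory_bundle`.
#' @export
trajectory_bundle <- function(atoms, groups, coords, box, dt) {
  check_columns(atoms, c("atom_id", "element"), "atoms")
  if (!"radius" %in% names(atoms)) atoms$radius <- vdw_radius(atoms$element)
  if (is.matrix(coords)) coords <- array(coords, c(1, dim(coords)))
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort("coords must be an n_frames x n_atoms x 3 array")
  }
  if (dim(coords)[2] != nrow(atoms)) {
    abort("coords atom dimension does not match the atom table")
  }
  if (dim(coords)[1] < 1) abort("need at least one frame")
  if (!all(is.finite(coords))) abort("coordinates must be finite")
  if (length(box) != 3 || any(box <= 0)) abort("box must be 3 positive lengths")
  if (!is.numeric(dt) || dt <= 0) abort("dt must be a positive time in ns")

  for (nm in c("swcnt", "dna", "analytes")) {
    if (is.null(groups[[nm]])) abort(sprintf("groups is missing '%s'", nm))
  }
  core <- list(swcnt = groups$swcnt, dna = groups$dna$all)
  mol_idx <- lapply(groups$analytes, `[[`, "atoms")
  all_sets <- c(core, mol_idx)
  idx <- unlist(all_sets)
  if (any(idx < 1 | idx > nrow(atoms))) abort("group index out of range")
  if (anyDuplicated(idx)) {
    abort("swcnt / dna / analyte atom sets must be disjoint")
  }

  structure(list(atoms = as_tibble(atoms), groups = groups,
                 coords = coords, box = as.numeric(box), dt = dt),
            class = "trajectory_bundle")
}

#' @export
print.trajectory_bundle <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d frames x %d atoms (dt = %g ns, %.1f ns total)\n",
    n_frames(x), nrow(x$atoms), x$dt, n_frames(x) * x$dt))
  cat(sprintf("  swcnt %d atoms, dna %d atoms, %d analyte molecules\n",
              length(x$groups$swcnt), length(x$groups$dna$all),
              length(x$groups$analytes)))
  invisible(x)
}

#' @rdname trajectory_bundle
#' @param traj A `trajectory_bundle`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

# coordinates of selected atoms at one frame, as an n x 3 matrix
frame_coords <- function(traj, frame, indices = NULL) {
  m <- traj$coords[frame, , , drop = TRUE]
  m <- matrix(m, ncol = 3)
  if (!is.null(indices)) m <- m[indices, , drop = FALSE]
  m
}

# unweighted center of mass of an index set at one frame
group_com <- function(traj, frame, indices) {
  colMeans(frame_coords(traj, frame, indices))
}

#' Read a trajectory from PDB topology and DCD frames
#'
#' Thin reader over bio3d: the PDB supplies atom ids, elements and names,
#' the DCD (if given) the coordinate frames, and a JSON group config maps
#' named groups to 1-based atom index vectors with the structure described
#' in [trajectory_bundle()].
#'
#' @param pdb_file Path to a PDB file (used alone, its MODEL records are
#'   the frames).
#' @param groups Either a groups list or a path to a JSON file encoding it.
#' @param dcd_file Optional DCD file of frames.
#' @param box Box lengths (Angstrom); required (PDB CRYST1 used if absent).
#' @param dt Time between stored frames in ns.
#' @return A `trajectory_bundle`.
#' @export
read_trajectory <- function(pdb_file, groups, dcd_file = NULL,
                            box = NULL, dt = 1) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading PDB/DCD requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(pdb_file, multi = is.null(dcd_file))
  el <- pdb$atom$elesy
  if (is.null(el) || all(is.na(el)) || all(el == "")) {
    el <- substr(trimws(pdb$atom$elety), 1, 1)
  }
  atoms <- tibble(atom_id = pdb$atom$eleno, element = trimws(el),
                  name = trimws(pdb$atom$elety))
  if (is.character(groups)) {
    groups <- jsonlite::fromJSON(groups, simplifyVector = TRUE)
    groups <- rapply(groups, as.integer, classes = c("integer", "numeric"),
                     how = "replace")
  }
  if (!is.null(dcd_file)) {
    xyz <- bio3d::read.dcd(dcd_file, verbose = FALSE)
  } else {
    xyz <- pdb$xyz
  }
  xyz <- matrix(xyz, ncol = 3 * nrow(atoms))
  coords <- array(0, c(nrow(xyz), nrow(atoms), 3))
  for (d in 1:3) coords[, , d] <- xyz[, seq(d, ncol(xyz), by = 3)]
  if (is.null(box)) {
    box <- apply(coords, 3, function(m) diff(range(m))) + 20
  }
  trajectory_bundle(atoms, groups, coords, box, dt)
}
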
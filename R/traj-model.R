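#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Standard atomic masses (Da) for the elements that occur in protein/ligand
# systems; used when the input format carries no masses (PDB, GRO).
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  "F" = 18.998, CL = 35.45, BR = 79.904, I = 126.904, "NA" = 22.990,
  K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38, FE = 55.845,
  MN = 54.938, CU = 63.546, SE = 78.971
)

.guess_element <- function(atom_name) {
  # Strip digits/primes, take the leading element symbol. Two-letter symbols
  # are only accepted when they match a known element (avoids CA -> calcium
  # for alpha carbons, which PDB disambiguates by column position; atom names
  # here are already trimmed so we default two-letter matches to one letter
  # for C/N/O/H/S starts).
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", atom_name)))
  one <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "BR", "MG", "ZN", "FE", "MN", "CU", "SE") &
           nchar(nm) >= 2, two, one)
}

.mass_from_element <- function(element) {
  m <- .element_masses[toupper(element)]
  m[is.na(m)] <- 12.011  # unknown elements get a carbon-like default
  unname(m)
}

#' Construct a simulation box
#'
#' Orthorhombic periodic (or open) box used for minimum-image distance
#' computations. All lengths are in Angstrom.
#'
#' @param lengths Numeric length-3 vector of box edge lengths (Angstrom).
#' @param periodic Logical; if `FALSE` distances are plain Euclidean.
#' @return An object of class `sim_box`.
#' @export
sim_box <- function(lengths = c(Inf, Inf, Inf), periodic = TRUE) {
  lengths <- rep_len(as.numeric(lengths), 3L)
  if (periodic && any(!is.finite(lengths) | lengths <= 0)) {
    abort("periodic box lengths must all be positive and finite")
  }
  structure(list(lengths = lengths, periodic = isTRUE(periodic)),
            class = "sim_box")
}

#' @export
print.sim_box <- function(x, ...) {
  if (x$periodic) {
    cat(sprintf("<sim_box> periodic, %.2f x %.2f x %.2f A\n",
                x$lengths[1], x$lengths[2], x$lengths[3]))
  } else {
    cat("<sim_box> non-periodic\n")
  }
  invisible(x)
}

#' Construct a topology
#'
#' A topology holds the per-atom metadata of a molecular system together with
#' the partition into a protein selection and zero or more substrate copies.
#' Atom indices are 1-based throughout the package.
#'
#' @param atoms A data frame with columns `atom_name`, `residue_name`,
#'   `residue_number`, `chain_id` and optionally `element` and `mass`
#'   (Daltons). Missing elements are guessed from atom names, missing masses
#'   filled from standard atomic masses.
#' @param protein Integer vector of protein atom indices.
#' @param substrates List of integer vectors, one per substrate copy.
#' @return An object of class `topology`.
#' @export
topology <- function(atoms, protein = integer(), substrates = list()) {
  atoms <- as_tibble(atoms)
  need <- c("atom_name", "residue_name", "residue_number", "chain_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) abort(paste0("atoms is missing column(s): ",
                                 paste(miss, collapse = ", ")))
  n <- nrow(atoms)
  if (n == 0L) abort("no atoms")
  if (is.null(atoms[["element"]])) {
    atoms$element <- .guess_element(atoms$atom_name)
  }
  if (is.null(atoms[["mass"]])) {
    atoms$mass <- .mass_from_element(atoms$element)
  }
  if (any(!is.finite(atoms$mass) | atoms$mass <= 0)) {
    abort("all atom masses must be positive")
  }
  atoms <- atoms |> mutate(atom_index = seq_len(n), .before = 1)
  protein <- as.integer(protein)
  substrates <- lapply(substrates, as.integer)
  all_idx <- c(protein, unlist(substrates))
  if (length(all_idx) && (any(all_idx < 1L) || any(all_idx > n))) {
    abort("selection indices out of range")
  }
  if (anyDuplicated(all_idx)) {
    abort("protein and substrate selections must be disjoint")
  }
  structure(list(atoms = atoms, protein = protein, substrates = substrates),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d protein, %d substrate copies\n",
              nrow(x$atoms), length(x$protein), length(x$substrates)))
  invisible(x)
}

#' Number of atoms in a topology or trajectory
#' @param x A `topology` or `trajectory`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Assign protein and substrate selections by residue name
#'
#' Convenience constructor of the protein/substrate partition: every residue
#' whose name matches `substrate_resname` becomes one substrate copy (one copy
#' per distinct chain/residue-number pair), everything else is protein.
#'
#' @param atoms Atom table as for [topology()].
#' @param substrate_resname Residue name identifying substrate copies.
#' @return A `topology`.
#' @export
topology_by_residue <- function(atoms, substrate_resname) {
  atoms <- as_tibble(atoms)
  is_sub <- atoms$residue_name == substrate_resname
  key <- paste(atoms$chain_id, atoms$residue_number)
  subs <- split(which(is_sub), key[is_sub])
  subs <- subs[order(vapply(subs, min, 1L))]
  topology(atoms, protein = which(!is_sub), substrates = unname(subs))
}

#' Construct a trajectory
#'
#' @param topology A [topology()].
#' @param coords Numeric array of dimension `c(n_atoms, 3, n_frames)`
#'   (Angstrom), or a single `n_atoms x 3` matrix.
#' @param box A [sim_box()] shared by all frames, or a list of one per frame.
#' @param frame_interval Time between stored frames in ps.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, box = sim_box(periodic = FALSE),
                       frame_interval = 1) {
  stopifnot(inherits(topology, "topology"))
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  d <- dim(coords)
  if (length(d) != 3L || d[2] != 3L) {
    abort("coords must be an n_atoms x 3 x n_frames array")
  }
  if (d[1] != n_atoms(topology)) {
    abort(sprintf("coordinate array has %d atoms but topology has %d",
                  d[1], n_atoms(topology)))
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    abort("frame_interval must be positive (ps)")
  }
  if (inherits(box, "sim_box")) box <- rep(list(box), d[3])
  if (length(box) != d[3]) abort("need one box per frame")
  structure(list(topology = topology, coords = coords, box = box,
                 frame_interval = as.numeric(frame_interval)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, %.3g ps/frame\n",
              n_frames(x), n_atoms(x), x$frame_interval))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param x A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) dim(x$coords)[3]

#' Extract one frame of coordinates
#' @param x A `trajectory`.
#' @param i Frame index (1-based).
#' @return `n_atoms x 3` matrix (Angstrom).
#' @export
frame_coords <- function(x, i) {
  if (i < 1L || i > n_frames(x)) abort(sprintf("frame %d out of range", i))
  x$coords[, , i, drop = TRUE]
}

#' Group several replicate trajectories
#'
#' Replicates are independent simulations of the same system (identical atom
#' ordering) at one nominal substrate concentration.
#'
#' @param trajectories List of [trajectory()] objects.
#' @param concentration Nominal bulk substrate concentration label (mM).
#' @param variant Free-text system label (e.g. enzyme variant).
#' @return An object of class `replicate_set`.
#' @export
replicate_set <- function(trajectories, concentration = NA_real_,
                          variant = "") {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  trajectories <- unname(trajectories)   # replicates are indexed, not named
  if (!length(trajectories)) abort("need at least one trajectory")
  counts <- vapply(trajectories, n_atoms, 1L)
  if (length(unique(counts)) != 1L) {
    abort("all replicates must share one topology (atom counts differ)")
  }
  nm1 <- trajectories[[1]]$topology$atoms$atom_name
  for (tr in trajectories[-1]) {
    if (!identical(tr$topology$atoms$atom_name, nm1)) {
      abort("all replicates must share an identical atom ordering")
    }
  }
  structure(list(trajectories = trajectories,
                 concentration = as.numeric(concentration),
                 variant = as.character(variant)),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set> %d replicates, c = %s mM%s\n",
              length(x$trajectories),
              format(x$concentration),
              if (nzchar(x$variant)) paste0(", ", x$variant) else ""))
  invisible(x)
}

#' Minimum-image distance between two points
#'
#' @param a,b Numeric length-3 coordinates (Angstrom).
#' @param box A [sim_box()].
#' @return Distance in Angstrom; under periodic boundaries the closest-image
#'   distance, otherwise plain Euclidean.
#' @export
minimum_image_distance <- function(a, b, box = sim_box(periodic = FALSE)) {
  d <- as.numeric(a) - as.numeric(b)
  if (box$periodic) d <- d - box$lengths * round(d / box$lengths)
  sqrt(sum(d^2))
}

# Vectorised minimum-image displacement: rows of `x` minus point `p`.
.mi_disp <- function(x, p, box) {
  d <- sweep(x, 2, p)
  if (box$periodic) {
    L <- box$lengths
    d <- d - sweep(round(sweep(d, 2, L, "/")), 2, L, "*")
  }
  d
}

# Vectorised minimum-image distances from rows of `x` to point `p`.
.mi_dist <- function(x, p, box) sqrt(rowSums(.mi_disp(x, p, box)^2))

#' Mass-weighted centre of mass of a selection
#'
#' For molecules split across periodic boundaries the atoms are first
#' unwrapped relative to the selection's first atom, so the result is the
#' centre of the connected molecule image (possibly outside the primary box).
#'
#' @param coords `n_atoms x 3` coordinate matrix (one frame, Angstrom).
#' @param indices Atom indices of the selection (1-based).
#' @param topology The [topology()] supplying masses.
#' @param box A [sim_box()] used for unwrapping.
#' @return Length-3 numeric centre of mass (Angstrom).
#' @export
center_of_mass <- function(coords, indices, topology,
                           box = sim_box(periodic = FALSE)) {
  indices <- as.integer(indices)
  if (!length(indices)) abort("empty selection")
  m <- topology$atoms$mass[indices]
  x <- coords[indices, , drop = FALSE]
  ref <- x[1, ]
  x <- sweep(.mi_disp(x, ref, box), 2, ref, "+")
  colSums(x * m) / sum(m)
}

# Centres of mass for every substrate copy in one frame: n_sub x 3 matrix.
.substrate_coms <- function(coords, topology, box) {
  t(vapply(topology$substrates,
           function(idx) center_of_mass(coords, idx, topology, box),
           numeric(3)))
}
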
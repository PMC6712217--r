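#' Piecewise-constant radial potential
#'
#' External potential `U(r)` (in kT) felt by non-interacting substrate
#' particles as a function of distance `r` from a fixed receptor site;
#' a stand-in with known ground truth for an enzyme's potential of mean
#' force. Segments must be contiguous and non-overlapping; outside all
#' segments `U = 0`. An optional hard core (`U = +Inf` for `r < r_core`)
#' models an impenetrable barrier.
#'
#' @param segments Data frame with columns `r_lo`, `r_hi` (Angstrom) and
#'   `u_kt`, or `NULL` for a free (ideal-gas) particle.
#' @param r_core Hard-core radius in Angstrom (0 = none).
#' @return Object of class `radial_potential`.
#' @export
radial_potential <- function(segments = NULL, r_core = 0) {
  if (is.null(segments)) {
    segments <- tibble(r_lo = numeric(), r_hi = numeric(), u_kt = numeric())
  }
  segments <- as_tibble(segments)[c("r_lo", "r_hi", "u_kt")]
  if (nrow(segments)) {
    segments <- arrange(segments, .data$r_lo)
    if (any(segments$r_hi <= segments$r_lo)) {
      abort("each segment needs r_lo < r_hi")
    }
    if (nrow(segments) > 1 &&
        any(segments$r_lo[-1] < segments$r_hi[-nrow(segments)] - 1e-9)) {
      abort("potential segments overlap")
    }
    if (any(!is.finite(segments$u_kt))) {
      abort("segment energies must be finite (use r_core for a hard core)")
    }
  }
  if (r_core < 0) abort("r_core must be >= 0")
  structure(list(segments = segments, r_core = as.numeric(r_core)),
            class = "radial_potential")
}

#' Evaluate a radial potential
#' @param potential A [radial_potential()].
#' @param r Distances (Angstrom).
#' @return `U(r)` in kT (`+Inf` inside the hard core, 0 outside all
#'   segments).
#' @export
potential_energy <- function(potential, r) {
  u <- numeric(length(r))
  seg <- potential$segments
  if (nrow(seg)) {
    for (i in seq_len(nrow(seg))) {
      u[r >= seg$r_lo[i] & r < seg$r_hi[i]] <- seg$u_kt[i]
    }
  }
  u[r < potential$r_core] <- Inf
  u
}

# Minimum-image radial distance of particle positions (n x 3) to the box
# centre.
.radii <- function(pos, centre, L) {
  d <- sweep(pos, 2, centre)
  d <- d - L * t(round(t(d) / L))
  sqrt(rowSums(d^2))
}

#' Equilibrium particle configurations in an external radial potential
#'
#' Metropolis Monte Carlo of `n_particles` non-interacting point particles
#' in a periodic cubic box, subject to an external radial potential centred
#' on a fixed single-atom receptor at the box centre. After burn-in the
#' particle positions are Boltzmann-distributed, `density(r) proportional to
#' exp(-U(r)/kT)`, which makes the output an exact ground truth for
#' Boltzmann-inversion profiling. Only equilibrium statistics are
#' meaningful: frame order carries no kinetic information.
#'
#' The emitted trajectory contains the receptor as atom 1 (protein selection)
#' and one single-atom substrate copy per particle, so the full downstream
#' pipeline (d_NAC, histograms, profiles, binding counts) runs unchanged
#' with the receptor atom as the serine-oxygen anchor; all four catalytic
#' distances then collapse to the radial distance.
#'
#' @param potential A [radial_potential()].
#' @param n_particles Number of substrate particles (default 5000).
#' @param box_length Cubic box edge (Angstrom; default 160 so that far-field
#'   bins beyond 60 A exist for the bulk-concentration calibration).
#' @param n_sweeps Total MC sweeps (default 600).
#' @param burn_in Sweeps discarded before sampling (default 200).
#' @param step_size Maximum per-axis displacement per move (Angstrom,
#'   default 30; large steps decorrelate successive frames of this
#'   interaction-free system).
#' @param frame_stride Sweeps between stored frames (default 2).
#' @param seed Integer RNG seed; the run is reproducible bit-for-bit.
#' @param substrate_resname Residue name given to the particles.
#' @return A [trajectory()] with attributes `acceptance_rate` and
#'   `generator` (a provenance list echoing every parameter). A warning is
#'   issued when the post-burn-in acceptance rate falls outside [0.1, 0.9].
#' @export
simulate_external_potential <- function(potential,
                                        n_particles = 5000,
                                        box_length = 160,
                                        n_sweeps = 600,
                                        burn_in = 200,
                                        step_size = 30,
                                        frame_stride = 2,
                                        seed = 1,
                                        substrate_resname = "SUB") {
  stopifnot(inherits(potential, "radial_potential"))
  if (burn_in >= n_sweeps) abort("burn_in must be < n_sweeps")
  if (n_particles < 1 || box_length <= 0 || step_size <= 0 ||
      frame_stride < 1) {
    abort("invalid Monte Carlo parameters")
  }
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  L <- box_length
  centre <- rep(L / 2, 3)
  # initial positions: uniform, resampled out of the hard core
  pos <- matrix(stats::runif(n_particles * 3, 0, L), ncol = 3)
  u <- potential_energy(potential, .radii(pos, centre, L))
  while (any(!is.finite(u))) {
    bad <- !is.finite(u)
    pos[bad, ] <- matrix(stats::runif(sum(bad) * 3, 0, L), ncol = 3)
    u[bad] <- potential_energy(potential, .radii(pos[bad, , drop = FALSE],
                                                 centre, L))
  }
  frames <- list()
  acc <- 0; tries <- 0
  for (sweep in seq_len(n_sweeps)) {
    prop <- pos + matrix(stats::runif(n_particles * 3, -step_size, step_size),
                         ncol = 3)
    prop <- prop %% L
    u_new <- potential_energy(potential, .radii(prop, centre, L))
    du <- u_new - u
    take <- stats::runif(n_particles) < exp(pmin(-du, 0))
    take[!is.finite(u_new)] <- FALSE
    pos[take, ] <- prop[take, ]
    u[take] <- u_new[take]
    if (sweep > burn_in) {
      acc <- acc + sum(take); tries <- tries + n_particles
      if ((sweep - burn_in) %% frame_stride == 0) {
        frames[[length(frames) + 1L]] <- pos
      }
    }
  }
  rate <- acc / tries
  if (rate < 0.1 || rate > 0.9) {
    warn(sprintf("MC acceptance rate %.3f outside [0.1, 0.9]", rate))
  }
  atoms <- tibble(
    atom_name = c("REC", rep("C1", n_particles)),
    residue_name = c("REC", rep(substrate_resname, n_particles)),
    residue_number = c(1L, seq_len(n_particles) + 1L),
    chain_id = c("R", rep("S", n_particles)),
    element = "C")
  top <- topology(atoms, protein = 1L,
                  substrates = as.list(seq_len(n_particles) + 1L))
  nf <- length(frames)
  arr <- array(NA_real_, c(n_particles + 1L, 3L, nf))
  for (f in seq_len(nf)) arr[, , f] <- rbind(centre, frames[[f]])
  traj <- trajectory(top, arr, box = sim_box(rep(L, 3), periodic = TRUE),
                     frame_interval = 1)
  attr(traj, "acceptance_rate") <- rate
  attr(traj, "generator") <- list(
    generator = "simulate_external_potential",
    potential = potential, n_particles = n_particles, box_length = box_length,
    n_sweeps = n_sweeps, burn_in = burn_in, step_size = step_size,
    frame_stride = frame_stride, seed = seed)
  traj
}

#' A NAC specification for generator trajectories
#'
#' For [simulate_external_potential()] output every catalytic distance is
#' anchored on the single receptor atom and the single substrate atom, so
#' d_NAC reduces to the radial distance from the receptor.
#'
#' @return A [nac_spec()].
#' @export
synthetic_nac_spec <- function() {
  nac_spec(ser_hydroxyl_o = 1L, substrate_carbonyl_c = "C1",
           substrate_carbonyl_o = "C1",
           donor_d2 = 1L, donor_d3 = 1L, donor_d4 = 1L)
}

#' Synthetic occupancy series of saturable identical binding sites
#'
#' Generative inverse of the Langmuir model: each of `n_sites` identical,
#' non-cooperative sites is independently occupied in each frame with
#' probability `c / (K_true + c)`; the per-frame bound count is their sum,
#' so the expected count is exactly the Langmuir isotherm. Defaults mirror
#' the study conditions of the access simulations: 5 replicates of 200000
#' production frames at equilibrated bulk concentrations 3, 5, 25 and 50 mM.
#'
#' @param K_true Planted binding constant (mM; default 7.4).
#' @param n_sites Number of binding sites (default 12).
#' @param concentrations Bulk concentrations (mM).
#' @param n_frames Frames per replicate (default 200000).
#' @param n_replicates Replicates per concentration (default 5).
#' @param seed Integer RNG seed.
#' @return Tibble with columns `concentration_mM`, `replicate`, `frame`,
#'   `n_bound`, and attribute `generator` echoing the parameters.
#' @export
generate_langmuir_occupancy <- function(K_true = 7.4, n_sites = 12,
                                        concentrations = c(3, 5, 25, 50),
                                        n_frames = 200000,
                                        n_replicates = 5,
                                        seed = 1) {
  if (K_true <= 0 || n_sites < 1) abort("K_true > 0 and n_sites >= 1 required")
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  out <- tidyr::expand_grid(concentration_mM = concentrations,
                            replicate = seq_len(n_replicates)) |>
    mutate(counts = purrr::map(.data$concentration_mM, function(cc) {
      stats::rbinom(n_frames, n_sites, cc / (K_true + cc))
    })) |>
    tidyr::unnest_longer(col = "counts", values_to = "n_bound",
                         indices_to = "frame") |>
    select("concentration_mM", "replicate", "frame", "n_bound")
  attr(out, "generator") <- list(generator = "generate_langmuir_occupancy",
                                 K_true = K_true, n_sites = n_sites,
                                 concentrations = concentrations,
                                 n_frames = n_frames,
                                 n_replicates = n_replicates, seed = seed)
  out
}

# Uniformly random rotation matrix (det +1) from three uniform quaternions.
.random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# A fixed non-degenerate C-alpha scaffold used as the carrier protein frame.
.default_scaffold <- function() {
  set <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 7, 0), c(0, 0, 8),
               c(5, 5, 0), c(0, 6, 6), c(7, 0, 7), c(4, 4, 4))
  set + 20
}

# A small default 5-atom substrate template.
.default_template <- function() {
  rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.3, 1.2, 0),
        c(1.5, 2.4, 0.3), c(-0.8, 0.9, 0.6))
}

#' Planted-cluster substrate conformers under random rigid frames
#'
#' Draws conformers as isotropic Gaussian perturbations (per-atom sd
#' `sigma`) of `k` reference substrate conformations; each conformer's
#' carrier protein frame (a fixed C-alpha scaffold) and substrate are then
#' jointly moved by a random rigid-body rotation + translation, so that a
#' correct protein-frame superposition must undo the transform before
#' clustering can recover the planted labels. Defaults emulate a dominant
#' pose holding 95% of conformers against a 5% minority pose.
#'
#' @param centers List of `n_atoms x 3` substrate reference conformations;
#'   default: two copies of a 5-atom template 10 A apart.
#' @param sizes Integer conformer counts per cluster; default `c(95, 5) /
#'   100 * n_total` with `n_total = 500`.
#' @param sigma Per-atom isotropic spread in Angstrom (default 0.5).
#' @param n_total Total conformers when `sizes` is not given.
#' @param max_shift Maximum rigid translation per axis (Angstrom).
#' @param seed Integer RNG seed.
#' @return A `conformer_set` (not yet superposed) whose `source` tibble
#'   carries the planted `true_label`, plus attribute `generator`.
#' @export
generate_conformers <- function(centers = NULL, sizes = NULL, sigma = 0.5,
                                n_total = 500, max_shift = 15, seed = 1) {
  if (is.null(centers)) {
    tmpl <- .default_template()
    centers <- list(tmpl + 28, tmpl + matrix(c(10, 0, 0), nrow(tmpl), 3,
                                             byrow = TRUE) + 28)
  }
  k <- length(centers)
  sizes <- sizes %||% {
    s <- round(n_total * c(0.95, rep(0.05 / max(1, k - 1), k - 1)))
    s[1] <- n_total - sum(s[-1])
    s
  }
  if (length(sizes) != k || any(sizes < 1)) {
    abort("sizes must give a positive count per cluster")
  }
  if (sigma < 0) abort("sigma must be >= 0")
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  scaffold <- .default_scaffold()
  na_sub <- nrow(centers[[1]])
  n <- sum(sizes)
  labels <- rep(seq_len(k), sizes)
  sub <- array(NA_real_, c(n, na_sub, 3))
  fit <- array(NA_real_, c(n, nrow(scaffold), 3))
  for (i in seq_len(n)) {
    conf <- centers[[labels[i]]] +
      matrix(stats::rnorm(na_sub * 3, 0, sigma), na_sub, 3)
    rot <- .random_rotation()
    shift <- stats::runif(3, -max_shift, max_shift)
    sub[i, , ] <- sweep(conf %*% t(rot), 2, shift, "+")
    fit[i, , ] <- sweep(scaffold %*% t(rot), 2, shift, "+")
  }
  structure(list(sub_coords = sub, fit_coords = fit,
                 source = tibble(replicate = 1L, frame = seq_len(n),
                                 substrate = 1L, dnac = NA_real_,
                                 true_label = labels),
                 window = c(NA_real_, NA_real_),
                 fit_indices = seq_len(nrow(scaffold)),
                 superposed = FALSE,
                 reference = scaffold),
            class = "conformer_set") |>
    (\(x) {attr(x, "generator") <- list(generator = "generate_conformers",
                                        k = k, sizes = sizes, sigma = sigma,
                                        max_shift = max_shift, seed = seed)
           x})()
}

# Preserve/restore the caller's RNG state so seeded generators do not
# perturb an enclosing simulation.
.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
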
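# Shared fixtures and independent brute-force oracles.

# Minimal atom table: names/residues chosen freely per test.
atom_tbl <- function(names, resnames = "GLY", resnos = seq_along(names),
                     chains = "A", elements = NULL, masses = NULL) {
  tb <- tibble::tibble(
    atom_name = names,
    residue_name = rep_len(resnames, length(names)),
    residue_number = rep_len(resnos, length(names)),
    chain_id = rep_len(chains, length(names)))
  if (!is.null(elements)) tb$element <- elements
  if (!is.null(masses)) tb$mass <- masses
  tb
}

# Single-site toy system: one "serine oxygen" anchor (protein atom 1), a few
# extra protein atoms, and single-atom substrate copies at caller-given
# positions. Substrate atom names make d_NAC collapse to the anchor distance.
toy_system <- function(sub_pos, prot_pos = NULL, box = NULL,
                       frame_interval = 1) {
  if (is.null(prot_pos)) prot_pos <- matrix(c(0, 0, 0), 1, 3)
  np <- nrow(prot_pos)
  ns <- nrow(sub_pos)
  atoms <- atom_tbl(c(rep("PA", np), rep("C1", ns)),
                    resnames = c(rep("PRO", np), rep("SUB", ns)),
                    resnos = seq_len(np + ns),
                    chains = c(rep("A", np), rep("S", ns)))
  atoms$atom_name[1] <- "OG"
  top <- topology(atoms, protein = seq_len(np),
                  substrates = as.list(np + seq_len(ns)))
  coords <- rbind(prot_pos, sub_pos)
  trajectory(top, coords, box = box %||% sim_box(periodic = FALSE),
             frame_interval = frame_interval)
}

toy_nac_spec <- function() {
  nac_spec(ser_hydroxyl_o = 1L, substrate_carbonyl_c = "C1",
           substrate_carbonyl_o = "C1", donor_d2 = 1L, donor_d3 = 1L,
           donor_d4 = 1L)
}

# Multi-frame variant: sub_pos_list is a list of n_sub x 3 matrices.
toy_multiframe <- function(sub_pos_list, prot_pos = NULL, box = NULL) {
  one <- toy_system(sub_pos_list[[1]], prot_pos, box)
  arr <- array(NA_real_, c(n_atoms(one), 3, length(sub_pos_list)))
  np <- length(one$topology$protein)
  for (f in seq_along(sub_pos_list)) {
    arr[seq_len(np), , f] <- one$coords[seq_len(np), , 1]
    arr[-seq_len(np), , f] <- sub_pos_list[[f]]
  }
  trajectory(one$topology, arr, box = one$box[[1]])
}

`%||%` <- rlang::`%||%`

# --- independent oracles ----------------------------------------------------

# Naive double-loop RMSD matrix.
naive_rmsd_matrix <- function(coords) {
  n <- dim(coords)[1]
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- sqrt(mean(rowSums((coords[i, , ] - coords[j, , ])^2)))
  }
  out
}

# Naive gromos clustering by direct neighbour recount each round.
naive_gromos <- function(m, cutoff) {
  n <- nrow(m)
  remaining <- seq_len(n)
  labels <- integer(n)
  centroids <- integer(0)
  k <- 0
  while (length(remaining)) {
    best <- remaining[1]; best_n <- -1
    for (i in remaining) {
      cnt <- sum(m[i, remaining] <= cutoff) - 1
      if (cnt > best_n) { best <- i; best_n <- cnt }
    }
    members <- remaining[m[best, remaining] <= cutoff]
    members <- union(best, members)
    k <- k + 1
    labels[members] <- k
    centroids[k] <- best
    remaining <- setdiff(remaining, members)
  }
  list(labels = labels, centroids = centroids)
}

# Same-partition check up to relabeling.
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

euler_rotation <- function(a, b, c) {
  rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
               3, 3, byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)),
               3, 3, byrow = TRUE)
  rz <- rotation_z(c)
  rz %*% ry %*% rx
}

# Brute-force minimal RMSD over rigid motions: coarse Euler-angle grid then
# Nelder-Mead refinement; translation handled by centring.
brute_force_fit_rmsd <- function(mobile, reference) {
  x0 <- sweep(mobile, 2, colMeans(mobile))
  y0 <- sweep(reference, 2, colMeans(reference))
  obj <- function(p) {
    r <- euler_rotation(p[1], p[2], p[3])
    sqrt(mean(rowSums((x0 %*% t(r) - y0)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 7)[-7]
  best <- NULL; best_v <- Inf
  for (a in grid) for (b in grid) for (c in grid) {
    v <- obj(c(a, b, c))
    if (v < best_v) { best_v <- v; best <- c(a, b, c) }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}
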
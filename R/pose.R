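#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares rotation + translation (no reflection) of `mobile` onto
#' `reference`, computed on the `fit_indices` atoms and applied to all atoms
#' of `mobile` (and to any `carry` coordinates sharing the same frame, e.g.
#' the substrate carried with a protein frame).
#'
#' @param mobile `n x 3` coordinate matrix to transform.
#' @param reference `n_fit x 3` (or `n x 3`) reference coordinates; must have
#'   as many rows as there are fit atoms.
#' @param fit_indices Row indices of `mobile` used for the fit (default: all
#'   rows). At least 3 non-collinear atoms are required.
#' @param carry Optional `m x 3` matrix transformed with the same rigid
#'   transform.
#' @return List with `coords` (transformed `mobile`), `carry` (transformed
#'   `carry` or `NULL`), `rmsd` (fit-atom RMSD after superposition,
#'   Angstrom), `rotation` (3x3, det +1) and `translation`.
#' @export
superpose_kabsch <- function(mobile, reference, fit_indices = NULL,
                             carry = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  fit_indices <- fit_indices %||% seq_len(nrow(mobile))
  if (length(fit_indices) < 3L) abort("need at least 3 fit atoms")
  x <- mobile[fit_indices, , drop = FALSE]
  y <- if (nrow(reference) == length(fit_indices)) reference else
    reference[fit_indices, , drop = FALSE]
  if (nrow(x) != nrow(y)) abort("fit atom counts differ")
  xc <- colMeans(x); yc <- colMeans(y)
  x0 <- sweep(x, 2, xc); y0 <- sweep(y, 2, yc)
  sv <- svd(crossprod(x0, y0))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1)) {
    abort("degenerate (collinear) fit geometry: rotation not determined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # maps centred x onto y
  apply_tf <- function(m) {
    sweep(sweep(m, 2, xc) %*% t(rot), 2, yc, "+")
  }
  fitted <- apply_tf(mobile)
  rmsd <- sqrt(mean(rowSums((fitted[fit_indices, , drop = FALSE] - y)^2)))
  list(coords = fitted,
       carry = if (!is.null(carry)) apply_tf(as.matrix(carry)),
       rmsd = rmsd, rotation = rot, translation = yc - as.vector(rot %*% xc))
}

#' Extract substrate conformers in a d_NAC window
#'
#' Collects, for every molecule-frame observation with
#' `d_lo < d_NAC < d_hi`, the substrate coordinates together with the
#' protein fit-atom coordinates of that frame, ready for superposition and
#' clustering. When the window matches nothing an empty set is returned with
#' a message (not an error).
#'
#' @param replicates The [replicate_set()] the series came from.
#' @param series The matching [dnac_series()].
#' @param window Length-2 numeric `(d_lo, d_hi)` in Angstrom, `d_lo < d_hi`;
#'   the window is open on both sides.
#' @param fit_indices Protein atom indices used later for superposition
#'   (e.g. all C-alpha atoms); default: atoms named `"CA"` in the protein
#'   selection, or all protein atoms if none are.
#' @return Object of class `conformer_set`: list with `sub_coords`
#'   (`n_conf x n_sub_atoms x 3` array), `fit_coords`
#'   (`n_conf x n_fit x 3`), `source` tibble (`replicate`, `frame`,
#'   `substrate`, `dnac`), `window`, `fit_indices`, `superposed` flag.
#' @export
extract_conformers <- function(replicates, series, window,
                               fit_indices = NULL) {
  if (length(window) != 2L || !(window[1] < window[2])) {
    abort("window must be (d_lo, d_hi) with d_lo < d_hi")
  }
  top <- replicates$trajectories[[1]]$topology
  if (is.null(fit_indices)) {
    ca <- top$protein[top$atoms$atom_name[top$protein] == "CA"]
    fit_indices <- if (length(ca) >= 3L) ca else top$protein
  }
  ns_atoms <- lengths(top$substrates)
  if (length(unique(ns_atoms)) != 1L) {
    abort("substrate copies differ in atom count")
  }
  hits <- filter(series, .data$dnac > window[1], .data$dnac < window[2])
  if (!nrow(hits)) {
    message(sprintf("no conformers in window (%g, %g) A",
                    window[1], window[2]))
  }
  nc <- nrow(hits)
  sub_coords <- array(NA_real_, c(nc, ns_atoms[1], 3L))
  fit_coords <- array(NA_real_, c(nc, length(fit_indices), 3L))
  for (i in seq_len(nc)) {
    traj <- replicates$trajectories[[hits$replicate[i]]]
    xyz <- traj$coords[, , hits$frame[i], drop = TRUE]
    sub_coords[i, , ] <- xyz[top$substrates[[hits$substrate[i]]], ,
                             drop = FALSE]
    fit_coords[i, , ] <- xyz[fit_indices, , drop = FALSE]
  }
  structure(list(sub_coords = sub_coords, fit_coords = fit_coords,
                 source = select(hits, "replicate", "frame", "substrate",
                                 "dnac"),
                 window = as.numeric(window),
                 fit_indices = as.integer(fit_indices),
                 superposed = FALSE),
            class = "conformer_set")
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf(
    "<conformer_set> %d conformers, window (%g, %g) A, %ssuperposed\n",
    n_conformers(x), x$window[1], x$window[2],
    if (x$superposed) "" else "not "))
  invisible(x)
}

#' Number of conformers in a set
#' @param x A `conformer_set`.
#' @return Integer count.
#' @export
n_conformers <- function(x) dim(x$sub_coords)[1]

#' Superpose every conformer onto a common protein frame
#'
#' Applies [superpose_kabsch()] per conformer: the protein fit atoms are
#' fitted onto the reference and the resulting rigid transform is applied to
#' the substrate atoms carried with the frame.
#'
#' @param set A [extract_conformers()] result.
#' @param reference `n_fit x 3` reference fit-atom coordinates; default: the
#'   first conformer's fit atoms.
#' @return The `conformer_set` with transformed coordinates, `superposed =
#'   TRUE` and a `fit_rmsd` vector (per-conformer fit RMSD).
#' @export
superpose_conformers <- function(set, reference = NULL) {
  nc <- n_conformers(set)
  if (!nc) return(set)
  reference <- reference %||% set$fit_coords[1, , ]
  rmsd <- numeric(nc)
  for (i in seq_len(nc)) {
    sp <- superpose_kabsch(set$fit_coords[i, , ], reference,
                           carry = set$sub_coords[i, , ])
    set$fit_coords[i, , ] <- sp$coords
    set$sub_coords[i, , ] <- sp$carry
    rmsd[i] <- sp$rmsd
  }
  set$superposed <- TRUE
  set$fit_rmsd <- rmsd
  set
}

#' All-against-all substrate RMSD matrix
#'
#' Plain coordinate RMSD over all substrate atoms, with no re-fitting
#' between pairs: the superposition is fixed once by the shared protein
#' frame, so conformer differences include rigid displacement of the
#' substrate relative to the protein.
#'
#' @param set A superposed `conformer_set` (or any `n x m x 3` array).
#' @return Symmetric `n x n` matrix of RMSD values (Angstrom), zero
#'   diagonal.
#' @export
pairwise_rmsd <- function(set) {
  coords <- if (inherits(set, "conformer_set")) set$sub_coords else set
  nc <- dim(coords)[1]
  if (nc < 2L) abort("need at least 2 conformers")
  m <- dim(coords)[2]
  flat <- matrix(coords, nrow = nc)   # n x (m*3), columns atom-major per dim
  sq <- rowSums(flat^2)
  g <- flat %*% t(flat)
  d2 <- (outer(sq, rep(1, nc)) + outer(rep(1, nc), sq) - 2 * g) / m
  d2[d2 < 0] <- 0
  m_out <- sqrt(d2)
  diag(m_out) <- 0
  (m_out + t(m_out)) / 2
}

#' Cluster conformers by the gromos neighbour-counting algorithm
#'
#' Iteratively, the conformer with the most neighbours within `cutoff` RMSD
#' becomes a cluster centroid; it and its neighbours form the cluster and
#' are removed; repeat until no conformers remain. Ties are broken by the
#' lowest conformer index. Clusters are reported in order of decreasing
#' population.
#'
#' @param rmsd_matrix Symmetric RMSD matrix, e.g. from [pairwise_rmsd()].
#' @param cutoff Neighbour cutoff in Angstrom (> 0). Default 1.0.
#' @return Object of class `cluster_result`: list with `labels` (cluster id
#'   per conformer, 1 = most populated), `clusters` tibble (`cluster`,
#'   `centroid`, `size`, `population`) and `cutoff`.
#' @export
gromos_cluster <- function(rmsd_matrix, cutoff = 1.0) {
  if (!is.numeric(cutoff) || cutoff <= 0) abort("cutoff must be positive")
  m <- as.matrix(rmsd_matrix)
  n <- nrow(m)
  adj <- m <= cutoff
  diag(adj) <- FALSE
  alive <- rep(TRUE, n)
  labels <- integer(n)
  centroids <- integer(0)
  k <- 0L
  while (any(alive)) {
    counts <- rowSums(adj[, alive, drop = FALSE])
    counts[!alive] <- -1L
    centre <- which.max(counts)          # ties -> lowest index
    members <- which(alive & (adj[centre, ] | seq_len(n) == centre))
    k <- k + 1L
    labels[members] <- k
    centroids[k] <- centre
    alive[members] <- FALSE
  }
  sizes <- tabulate(labels, nbins = k)
  ord <- order(-sizes, centroids)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  structure(list(labels = relabel[labels],
                 clusters = tibble(cluster = seq_len(k),
                                   centroid = centroids[ord],
                                   size = sizes[ord],
                                   population = sizes[ord] / n),
                 cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters at %.2f A; largest %.1f%%\n",
              nrow(x$clusters), x$cutoff, 100 * x$clusters$population[1]))
  invisible(x)
}

#' Tidy a clustering result
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return The per-cluster tibble (`cluster`, `centroid`, `size`,
#'   `population`).
#' @exportS3Method generics::tidy
tidy.cluster_result <- function(x, ...) x$clusters

#' One-row summary of a clustering result
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return Tibble with `n_clusters`, `n_conformers`, `largest_population`,
#'   `cutoff`.
#' @exportS3Method generics::glance
glance.cluster_result <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         n_conformers = sum(x$clusters$size),
         largest_population = x$clusters$population[1],
         cutoff = x$cutoff)
}

#' Per-residue substrate contact frequencies
#'
#' For every protein residue, the fraction of considered frames in which any
#' atom of the residue lies within `cutoff` of any atom of any substrate
#' copy (minimum image). Persistent near-1 frequencies identify residues
#' that hold the substrate (pocket-entrance gatekeepers, in-pocket traps).
#'
#' @param replicates A [replicate_set()].
#' @param cutoff Contact cutoff in Angstrom (> 0). Default 4 (all-atom).
#' @param frames Optional frame filter: an integer vector of frame indices
#'   (applied to every replicate) or a data frame with columns `replicate`
#'   and `frame` selecting per-replicate frames; default all frames.
#' @param substrates Optional integer vector restricting which substrate
#'   copies are considered; default all.
#' @return Tibble of class `contact_profile`: `chain`, `resnum`, `resname`,
#'   `frequency` (in [0, 1]), sorted by decreasing frequency; attribute
#'   `cutoff`.
#' @export
contact_frequency <- function(replicates, cutoff = 4, frames = NULL,
                              substrates = NULL) {
  if (!is.numeric(cutoff) || cutoff <= 0) abort("cutoff must be positive")
  top <- replicates$trajectories[[1]]$topology
  a <- top$atoms
  prot <- top$protein
  res_key <- paste(a$chain_id[prot], a$residue_number[prot],
                   a$residue_name[prot], sep = "\r")
  res_groups <- split(prot, factor(res_key, levels = unique(res_key)))
  subs <- top$substrates[substrates %||% seq_along(top$substrates)]
  sub_idx <- unlist(subs)
  if (!length(sub_idx)) abort("no substrate atoms selected")
  hit <- numeric(length(res_groups))
  total <- 0L
  cut2 <- cutoff^2
  by_rep <- is.data.frame(frames)
  if (!by_rep && !is.null(frames) && !length(frames)) {
    abort("empty frame filter")
  }
  for (r in seq_along(replicates$trajectories)) {
    traj <- replicates$trajectories[[r]]
    fr <- if (by_rep) {
      unique(frames$frame[frames$replicate == r])
    } else {
      frames %||% seq_len(n_frames(traj))
    }
    if (by_rep && !length(fr)) next
    for (f in fr) {
      xyz <- traj$coords[, , f, drop = TRUE]
      box <- traj$box[[f]]
      # per protein atom: squared minimum-image distance to nearest
      # substrate atom
      pmat <- xyz[prot, , drop = FALSE]
      dmin <- rep(Inf, length(prot))
      for (s in sub_idx) {
        d2 <- rowSums(.mi_disp(pmat, xyz[s, ], box)^2)
        dmin <- pmin(dmin, d2)
      }
      names(dmin) <- NULL
      in_contact <- dmin <= cut2
      per_res <- vapply(res_groups, function(idx) {
        any(in_contact[match(idx, prot)])
      }, TRUE)
      hit <- hit + per_res
      total <- total + 1L
    }
  }
  if (total == 0L) abort("empty frame filter")
  first <- vapply(res_groups, function(idx) idx[1], 1L)
  out <- tibble(chain = a$chain_id[first],
                resnum = a$residue_number[first],
                resname = a$residue_name[first],
                frequency = unname(hit / total)) |>
    arrange(desc(.data$frequency), .data$resnum)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_profile", class(out))
  out
}

#' Plot a contact-frequency profile
#' @param object A `contact_profile`.
#' @param top_n Number of highest-frequency residues to show (default 20).
#' @param ... Unused.
#' @return A ggplot bar chart of contact frequency per residue.
#' @exportS3Method ggplot2::autoplot
autoplot.contact_profile <- function(object, top_n = 20, ...) {
  df <- utils::head(as_tibble(object), top_n)
  df$label <- sprintf("%s%d%s", df$chain, df$resnum, df$resname)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label,
                                                      .data$frequency),
                                   y = .data$frequency)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "contact frequency") +
    ggplot2::theme_minimal()
}

#' Write cluster centroid conformers as a multi-model PDB
#'
#' @param set The superposed [extract_conformers()] set the clustering was
#'   computed on.
#' @param result The matching [gromos_cluster()] result.
#' @param topology The source [topology()] (supplies substrate atom names).
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_centroids_pdb <- function(set, result, topology, path) {
  sub1 <- topology$substrates[[1]]
  a <- topology$atoms[sub1, ]
  cen <- result$clusters$centroid
  arr <- aperm(set$sub_coords[cen, , , drop = FALSE], c(2, 3, 1))
  top <- topology(a[, c("atom_name", "residue_name", "residue_number",
                        "chain_id", "element", "mass")],
                  protein = seq_len(nrow(a)))
  write_pdb(trajectory(top, arr), path)
}
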
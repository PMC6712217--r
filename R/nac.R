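#' Specify the atoms defining the near-attack-conformation distances
#'
#' The composite reaction coordinate is built from four catalytic distances:
#' d1 between the catalytic serine hydroxyl oxygen and the substrate carbonyl
#' carbon, and d2--d4 between three oxyanion-hole donor atoms and the
#' substrate carbonyl oxygen. Donor atoms are given as explicit atom indices
#' so that active-site mutants are handled purely by configuration; the two
#' substrate atoms are given as atom names resolved within each substrate
#' copy (the same name may be used for both in single-site models).
#'
#' @param ser_hydroxyl_o Atom index of the catalytic serine hydroxyl oxygen.
#' @param substrate_carbonyl_c Atom name of the substrate carbonyl carbon.
#' @param substrate_carbonyl_o Atom name of the substrate carbonyl oxygen.
#' @param donor_d2,donor_d3,donor_d4 Atom indices of the oxyanion-hole donor
#'   atoms paired with the carbonyl oxygen.
#' @return An object of class `nac_spec`.
#' @export
nac_spec <- function(ser_hydroxyl_o, substrate_carbonyl_c,
                     substrate_carbonyl_o, donor_d2, donor_d3, donor_d4) {
  idx <- c(ser_hydroxyl_o, donor_d2, donor_d3, donor_d4)
  if (any(!is.finite(idx)) || any(idx < 1)) {
    abort("nac_spec atom indices must be positive integers")
  }
  structure(list(ser_hydroxyl_o = as.integer(ser_hydroxyl_o),
                 substrate_carbonyl_c = as.character(substrate_carbonyl_c),
                 substrate_carbonyl_o = as.character(substrate_carbonyl_o),
                 donors = as.integer(c(donor_d2, donor_d3, donor_d4))),
            class = "nac_spec")
}

#' @export
print.nac_spec <- function(x, ...) {
  cat(sprintf(
    "<nac_spec> serO atom %d -> substrate %s; donors %s -> substrate %s\n",
    x$ser_hydroxyl_o, x$substrate_carbonyl_c,
    paste(x$donors, collapse = "/"), x$substrate_carbonyl_o))
  invisible(x)
}

.check_spec_atoms <- function(spec, top) {
  n <- n_atoms(top)
  idx <- c(spec$ser_hydroxyl_o, spec$donors)
  if (any(idx > n)) abort("nac_spec atom index out of range for this topology")
  if (!length(top$substrates)) abort("topology has no substrate copies")
  nm <- top$atoms$atom_name
  for (s in seq_along(top$substrates)) {
    sub <- top$substrates[[s]]
    for (target in unique(c(spec$substrate_carbonyl_c,
                            spec$substrate_carbonyl_o))) {
      if (!any(nm[sub] == target)) {
        abort(sprintf("substrate copy %d has no atom named '%s'", s, target))
      }
    }
  }
  invisible(TRUE)
}

#' Composite near-attack distance from four catalytic distances
#'
#' `d_NAC = sqrt((d1^2 + d2^2 + min(d3, d4)^2) / 3)`: the root mean square of
#' the serine-to-carbonyl-carbon distance, one oxyanion distance, and the
#' smaller of the two remaining oxyanion distances. Vectorised over frames.
#'
#' @param d1,d2,d3,d4 Catalytic distances in Angstrom (all > 0).
#' @return d_NAC in Angstrom.
#' @export
compute_dnac <- function(d1, d2, d3, d4) {
  if (any(c(d1, d2, d3, d4) <= 0) || any(!is.finite(c(d1, d2, d3, d4)))) {
    abort("all four catalytic distances must be positive and finite")
  }
  sqrt((d1^2 + d2^2 + pmin(d3, d4)^2) / 3)
}

# d_NAC for all frames of one trajectory and one substrate copy.
.dnac_one <- function(traj, spec, sub_idx) {
  top <- traj$topology
  nm <- top$atoms$atom_name
  c_idx <- sub_idx[nm[sub_idx] == spec$substrate_carbonyl_c][1]
  o_idx <- sub_idx[nm[sub_idx] == spec$substrate_carbonyl_o][1]
  nf <- n_frames(traj)
  box1 <- traj$box[[1]]
  shared_box <- all(vapply(traj$box, identical, TRUE, y = box1))
  dist_t <- function(i, j) {
    if (shared_box) {
      # vectorised over frames: coords[i, , ] is 3 x nf, recycling of the
      # length-3 box over rows applies the minimum image per dimension
      d <- matrix(traj$coords[i, , ] - traj$coords[j, , ], nrow = 3L)
      if (box1$periodic) {
        L <- box1$lengths
        d <- d - L * round(d / L)
      }
      return(sqrt(colSums(d^2)))
    }
    vapply(seq_len(nf), function(f) {
      minimum_image_distance(traj$coords[i, , f], traj$coords[j, , f],
                             traj$box[[f]])
    }, 1.0)
  }
  d1 <- dist_t(spec$ser_hydroxyl_o, c_idx)
  d2 <- dist_t(spec$donors[1], o_idx)
  d3 <- dist_t(spec$donors[2], o_idx)
  d4 <- dist_t(spec$donors[3], o_idx)
  compute_dnac(d1, d2, d3, d4)
}

#' d_NAC time series for a replicate set
#'
#' Computes the composite near-attack distance for every frame and every
#' substrate copy of every replicate, under the minimum-image convention.
#'
#' @param replicates A [replicate_set()].
#' @param spec A [nac_spec()].
#' @return A tibble with columns `replicate`, `frame`, `time_ps`,
#'   `substrate`, `dnac` (Angstrom), of class `dnac_series`. The frame
#'   interval is carried in attribute `frame_interval`.
#' @export
dnac_series <- function(replicates, spec) {
  stopifnot(inherits(replicates, "replicate_set"), inherits(spec, "nac_spec"))
  .check_spec_atoms(spec, replicates$trajectories[[1]]$topology)
  res <- purrr::imap(replicates$trajectories, function(traj, r) {
    nf <- n_frames(traj)
    ns <- length(traj$topology$substrates)
    vals <- matrix(vapply(traj$topology$substrates,
                          function(sub_idx) .dnac_one(traj, spec, sub_idx),
                          numeric(nf)),
                   nrow = nf)
    tibble(replicate = as.integer(r),
           frame = rep(seq_len(nf), times = ns),
           time_ps = rep((seq_len(nf) - 1) * traj$frame_interval, times = ns),
           substrate = rep(seq_len(ns), each = nf),
           dnac = as.vector(vals))
  }) |> purrr::list_rbind()
  res <- arrange(res, .data$replicate, .data$frame, .data$substrate)
  attr(res, "frame_interval") <- replicates$trajectories[[1]]$frame_interval
  attr(res, "discarded") <- tibble(replicate = integer(), range = numeric(),
                                   reason = character())
  class(res) <- c("dnac_series", class(res))
  res
}

#' Replicates discarded from a d_NAC series
#' @param series A `dnac_series`.
#' @return Tibble of discarded replicates with observed ranges and reasons.
#' @export
discarded_replicates <- function(series) {
  attr(series, "discarded") %||%
    tibble(replicate = integer(), range = numeric(), reason = character())
}

#' Discard kinetically trapped replicates
#'
#' A replicate whose d_NAC never deviates from its starting value indicates a
#' substrate kinetically trapped in its initial conformation; such replicates
#' are excluded from all downstream statistics. A replicate is kept if, for
#' at least one tracked substrate copy, the observed d_NAC range
#' (max - min) reaches `min_range`.
#'
#' @param series A [dnac_series()] tibble.
#' @param min_range Minimal d_NAC range (Angstrom) a mobile replicate must
#'   span. Default 1.0 A, far below the 2.2--13 A span typical of mobile
#'   bound-substrate runs.
#' @return The series restricted to retained replicates; discarded replicates
#'   (with observed ranges) are available via [discarded_replicates()].
#' @export
discard_trapped_replicates <- function(series, min_range = 1.0) {
  if (!is.numeric(min_range) || min_range <= 0) {
    abort("min_range must be positive")
  }
  rng <- series |>
    group_by(.data$replicate, .data$substrate) |>
    summarise(range = max(.data$dnac) - min(.data$dnac), .groups = "drop") |>
    group_by(.data$replicate) |>
    summarise(range = max(.data$range), .groups = "drop")
  bad <- filter(rng, .data$range < min_range)
  if (nrow(bad) == nrow(rng)) {
    abort("no usable replicates: all are kinetically trapped")
  }
  out <- filter(series, !(.data$replicate %in% bad$replicate))
  prev <- discarded_replicates(series)
  attr(out, "frame_interval") <- attr(series, "frame_interval")
  attr(out, "discarded") <- bind_rows(
    prev,
    tibble(replicate = bad$replicate, range = bad$range,
           reason = sprintf("kinetic trapping: d_NAC range %.3g A < %.3g A",
                            bad$range, min_range)))
  class(out) <- unique(c("dnac_series", class(out)))
  out
}
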
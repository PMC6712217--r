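#' Sampling bookkeeping for a simulation protocol
#'
#' Frame and total-time arithmetic implied by a saved-frame interval and a
#' per-replicate production length: frames per run, total frames, and total
#' simulated time per condition.
#'
#' @param production_ns Production length per replicate (ns).
#' @param frame_interval_ps Interval between saved frames (ps).
#' @param n_replicates Replicates per condition.
#' @param n_conditions Number of conditions (e.g. concentrations) sharing
#'   the protocol.
#' @return One-row tibble: `frames_per_run`, `frames_per_condition`,
#'   `total_us_per_condition`, `total_us`.
#' @export
sampling_plan <- function(production_ns, frame_interval_ps = 1,
                          n_replicates = 5, n_conditions = 1) {
  if (production_ns <= 0 || frame_interval_ps <= 0) {
    abort("durations must be positive")
  }
  fpr <- production_ns * 1000 / frame_interval_ps
  tibble(frames_per_run = fpr,
         frames_per_condition = fpr * n_replicates,
         total_us_per_condition = production_ns * n_replicates / 1000,
         total_us = production_ns * n_replicates * n_conditions / 1000)
}

#' Configuration for a pipeline run
#'
#' Bundles every analysis parameter of the two tracks; all defaults that
#' fill an unreported choice are echoed into the run manifest so that a run
#' is fully re-derivable from its outputs.
#'
#' @param track `"access"` (multi-concentration profiles + Langmuir) or
#'   `"complex"` (in-pocket profile + pose clustering).
#' @param nac A [nac_spec()].
#' @param variant System label.
#' @param bin_width Histogram bin width (Angstrom).
#' @param calibration_min Far-field calibration lower edge (Angstrom).
#' @param d_max Histogram upper edge (Angstrom; `NULL` = data-driven).
#' @param min_range Kinetic-trapping discard threshold (Angstrom).
#' @param criterion A [binding_criterion()].
#' @param equilibration_ps Equilibration trim per replicate (ps).
#' @param cluster_window d_NAC window (Angstrom) for conformer extraction.
#' @param cluster_cutoff gromos RMSD cutoff (Angstrom).
#' @param contact_cutoff Contact cutoff (Angstrom).
#' @param productive_window,trap_window d_NAC windows (Angstrom) whose
#'   contact profiles characterise the productive pose and the in-pocket
#'   trap.
#' @param use_fitted_bulk If `TRUE` (default) the concentrations entering
#'   the Langmuir fit are the equilibrated bulk concentrations fitted from
#'   each profile's far field; if `FALSE`, the nominal concentration labels
#'   of the replicate sets are used.
#' @param seed Seed for any resampling step.
#' @return A `run_config` list.
#' @export
run_config <- function(track = c("access", "complex"),
                       nac,
                       variant = "",
                       bin_width = 1,
                       calibration_min = 60,
                       d_max = NULL,
                       min_range = 1.0,
                       criterion = binding_criterion(),
                       equilibration_ps = 0,
                       cluster_window = c(18, 20),
                       cluster_cutoff = 1.0,
                       contact_cutoff = 4.0,
                       productive_window = c(2.5, 4.5),
                       trap_window = c(8.5, 10.5),
                       use_fitted_bulk = TRUE,
                       seed = 1) {
  track <- match.arg(track)
  stopifnot(inherits(nac, "nac_spec"), inherits(criterion,
                                                "binding_criterion"))
  structure(list(track = track, nac = nac, variant = variant,
                 bin_width = bin_width, calibration_min = calibration_min,
                 d_max = d_max, min_range = min_range, criterion = criterion,
                 equilibration_ps = equilibration_ps,
                 cluster_window = cluster_window,
                 cluster_cutoff = cluster_cutoff,
                 contact_cutoff = contact_cutoff,
                 productive_window = productive_window,
                 trap_window = trap_window,
                 use_fitted_bulk = isTRUE(use_fitted_bulk), seed = seed),
            class = "run_config")
}

.config_manifest <- function(config) {
  list(track = config$track, variant = config$variant,
       nac = unclass(config$nac),
       bin_width = config$bin_width,
       calibration_min = config$calibration_min,
       d_max = config$d_max, min_range = config$min_range,
       binding_criterion = unclass(config$criterion),
       equilibration_ps = config$equilibration_ps,
       cluster_window = config$cluster_window,
       cluster_cutoff = config$cluster_cutoff,
       contact_cutoff = config$contact_cutoff,
       productive_window = config$productive_window,
       trap_window = config$trap_window,
       use_fitted_bulk = config$use_fitted_bulk,
       seed = config$seed,
       package_version = as.character(utils::packageVersion("subaccess")))
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

.with_stage <- function(stage, cleanup_dir, expr) {
  tryCatch(expr, error = function(e) {
    unlink(list.files(cleanup_dir, full.names = TRUE))
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the substrate-access analysis track
#'
#' For each concentration's replicate set: d_NAC series, trapping discards,
#' histogramming, far-field bulk-concentration fit and free energy profile;
#' then surface-bound counting, replicate averaging and (given >= 2
#' concentrations) the Langmuir fit across concentrations; finally a
#' gatekeeper contact profile for the configured window. Outputs are
#' written as CSV/JSON next to a manifest of every parameter, discarded
#' replicate and fitted bulk concentration; on failure partial outputs are
#' removed.
#'
#' @param replicate_sets List of [replicate_set()] objects, one per
#'   concentration.
#' @param config A [run_config()] with `track = "access"`.
#' @param ser_o Serine hydroxyl oxygen atom index (anchor for the binding
#'   criterion); defaults to the `nac_spec` anchor.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @return List with `profiles` (per-concentration `fe_profile`),
#'   `occupancy` (per-concentration tibble), `langmuir`
#'   (`langmuir_fit` or `NULL`), `contacts` (`contact_profile`),
#'   `manifest`.
#' @export
run_access_track <- function(replicate_sets, config, ser_o = NULL,
                             out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (config$track != "access") abort("config$track must be 'access'")
  if (inherits(replicate_sets, "replicate_set")) {
    replicate_sets <- list(replicate_sets)
  }
  ser_o <- ser_o %||% config$nac$ser_hydroxyl_o
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  cleanup <- out_dir %||% tempfile()
  manifest <- .config_manifest(config)
  profiles <- list(); occ <- list(); discards <- list()
  for (i in seq_along(replicate_sets)) {
    rs <- replicate_sets[[i]]
    lab <- format(rs$concentration)
    series <- .with_stage(paste0("dnac[", lab, "]"), cleanup,
                          dnac_series(rs, config$nac))
    series <- .with_stage(paste0("discard[", lab, "]"), cleanup,
                          discard_trapped_replicates(series,
                                                     config$min_range))
    discards[[lab]] <- discarded_replicates(series)
    counts <- .with_stage(paste0("bin[", lab, "]"), cleanup,
                          bin_dnac_counts(series, config$bin_width,
                                          config$d_max))
    prof <- .with_stage(paste0("profile[", lab, "]"), cleanup,
                        free_energy_profile(counts,
                                            calibration_min =
                                              config$calibration_min))
    profiles[[lab]] <- prof
    bound <- .with_stage(paste0("bound[", lab, "]"), cleanup,
                         count_bound(rs, ser_o, config$criterion,
                                     config$equilibration_ps))
    occ[[lab]] <- mean_occupancy(
      bound,
      concentration = if (config$use_fitted_bulk) attr(prof, "bulk_mM")
                      else rs$concentration)
  }
  occ_tbl <- purrr::list_rbind(occ)
  lang <- NULL
  if (length(replicate_sets) >= 2) {
    lang <- .with_stage("langmuir", cleanup,
                        fit_langmuir(occ_tbl,
                                     require_concs =
                                       min(3L, nrow(occ_tbl))))
  } else {
    warn("single concentration: Langmuir stage skipped")
  }
  contacts <- .with_stage("contacts", cleanup,
                          contact_frequency(replicate_sets[[1]],
                                            cutoff = config$contact_cutoff))
  manifest$discarded_replicates <- purrr::imap(discards, function(d, lab) {
    list(concentration = lab, replicates = d$replicate, ranges = d$range)
  })
  manifest$fitted_bulk_mM <- vapply(profiles, attr, 1.0, "bulk_mM")
  if (!is.null(out_dir)) {
    for (lab in names(profiles)) {
      write_csv_units(
        as_tibble(profiles[[lab]]),
        file.path(out_dir, paste0("profile_", gsub("\\s", "", lab), ".csv")),
        comment = c("free energy profile",
                    "bin_lo,bin_hi: A; count,reference_count: molecules;",
                    "dG_kT: kT",
                    sprintf("fitted bulk concentration: %.6g mM",
                            attr(profiles[[lab]], "bulk_mM"))))
    }
    if (!is.null(lang)) {
      jsonlite::write_json(
        list(K_mM = lang$K_mM, K_se = lang$K_se, bmax = lang$bmax,
             bmax_se = lang$bmax_se, occupancy = occ_tbl),
        file.path(out_dir, "langmuir.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    write_csv_units(as_tibble(contacts), file.path(out_dir, "contacts.csv"),
                    comment = c("per-residue substrate contact frequency",
                                sprintf("cutoff: %g A",
                                        config$contact_cutoff)))
    .write_manifest(manifest, out_dir)
  }
  list(profiles = profiles, occupancy = occ_tbl, langmuir = lang,
       contacts = contacts, manifest = manifest)
}

#' Run the enzyme-substrate-complex analysis track
#'
#' For replicates carrying exactly one substrate copy: d_NAC series,
#' trapping discards, pooled relative free energy profile (no bulk
#' reference: the substrate never leaves the pocket, so only relative bin
#' populations are meaningful and the profile is shifted to a 0 kT
#' minimum), gromos clustering of conformers in the configured window, and
#' contact profiles for the productive-pose and trap windows.
#'
#' @param replicates A [replicate_set()] whose trajectories contain exactly
#'   one substrate copy.
#' @param config A [run_config()] with `track = "complex"`.
#' @param out_dir Output directory or `NULL`.
#' @return List with `profile` (relative `fe_profile`), `series`,
#'   `clusters` (`cluster_result` or `NULL` if the window is empty),
#'   `conformers`, `contacts` (named list for the productive and trap
#'   windows), `manifest`.
#' @export
run_complex_track <- function(replicates, config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (config$track != "complex") abort("config$track must be 'complex'")
  ns <- length(replicates$trajectories[[1]]$topology$substrates)
  if (ns != 1L) {
    abort(sprintf("complex track requires exactly 1 substrate copy, got %d",
                  ns))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  cleanup <- out_dir %||% tempfile()
  manifest <- .config_manifest(config)
  series <- .with_stage("dnac", cleanup, dnac_series(replicates, config$nac))
  series <- .with_stage("discard", cleanup,
                        discard_trapped_replicates(series, config$min_range))
  manifest$discarded_replicates <- as.list(discarded_replicates(series))
  counts <- .with_stage("bin", cleanup,
                        bin_dnac_counts(series, config$bin_width,
                                        config$d_max))
  prof <- .with_stage("profile", cleanup, relative_free_energy_profile(counts))
  kept <- sort(unique(series$replicate))
  kept_set <- replicate_set(replicates$trajectories[kept],
                            concentration = replicates$concentration,
                            variant = replicates$variant)
  kept_series <- mutate(series, replicate = match(.data$replicate, kept))
  confs <- .with_stage("conformers", cleanup,
                       extract_conformers(kept_set, kept_series,
                                          config$cluster_window))
  clusters <- NULL
  if (n_conformers(confs) >= 2) {
    # fewer than 3 fit atoms (e.g. a fixed single-site receptor) means the
    # frames already share a rigid frame; superposition is then skipped
    if (length(confs$fit_indices) >= 3L) {
      confs <- .with_stage("superpose", cleanup, superpose_conformers(confs))
    }
    clusters <- .with_stage("cluster", cleanup,
                            gromos_cluster(pairwise_rmsd(confs),
                                           config$cluster_cutoff))
  }
  win_frames <- function(window) {
    filter(kept_series, .data$dnac > window[1], .data$dnac < window[2])
  }
  contacts <- list()
  for (w in c("productive", "trap")) {
    window <- config[[paste0(w, "_window")]]
    fr <- win_frames(window)
    contacts[[w]] <- if (nrow(fr)) {
      contact_frequency(kept_set, cutoff = config$contact_cutoff,
                        frames = fr[, c("replicate", "frame")])
    } else NULL
  }
  if (!is.null(out_dir)) {
    write_csv_units(as_tibble(prof), file.path(out_dir, "profile.csv"),
                    comment = c("relative in-pocket free energy profile",
                                "bin_lo,bin_hi: A; dG_kT: kT (min = 0)"))
    if (!is.null(clusters)) {
      jsonlite::write_json(
        list(cutoff = clusters$cutoff, window = config$cluster_window,
             clusters = clusters$clusters),
        file.path(out_dir, "clusters.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      write_centroids_pdb(confs, clusters,
                          replicates$trajectories[[1]]$topology,
                          file.path(out_dir, "centroids.pdb"))
    }
    for (w in names(contacts)) {
      if (!is.null(contacts[[w]])) {
        write_csv_units(as_tibble(contacts[[w]]),
                        file.path(out_dir, paste0("contacts_", w, ".csv")),
                        comment = sprintf("window (%g, %g) A; cutoff %g A",
                                          config[[paste0(w, "_window")]][1],
                                          config[[paste0(w, "_window")]][2],
                                          config$contact_cutoff))
      }
    }
    .write_manifest(manifest, out_dir)
  }
  list(profile = prof, series = series, clusters = clusters,
       conformers = confs, contacts = contacts, manifest = manifest)
}
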
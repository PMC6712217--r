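#' Read and validate a pipeline run configuration from YAML
#'
#' The YAML schema mirrors [run_config()] plus an `inputs` section listing
#' the systems to load. Every referenced file is checked for existence
#' before anything is computed (pre-flight), so a broken path fails fast.
#'
#' ```yaml
#' track: access            # or complex
#' variant: WT
#' substrate_resname: CPC
#' nac:
#'   ser_hydroxyl_o: 1      # atom indices, 1-based
#'   substrate_carbonyl_c: C8
#'   substrate_carbonyl_o: O9
#'   donor_d2: 10
#'   donor_d3: 11
#'   donor_d4: 12
#' bin_width: 1.0
#' calibration_min: 60
#' min_range: 1.0
#' equilibration_ps: 0
#' inputs:
#'   - concentration: 25    # mM (one block per concentration)
#'     structure: sys.pdb
#'     trajectories: [rep1.dcd, rep2.dcd]
#' ```
#'
#' @param path YAML file path.
#' @return List with `config` (a [run_config()]), `substrate_resname` and
#'   `inputs` (list of `concentration`/`structure`/`trajectories` blocks).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  for (field in c("track", "nac", "inputs")) {
    if (is.null(y[[field]])) abort(paste0("config missing field: ", field))
  }
  nac <- do.call(nac_spec, y$nac)
  base <- dirname(path)
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base, p)
  }
  inputs <- lapply(y$inputs, function(inp) {
    if (is.null(inp$structure) || is.null(inp$trajectories)) {
      abort("each input block needs 'structure' and 'trajectories'")
    }
    inp$structure <- resolve(inp$structure)
    inp$trajectories <- vapply(inp$trajectories, resolve, "")
    for (f in c(inp$structure, inp$trajectories)) {
      if (!file.exists(f)) abort(paste0("input file not found: ", f))
    }
    inp$concentration <- inp$concentration %||% NA_real_
    inp
  })
  take <- function(nm, default) y[[nm]] %||% default
  crit <- binding_criterion(
    site_radius = take("site_radius", 25),
    contact_radius = take("contact_radius", 5),
    heavy_only = take("heavy_atoms_only", FALSE),
    static_site = take("static_site", FALSE))
  config <- run_config(
    track = y$track, nac = nac, variant = take("variant", ""),
    bin_width = take("bin_width", 1),
    calibration_min = take("calibration_min", 60),
    d_max = y$d_max, min_range = take("min_range", 1.0),
    criterion = crit,
    equilibration_ps = take("equilibration_ps", 0),
    cluster_window = unlist(take("cluster_window", c(18, 20))),
    cluster_cutoff = take("cluster_cutoff", 1.0),
    contact_cutoff = take("contact_cutoff", 4.0),
    productive_window = unlist(take("productive_window", c(2.5, 4.5))),
    trap_window = unlist(take("trap_window", c(8.5, 10.5))),
    use_fitted_bulk = take("use_fitted_bulk", TRUE),
    seed = take("seed", 1))
  list(config = config,
       substrate_resname = take("substrate_resname", "SUB"),
       inputs = inputs)
}

#' Load the replicate sets referenced by a parsed configuration
#'
#' @param parsed Result of [read_run_config()].
#' @param frame_interval Frame interval (ps) for trajectory files that do
#'   not carry one.
#' @return List of [replicate_set()] objects, one per input block.
#' @export
load_run_inputs <- function(parsed, frame_interval = 1) {
  lapply(parsed$inputs, function(inp) {
    st <- read_structure(inp$structure,
                         substrate_resname = parsed$substrate_resname)
    trajs <- lapply(inp$trajectories, function(tf) {
      read_trajectory(tf, st$topology, frame_interval = frame_interval,
                      box = st$box)
    })
    replicate_set(trajs, concentration = inp$concentration,
                  variant = parsed$config$variant)
  })
}

#' Run a configured analysis track end to end
#'
#' Reads the YAML configuration ([read_run_config()]), loads every input
#' ([load_run_inputs()]) and dispatches to [run_access_track()] or
#' [run_complex_track()].
#'
#' @param path YAML config path.
#' @param out_dir Output directory (default: `outputs` next to the config).
#' @param frame_interval Frame interval (ps) for trajectory formats without
#'   time metadata.
#' @return The track result list, invisibly.
#' @export
run_from_config <- function(path, out_dir = NULL, frame_interval = 1) {
  parsed <- read_run_config(path)
  out_dir <- out_dir %||% file.path(dirname(path), "outputs")
  sets <- load_run_inputs(parsed, frame_interval)
  res <- if (parsed$config$track == "access") {
    run_access_track(sets, parsed$config, out_dir = out_dir)
  } else {
    if (length(sets) != 1L) {
      abort("complex track expects exactly one input block")
    }
    run_complex_track(sets[[1]], parsed$config, out_dir = out_dir)
  }
  invisible(res)
}
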
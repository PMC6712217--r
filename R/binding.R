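#' Geometric bound-state criterion
#'
#' A substrate copy counts as bound to the protein surface near the pocket
#' entrance when its centre of mass lies within `contact_radius` of at least
#' one protein atom that itself lies within `site_radius` of the catalytic
#' serine hydroxyl oxygen. Defaults follow the 25 A site / 5 A contact
#' convention.
#'
#' @param site_radius Radius (Angstrom) around the serine hydroxyl oxygen
#'   defining the entrance site atoms. Default 25.
#' @param contact_radius Maximum substrate-COM-to-site-atom distance
#'   (Angstrom). Default 5.
#' @param heavy_only If `TRUE`, hydrogens are excluded from the qualifying
#'   protein atoms. Default `FALSE` (all atoms).
#' @param static_site If `TRUE`, the qualifying atom set is computed once on
#'   the first frame instead of per frame.
#' @return Object of class `binding_criterion`.
#' @export
binding_criterion <- function(site_radius = 25, contact_radius = 5,
                              heavy_only = FALSE, static_site = FALSE) {
  if (site_radius <= 0 || contact_radius <= 0) {
    abort("both radii must be positive")
  }
  structure(list(site_radius = site_radius, contact_radius = contact_radius,
                 heavy_only = isTRUE(heavy_only),
                 static_site = isTRUE(static_site)),
            class = "binding_criterion")
}

.protein_pool <- function(topology, criterion) {
  pool <- topology$protein
  if (criterion$heavy_only) {
    pool <- pool[toupper(topology$atoms$element[pool]) != "H"]
  }
  if (!length(pool)) abort("empty protein selection")
  pool
}

#' Count bound substrate copies in one frame
#'
#' @param coords `n_atoms x 3` coordinate matrix (Angstrom).
#' @param topology A [topology()] with protein and substrate selections.
#' @param ser_o Atom index of the serine hydroxyl oxygen (must be a protein
#'   atom).
#' @param criterion A [binding_criterion()].
#' @param box A [sim_box()]; all distances are minimum-image.
#' @return Integer number of bound substrate copies.
#' @export
bound_count_per_frame <- function(coords, topology, ser_o,
                                  criterion = binding_criterion(),
                                  box = sim_box(periodic = FALSE)) {
  if (!(ser_o %in% topology$protein)) {
    abort("ser_o must be a protein atom index")
  }
  if (!length(topology$substrates)) abort("topology has no substrate copies")
  pool <- .protein_pool(topology, criterion)
  site <- .site_atoms(coords, topology, ser_o, criterion, box, pool)
  .count_bound_frame(coords, topology, criterion, box, site)
}

.site_atoms <- function(coords, topology, ser_o, criterion, box, pool) {
  d <- .mi_dist(coords[pool, , drop = FALSE], coords[ser_o, ], box)
  pool[d <= criterion$site_radius]
}

.count_bound_frame <- function(coords, topology, criterion, box, site) {
  if (!length(site)) return(0L)
  coms <- .substrate_coms(coords, topology, box)
  site_xyz <- coords[site, , drop = FALSE]
  sum(vapply(seq_len(nrow(coms)), function(s) {
    any(.mi_dist(site_xyz, coms[s, ], box) <= criterion$contact_radius)
  }, TRUE))
}

#' Per-frame bound-substrate counts for a replicate set
#'
#' Applies [bound_count_per_frame()] to every production frame of every
#' replicate. Frames before `equilibration_ps` are dropped.
#'
#' @param replicates A [replicate_set()].
#' @param ser_o Serine hydroxyl oxygen atom index.
#' @param criterion A [binding_criterion()].
#' @param equilibration_ps Equilibration trim (ps) removed from the start of
#'   each replicate. Default 0 (trajectories already trimmed).
#' @return Tibble with columns `replicate`, `frame`, `time_ps`, `n_bound`,
#'   `concentration_mM`.
#' @export
count_bound <- function(replicates, ser_o, criterion = binding_criterion(),
                        equilibration_ps = 0) {
  stopifnot(inherits(replicates, "replicate_set"))
  purrr::imap(replicates$trajectories, function(traj, r) {
    top <- traj$topology
    if (!(ser_o %in% top$protein)) abort("ser_o must be a protein atom index")
    pool <- .protein_pool(top, criterion)
    keep <- which((seq_len(n_frames(traj)) - 1) * traj$frame_interval >=
                    equilibration_ps)
    if (!length(keep)) abort("equilibration trim removes every frame")
    site0 <- NULL
    if (criterion$static_site) {
      f0 <- keep[1]
      site0 <- .site_atoms(traj$coords[, , f0, drop = TRUE], top, ser_o,
                           criterion, traj$box[[f0]], pool)
    }
    nb <- vapply(keep, function(f) {
      xyz <- traj$coords[, , f, drop = TRUE]
      site <- site0 %||% .site_atoms(xyz, top, ser_o, criterion,
                                     traj$box[[f]], pool)
      .count_bound_frame(xyz, top, criterion, traj$box[[f]], site)
    }, 1L)
    tibble(replicate = as.integer(r), frame = keep,
           time_ps = (keep - 1) * traj$frame_interval,
           n_bound = nb, concentration_mM = replicates$concentration)
  }) |> purrr::list_rbind()
}

#' Replicate-averaged occupancy with propagated error
#'
#' The mean number of bound substrate molecules is the unweighted mean over
#' replicates of the per-replicate time means. The standard error propagates
#' the per-replicate standard deviations `s_r` of the frame counts through
#' that average: `SE = sqrt(sum(s_r^2)) / R`.
#'
#' @param counts Tibble from [count_bound()] (one concentration), or any
#'   tibble with columns `replicate`, `n_bound` and optionally
#'   `concentration_mM`.
#' @param concentration Bulk concentration label (mM); defaults to the
#'   `concentration_mM` column.
#' @return One-row tibble: `concentration_mM`, `mean_bound`, `se_bound`,
#'   `n_replicates`, `n_frames`. With a single replicate the SE is `NA`
#'   (flagged unavailable with a message).
#' @export
mean_occupancy <- function(counts, concentration = NULL) {
  concentration <- concentration %||% counts$concentration_mM[1]
  per_rep <- counts |>
    group_by(.data$replicate) |>
    summarise(m = mean(.data$n_bound),
              s = stats::sd(.data$n_bound),
              n = dplyr::n(), .groups = "drop")
  r <- nrow(per_rep)
  se <- if (r >= 2L) sqrt(sum(per_rep$s^2)) / r else {
    message("single replicate: standard error unavailable")
    NA_real_
  }
  tibble(concentration_mM = as.numeric(concentration),
         mean_bound = mean(per_rep$m), se_bound = se,
         n_replicates = r, n_frames = sum(per_rep$n))
}

#' Fit a Langmuir binding isotherm
#'
#' Nonlinear least squares of the saturable non-cooperative binding model
#' `bound(c) = bmax * c / (K + c)` to replicate-averaged occupancies at
#' several bulk concentrations. `K` (mM) is the binding constant (the
#' half-saturation concentration) and `bmax` the saturation count. Starting
#' values are `bmax = max(mean_bound)`, `K = median(concentration)`.
#'
#' @param records Tibble with columns `concentration_mM` and `mean_bound`
#'   (e.g. rows of [mean_occupancy()]).
#' @param require_concs Minimum number of distinct concentrations (default
#'   3; the isotherm has two parameters).
#' @return Object of class `langmuir_fit`: list with `K_mM`, `K_se`, `bmax`,
#'   `bmax_se`, the underlying `nls` fit, the data, and per-concentration
#'   residuals.
#' @export
fit_langmuir <- function(records, require_concs = 3L) {
  records <- as_tibble(records)
  cs <- unique(records$concentration_mM)
  if (length(cs) < require_concs) {
    abort(sprintf("need >= %d distinct concentrations, got %d",
                  require_concs, length(cs)))
  }
  start <- list(bmax = max(records$mean_bound),
                K = stats::median(records$concentration_mM))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      mean_bound ~ bmax * concentration_mM / (K + concentration_mM),
      data = records, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(paste0("Langmuir fit did not converge: ", conditionMessage(e),
                   " (starts: bmax=", signif(start$bmax, 4),
                   ", K=", signif(start$K, 4), ")"))
    })
  est <- stats::coef(fit)
  if (any(est <= 0)) {
    abort(paste0("model inadequate: non-positive parameter at optimum (",
                 paste(sprintf("%s=%.3g", names(est), est), collapse = ", "),
                 ")"))
  }
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(K_mM = unname(est["K"]), K_se = unname(se["K"]),
                 bmax = unname(est["bmax"]), bmax_se = unname(se["bmax"]),
                 fit = fit, data = records,
                 residuals = mutate(records,
                                    fitted = stats::fitted(fit),
                                    residual = stats::resid(fit))),
            class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf("<langmuir_fit> K = %.3g +/- %.2g mM, bmax = %.3g +/- %.2g\n",
              x$K_mM, x$K_se, x$bmax, x$bmax_se))
  invisible(x)
}

#' Predicted occupancy from a Langmuir fit
#' @param object A `langmuir_fit`.
#' @param concentration Concentrations (mM) at which to evaluate the fitted
#'   isotherm; defaults to the fitted data's concentrations.
#' @param ... Unused.
#' @return Numeric predicted bound counts.
#' @export
predict.langmuir_fit <- function(object, concentration = NULL, ...) {
  concentration <- concentration %||% object$data$concentration_mM
  object$bmax * concentration / (object$K_mM + concentration)
}

#' Tidy a Langmuir fit
#' @param x A `langmuir_fit`.
#' @param conf.int If `TRUE`, add Wald confidence bounds (t quantile on the
#'   fit's residual degrees of freedom).
#' @param conf.level Confidence level (default 0.95).
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`,
#'   `std.error`, and optionally `conf.low`, `conf.high`).
#' @exportS3Method generics::tidy
tidy.langmuir_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- tibble(term = c("K", "bmax"),
                estimate = c(x$K_mM, x$bmax),
                std.error = c(x$K_se, x$bmax_se))
  if (conf.int) {
    dof <- stats::df.residual(x$fit)
    q <- stats::qt(1 - (1 - conf.level) / 2, dof)
    out <- mutate(out, conf.low = .data$estimate - q * .data$std.error,
                  conf.high = .data$estimate + q * .data$std.error)
  }
  out
}

#' One-row summary of a Langmuir fit
#' @param x A `langmuir_fit`.
#' @param ... Unused.
#' @return One-row tibble: estimates, standard errors, residual sum of
#'   squares, degrees of freedom and number of concentrations.
#' @exportS3Method generics::glance
glance.langmuir_fit <- function(x, ...) {
  tibble(K_mM = x$K_mM, K_se = x$K_se, bmax = x$bmax, bmax_se = x$bmax_se,
         sigma = summary(x$fit)$sigma,
         df.residual = stats::df.residual(x$fit),
         nobs = nrow(x$data))
}

#' Plot a Langmuir isotherm fit
#' @param object A `langmuir_fit`.
#' @param ... Unused.
#' @return A ggplot with the measured occupancies (error bars where
#'   available) and the fitted isotherm.
#' @exportS3Method ggplot2::autoplot
autoplot.langmuir_fit <- function(object, ...) {
  d <- object$data
  cmax <- max(d$concentration_mM)
  curve <- tibble(concentration_mM = seq(0, 1.1 * cmax, length.out = 200))
  curve$mean_bound <- predict(object, curve$concentration_mM)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration_mM,
                                       y = .data$mean_bound)) +
    ggplot2::geom_line(data = curve) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "bulk concentration (mM)",
                  y = "bound substrate molecules") +
    ggplot2::theme_minimal()
  if (!is.null(d[["se_bound"]]) && any(is.finite(d$se_bound))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_bound - .data$se_bound,
                   ymax = .data$mean_bound + .data$se_bound), width = 0)
  }
  p
}
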
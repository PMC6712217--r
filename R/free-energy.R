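# Conversion: c [mM] -> number density [molecules / A^3].
# 1 mM = 1 mol/m^3 = 6.022e23 / 1e30 A^3.
.MM_TO_PER_A3 <- 6.022e-7

#' Histogram a d_NAC series into fixed-width bins
#'
#' Counts molecule-frame observations per d_NAC bin. Every sampled
#' (replicate, frame, substrate) observation contributes one count, pooled
#' over replicates and substrate copies. Values at or beyond `d_max` are
#' collected in an overflow count (attribute `overflow`) and reported with a
#' message, never silently dropped.
#'
#' @param series A [dnac_series()] tibble (after any replicate discards).
#' @param bin_width Bin width in Angstrom (default 1).
#' @param d_max Upper histogram edge in Angstrom; rounded up to a multiple of
#'   `bin_width`. Defaults to covering the largest observed value.
#' @return A tibble of class `dnac_counts` with columns `bin_lo`, `bin_hi`
#'   (Angstrom) and `count`, and attributes `n_conformers` (total
#'   molecule-frame observations), `n_frames` (total retained frames summed
#'   over replicates), `bin_width` and `overflow`.
#' @export
bin_dnac_counts <- function(series, bin_width = 1, d_max = NULL) {
  if (!nrow(series)) abort("empty d_NAC series")
  if (!is.numeric(bin_width) || bin_width <= 0) {
    abort("bin_width must be positive")
  }
  d_max <- d_max %||% max(series$dnac)
  d_max <- ceiling(d_max / bin_width - 1e-9) * bin_width
  edges <- seq(0, d_max, by = bin_width)
  nb <- length(edges) - 1L
  over <- sum(series$dnac >= d_max)
  if (over > 0) {
    message(sprintf("%d observation(s) at d_NAC >= %.3g A counted as overflow",
                    over, d_max))
  }
  idx <- findInterval(series$dnac[series$dnac < d_max], edges,
                      rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = nb)
  out <- tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                count = as.integer(counts))
  attr(out, "n_conformers") <- nrow(series)
  attr(out, "n_frames") <- nrow(distinct(series, .data$replicate,
                                         .data$frame))
  attr(out, "bin_width") <- bin_width
  attr(out, "overflow") <- as.integer(over)
  class(out) <- c("dnac_counts", class(out))
  out
}

#' Expected substrate count per spherical shell in enzyme-free solution
#'
#' The reference state of the Boltzmann inversion: in an ideal solution at
#' bulk concentration `c`, the expected number of molecules whose distance
#' from the centre falls in the shell `[a_i, a_i + delta_b)` is
#' `N(i) = (4/3) * pi * ((a_i + delta_b)^3 - a_i^3) * c * N_A`, evaluated per
#' frame with `a_i` the lower bin edge.
#'
#' @param bin_lo Lower bin edges (Angstrom).
#' @param concentration Bulk concentration in mM.
#' @param delta_b Shell thickness in Angstrom (the histogram bin width).
#' @return Expected molecules per bin per frame (same length as `bin_lo`).
#' @export
shell_reference_counts <- function(bin_lo, concentration, delta_b = 1) {
  if (!is.numeric(concentration) || concentration < 0) {
    abort("concentration must be >= 0 (mM)")
  }
  (4 / 3) * pi * ((bin_lo + delta_b)^3 - bin_lo^3) *
    concentration * .MM_TO_PER_A3
}

#' Fit the equilibrated bulk concentration from far-field bins
#'
#' At large d_NAC the enzyme does not perturb the substrate distribution, so
#' the observed per-frame bin counts must equal the ideal spherical-shell
#' expectation. The single scale parameter (the bulk concentration after
#' equilibration, in mM) is obtained by unweighted linear least squares
#' through the origin of mean per-frame counts against shell volumes over
#' all bins with `bin_lo >= calibration_min`.
#'
#' @param counts A [bin_dnac_counts()] result.
#' @param calibration_min Lower edge (Angstrom) of the calibration region
#'   (default 60).
#' @return Object of class `bulk_fit`: list with `concentration_mM`, `se_mM`,
#'   `n_bins`, `calibration_min` and a `residuals` tibble (per-bin observed
#'   and fitted per-frame counts).
#' @export
fit_bulk_concentration <- function(counts, calibration_min = 60) {
  nfr <- attr(counts, "n_frames")
  bw <- attr(counts, "bin_width")
  far <- filter(counts, .data$bin_lo >= calibration_min)
  if (sum(far$count > 0) < 3L) {
    abort(paste0("fewer than 3 non-empty bins beyond the calibration ",
                 "distance; use a larger box or a smaller calibration_min"))
  }
  vol <- (4 / 3) * pi * ((far$bin_lo + bw)^3 - far$bin_lo^3)
  y <- far$count / nfr
  slope <- sum(vol * y) / sum(vol^2)             # molecules / A^3
  fitted <- slope * vol
  dof <- nrow(far) - 1L
  s2 <- sum((y - fitted)^2) / dof
  se_slope <- sqrt(s2 / sum(vol^2))
  structure(list(concentration_mM = slope / .MM_TO_PER_A3,
                 se_mM = se_slope / .MM_TO_PER_A3,
                 n_bins = nrow(far),
                 calibration_min = calibration_min,
                 residuals = tibble(bin_lo = far$bin_lo,
                                    observed = y, fitted = fitted)),
            class = "bulk_fit")
}

#' @export
print.bulk_fit <- function(x, ...) {
  cat(sprintf(
    "<bulk_fit> c = %.4g +/- %.2g mM (%d far-field bins, d >= %g A)\n",
    x$concentration_mM, x$se_mM, x$n_bins, x$calibration_min))
  invisible(x)
}

#' Concentration-referenced free energy profile by Boltzmann inversion
#'
#' For each d_NAC bin the free energy (in units of kT) is the negative log
#' ratio of the observed population to the enzyme-free spherical-shell
#' reference at the equilibrated bulk concentration:
#' `dG/kT = -ln(observed(i) / reference(i))`, both on the same per-frame
#' scale. When `concentration` is not supplied it is first fitted from the
#' far field ([fit_bulk_concentration()]), which makes the profile approach
#' zero beyond the calibration distance by construction. Bins with zero
#' observed count carry `dG = +Inf` and flag `"unsampled"`: they are data
#' (an insurmountable barrier at this sampling), not errors.
#'
#' @param counts A [bin_dnac_counts()] result.
#' @param concentration Bulk concentration in mM, or `NULL` to fit it.
#' @param calibration_min Passed to [fit_bulk_concentration()].
#' @return Tibble of class `fe_profile` with columns `bin_lo`, `bin_hi`,
#'   `count`, `reference_count` (expected counts on the same total scale as
#'   `count`), `dG_kT` and `flag`; attributes `bulk_mM`, `bulk_fit` (when
#'   fitted), `n_conformers`, `n_frames`.
#' @export
free_energy_profile <- function(counts, concentration = NULL,
                                calibration_min = 60) {
  nfr <- attr(counts, "n_frames")
  bw <- attr(counts, "bin_width")
  fit <- NULL
  if (is.null(concentration)) {
    fit <- fit_bulk_concentration(counts, calibration_min)
    concentration <- fit$concentration_mM
  }
  ref <- shell_reference_counts(counts$bin_lo, concentration, bw)
  if (any(ref <= 0 & counts$count > 0)) {
    abort("reference count is zero in a sampled bin; is the concentration 0?")
  }
  dg <- -log((counts$count / nfr) / ref)
  out <- counts |>
    mutate(reference_count = ref * nfr,
           dG_kT = dg,
           flag = ifelse(.data$count == 0, "unsampled", "ok"))
  for (a in c("n_conformers", "n_frames", "bin_width")) {
    attr(out, a) <- attr(counts, a)
  }
  attr(out, "bulk_mM") <- concentration
  attr(out, "bulk_fit") <- fit
  class(out) <- c("fe_profile", setdiff(class(out), "dnac_counts"))
  out
}

#' Relative (in-pocket) free energy profile
#'
#' For simulations of a single substrate confined to the binding pocket there
#' is no meaningful bulk reference; the profile is then the negative log of
#' the bin probability, shifted so that the global minimum is 0 kT. Such
#' profiles are comparable only within themselves, not to
#' concentration-referenced profiles.
#'
#' @param counts A [bin_dnac_counts()] result.
#' @return Tibble of class `fe_profile` with `dG_kT` relative to the most
#'   populated bin; attribute `bulk_mM` is `NA`.
#' @export
relative_free_energy_profile <- function(counts) {
  n <- attr(counts, "n_conformers")
  if (all(counts$count == 0)) abort("empty histogram")
  p <- counts$count / n
  dg <- -log(p)
  dg <- dg - min(dg[is.finite(dg)])
  out <- counts |>
    mutate(reference_count = NA_real_, dG_kT = dg,
           flag = ifelse(.data$count == 0, "unsampled", "ok"))
  for (a in c("n_conformers", "n_frames", "bin_width")) {
    attr(out, a) <- attr(counts, a)
  }
  attr(out, "bulk_mM") <- NA_real_
  attr(out, "bulk_fit") <- NULL
  class(out) <- c("fe_profile", setdiff(class(out), "dnac_counts"))
  out
}

#' Plot a free energy profile
#'
#' @param object A `fe_profile`.
#' @param ... Unused.
#' @return A ggplot of dG (kT) against d_NAC; unsampled bins are omitted.
#' @exportS3Method ggplot2::autoplot
autoplot.fe_profile <- function(object, ...) {
  df <- filter(as_tibble(object), is.finite(.data$dG_kT))
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                   y = .data$dG_kT)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = expression(d[NAC] ~ "(Å)"),
                  y = expression(Delta * G ~ "(kT)")) +
    ggplot2::theme_minimal()
}
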
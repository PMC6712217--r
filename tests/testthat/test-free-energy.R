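fake_series <- function(values) {
  structure(tibble::tibble(replicate = 1L, frame = seq_along(values),
                           time_ps = seq_along(values) - 1, substrate = 1L,
                           dnac = values),
            frame_interval = 1,
            class = c("dnac_series", class(tibble::tibble())))
}

# series with a chosen number of frames and per-frame observations
fake_series_multi <- function(values, n_sub) {
  n_fr <- length(values) / n_sub
  structure(tibble::tibble(replicate = 1L,
                           frame = rep(seq_len(n_fr), each = n_sub),
                           time_ps = 0,
                           substrate = rep(seq_len(n_sub), times = n_fr),
                           dnac = values),
            frame_interval = 1,
            class = c("dnac_series", class(tibble::tibble())))
}

test_that("bin counts place values and account for every observation", {
  ser <- fake_series(c(0.5, 1.5, 1.6))
  counts <- bin_dnac_counts(ser, bin_width = 1)
  expect_equal(counts$count[1:2], c(1L, 2L))
  expect_equal(sum(counts$count) + attr(counts, "overflow"), 3L)
  expect_equal(attr(counts, "n_conformers"), 3L)
  expect_message(bin_dnac_counts(fake_series(c(0.5, 99)), d_max = 10),
                 "overflow")
  expect_error(bin_dnac_counts(fake_series(numeric())), "empty")
})

test_that("conformer bookkeeping counts one observation per molecule-frame", {
  # 20 frames x 3 substrate copies = 60 conformers
  set.seed(1)
  ser <- fake_series_multi(runif(60, 0, 10), n_sub = 3)
  counts <- bin_dnac_counts(ser, bin_width = 1)
  expect_equal(attr(counts, "n_conformers"), 60L)
  expect_equal(attr(counts, "n_frames"), 20L)
  expect_equal(sum(counts$count), 60L)
})

test_that("shell reference counts match hand evaluation of the shell model", {
  expect_equal(shell_reference_counts(0, 50, 1),
               (4 / 3) * pi * (50 * 6.022e-7), tolerance = 1e-12)
  expect_equal(shell_reference_counts(0, 50, 1), 1.261e-4, tolerance = 1e-3)
  expect_equal(shell_reference_counts(60, 50, 1),
               (4 / 3) * pi * (61^3 - 60^3) * 3.011e-5, tolerance = 1e-12)
  expect_equal(shell_reference_counts(60, 50, 1), 1.385, tolerance = 1e-3)
  expect_equal(shell_reference_counts(c(0, 5, 60), 0), rep(0, 3))
})

test_that("shell volumes telescope to the enclosing sphere", {
  lo <- seq(0, 79, by = 1)
  total <- sum(shell_reference_counts(lo, 25, 1))
  expect_equal(total, (4 / 3) * pi * 80^3 * 25 * 6.022e-7, tolerance = 1e-12)
})

test_that("bulk-concentration fit recovers an exactly planted value", {
  lo <- seq(0, 79)
  c_true <- 25
  per_frame <- shell_reference_counts(lo, c_true, 1)
  counts <- tibble::tibble(bin_lo = lo, bin_hi = lo + 1,
                           count = as.integer(round(per_frame * 1000)))
  attr(counts, "n_frames") <- 1000L
  attr(counts, "bin_width") <- 1
  fit <- fit_bulk_concentration(counts, calibration_min = 60)
  expect_equal(fit$concentration_mM, c_true, tolerance = 1e-4)
  # empty far field -> error
  counts0 <- counts
  counts0$count[counts0$bin_lo >= 60] <- 0L
  expect_error(fit_bulk_concentration(counts0), "calibration")
})

test_that("free energy profile is a log count ratio with unsampled flags", {
  lo <- seq(0, 79)
  c_true <- 25
  nfr <- 500L
  ref <- shell_reference_counts(lo, c_true, 1)
  obs <- ref * nfr
  obs[lo == 30] <- exp(2) * obs[lo == 30]   # a -2 kT well at 30 A
  obs[lo < 18] <- 0                         # an unsampled core
  counts <- tibble::tibble(bin_lo = lo, bin_hi = lo + 1,
                           count = as.integer(round(obs)))
  attr(counts, "n_frames") <- nfr
  attr(counts, "bin_width") <- 1
  prof <- free_energy_profile(counts, concentration = c_true)
  expect_equal(prof$dG_kT[prof$bin_lo == 30], -2, tolerance = 2e-3)
  expect_equal(prof$dG_kT[prof$bin_lo == 50], 0, tolerance = 2e-3)
  expect_true(all(is.infinite(prof$dG_kT[prof$bin_lo < 18])))
  expect_true(all(prof$flag[prof$bin_lo < 18] == "unsampled"))
  # fitted-concentration route drives the far field to zero by construction
  prof2 <- free_energy_profile(counts, calibration_min = 60)
  expect_lt(max(abs(prof2$dG_kT[prof2$bin_lo >= 60])), 0.01)
})

test_that("doubling every count leaves the refitted profile unchanged", {
  set.seed(42)
  lo <- seq(0, 79)
  base <- pmax(rpois(80, shell_reference_counts(lo, 40, 1) * 200), 0)
  mk <- function(cnt, nfr) {
    counts <- tibble::tibble(bin_lo = lo, bin_hi = lo + 1,
                             count = as.integer(cnt))
    attr(counts, "n_frames") <- nfr
    attr(counts, "bin_width") <- 1
    free_energy_profile(counts, calibration_min = 60)
  }
  p1 <- mk(base, 200L)
  p2 <- mk(2L * base, 400L)
  expect_equal(p1$dG_kT, p2$dG_kT, tolerance = 1e-12)
})

test_that("relative profile normalises to a zero-kT minimum", {
  counts <- tibble::tibble(bin_lo = 0:3, bin_hi = 1:4,
                           count = c(0L, 100L, 50L, 25L))
  attr(counts, "n_conformers") <- 175L
  attr(counts, "n_frames") <- 175L
  attr(counts, "bin_width") <- 1
  prof <- relative_free_energy_profile(counts)
  expect_equal(min(prof$dG_kT[is.finite(prof$dG_kT)]), 0)
  expect_equal(prof$dG_kT[3] - prof$dG_kT[2], log(2), tolerance = 1e-12)
  expect_equal(prof$flag[1], "unsampled")
})
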
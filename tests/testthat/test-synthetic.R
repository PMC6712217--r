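test_that("radial potentials validate segments and evaluate piecewise", {
  pot <- radial_potential(data.frame(r_lo = 25, r_hi = 40, u_kt = -2),
                          r_core = 18)
  expect_equal(potential_energy(pot, c(10, 20, 30, 50)), c(Inf, 0, -2, 0))
  expect_error(radial_potential(data.frame(r_lo = 5, r_hi = 3, u_kt = 1)),
               "r_lo < r_hi")
  expect_error(radial_potential(data.frame(r_lo = c(0, 5), r_hi = c(10, 15),
                                           u_kt = c(1, 2))), "overlap")
  expect_error(radial_potential(data.frame(r_lo = 0, r_hi = 5, u_kt = Inf)),
               "finite")
})

test_that("generators are bit-reproducible and echo provenance", {
  t1 <- suppressWarnings(simulate_external_potential(
    radial_potential(), n_particles = 50, n_sweeps = 30, burn_in = 10,
    seed = 42))
  t2 <- suppressWarnings(simulate_external_potential(
    radial_potential(), n_particles = 50, n_sweeps = 30, burn_in = 10,
    seed = 42))
  expect_identical(t1$coords, t2$coords)
  expect_equal(attr(t1, "generator")$seed, 42)
  o1 <- generate_langmuir_occupancy(n_frames = 100, seed = 7)
  o2 <- generate_langmuir_occupancy(n_frames = 100, seed = 7)
  expect_identical(o1$n_bound, o2$n_bound)
  c1 <- generate_conformers(n_total = 20, seed = 5)
  c2 <- generate_conformers(n_total = 20, seed = 5)
  expect_identical(c1$sub_coords, c2$sub_coords)
})

test_that("ideal-gas MC yields a flat profile within 3 SE everywhere", {
  traj <- suppressWarnings(simulate_external_potential(
    radial_potential(), n_particles = 1500, box_length = 160,
    n_sweeps = 160, burn_in = 60, frame_stride = 4, seed = 11))
  rs <- replicate_set(list(traj), concentration = NA)
  ser <- dnac_series(rs, synthetic_nac_spec())
  counts <- bin_dnac_counts(ser, bin_width = 4, d_max = 80)
  prof <- free_energy_profile(counts, calibration_min = 40)
  sampled <- dplyr::filter(prof, count > 0, bin_lo >= 8)
  expect_true(all(abs(sampled$dG_kT) < 3 / sqrt(sampled$count)))
})

test_that("fitted bulk concentration recovers the loading concentration", {
  n <- 2000; L <- 160
  traj <- suppressWarnings(simulate_external_potential(
    radial_potential(), n_particles = n, box_length = L,
    n_sweeps = 120, burn_in = 40, frame_stride = 4, seed = 19))
  ser <- dnac_series(replicate_set(list(traj)), synthetic_nac_spec())
  counts <- bin_dnac_counts(ser, bin_width = 2, d_max = 80)
  fit <- fit_bulk_concentration(counts, calibration_min = 60)
  c_load <- n / L^3 / 6.022e-7
  expect_lt(abs(fit$concentration_mM - c_load), 3 * fit$se_mM + 0.02 * c_load)
})

test_that("hard-core potential leaves the core unsampled", {
  pot <- radial_potential(r_core = 18)
  traj <- suppressWarnings(simulate_external_potential(
    pot, n_particles = 800, n_sweeps = 80, burn_in = 30, seed = 23))
  ser <- dnac_series(replicate_set(list(traj)), synthetic_nac_spec())
  expect_gte(min(ser$dnac), 18)
})

test_that("occupancy generator honours the saturation limits", {
  K <- 7.4; n_sites <- 12
  sat <- generate_langmuir_occupancy(K_true = K, n_sites = n_sites,
                                     concentrations = 1000 * K,
                                     n_frames = 4000, n_replicates = 1,
                                     seed = 2)
  m <- mean(sat$n_bound)
  se <- sd(sat$n_bound) / sqrt(nrow(sat))
  expect_lt(abs(m - n_sites * 1000 / 1001), 3 * se + 1e-3)
  half <- generate_langmuir_occupancy(K_true = K, n_sites = n_sites,
                                      concentrations = K, n_frames = 4000,
                                      n_replicates = 1, seed = 3)
  mh <- mean(half$n_bound)
  seh <- sd(half$n_bound) / sqrt(nrow(half))
  expect_lt(abs(mh - n_sites / 2), 3 * seh)
})

test_that("planted conformer clusters are recovered after superposition", {
  # sigma = 0: all intra-cluster RMSD vanish after undoing the rigid frames
  c0 <- generate_conformers(sigma = 0, n_total = 12, seed = 9)
  c0 <- superpose_conformers(c0, reference = c0$reference)
  m0 <- pairwise_rmsd(c0)
  lab <- c0$source$true_label
  expect_lt(max(m0[lab == 1, lab == 1]), 1e-6)
  # two centres 10 A apart, sigma 0.5: cutoff 2 A recovers labels exactly
  cc <- generate_conformers(sigma = 0.5, n_total = 60, seed = 13)
  cc <- superpose_conformers(cc, reference = cc$reference)
  res <- gromos_cluster(pairwise_rmsd(cc), cutoff = 2)
  expect_true(same_partition(res$labels, cc$source$true_label))
  # k = 1 -> a single total cluster
  one <- generate_conformers(centers = list(.5 * diag(3)[, ] + 20),
                             sizes = 15, sigma = 0.2, seed = 4)
  one <- superpose_conformers(one, reference = one$reference)
  res1 <- gromos_cluster(pairwise_rmsd(one), cutoff = 2)
  expect_equal(res1$clusters$population, 1)
})

test_that("square-well MC reproduces the planted depth by Boltzmann inversion", {
  pot <- radial_potential(data.frame(r_lo = 25, r_hi = 40, u_kt = -2),
                          r_core = 18)
  traj <- suppressWarnings(simulate_external_potential(
    pot, n_particles = 2500, box_length = 160, n_sweeps = 220, burn_in = 80,
    frame_stride = 4, seed = 29))
  ser <- dnac_series(replicate_set(list(traj)), synthetic_nac_spec())
  counts <- bin_dnac_counts(ser, bin_width = 2, d_max = 80)
  prof <- free_energy_profile(counts, calibration_min = 60)
  well <- dplyr::filter(prof, bin_lo >= 26, bin_hi <= 40, count > 0)
  for (i in seq_len(nrow(well))) {
    expect_lt(abs(well$dG_kT[i] + 2), 3 / sqrt(well$count[i]) + 0.15)
  }
  expect_gte(min(ser$dnac), 18)
})
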
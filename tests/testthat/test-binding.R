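# Protein geometry: anchor OG at origin, a qualifying atom 10 A away and a
# non-qualifying atom 30 A away from the anchor.
binding_fixture <- function(sub_pos) {
  prot <- rbind(c(0, 0, 0), c(10, 0, 0), c(30, 0, 0))
  toy_system(sub_pos, prot_pos = prot)
}

test_that("bound counting follows the two-radius rule", {
  crit <- binding_criterion(site_radius = 25, contact_radius = 5)
  # substrate COM 4 A from the qualifying atom -> counted
  t1 <- binding_fixture(rbind(c(14, 0, 0)))
  expect_equal(bound_count_per_frame(frame_coords(t1, 1), t1$topology, 1L,
                                     crit, t1$box[[1]]), 1L)
  # 6 A from the nearest qualifying atom -> not counted
  t2 <- binding_fixture(rbind(c(16, 0, 0)))
  expect_equal(bound_count_per_frame(frame_coords(t2, 1), t2$topology, 1L,
                                     crit, t2$box[[1]]), 0L)
  # 1 A from an atom that is itself outside the 25 A site -> not counted
  t3 <- binding_fixture(rbind(c(31, 0, 0)))
  expect_equal(bound_count_per_frame(frame_coords(t3, 1), t3$topology, 1L,
                                     crit, t3$box[[1]]), 0L)
  expect_error(bound_count_per_frame(frame_coords(t3, 1), t3$topology, 99L,
                                     crit, t3$box[[1]]), "protein atom")
})

test_that("bound count is monotone in both radii", {
  set.seed(8)
  prot <- matrix(runif(30, -20, 20), 10, 3)
  sub <- matrix(runif(60, -30, 30), 20, 3)
  traj <- toy_system(sub, prot_pos = prot)
  xyz <- frame_coords(traj, 1)
  base <- bound_count_per_frame(xyz, traj$topology, 1L,
                                binding_criterion(15, 4), traj$box[[1]])
  for (crit2 in list(binding_criterion(20, 4), binding_criterion(15, 7),
                     binding_criterion(25, 8))) {
    expect_gte(bound_count_per_frame(xyz, traj$topology, 1L, crit2,
                                     traj$box[[1]]), base)
  }
})

test_that("replicate averaging propagates per-run scatter", {
  mk <- function(vals) tibble::tibble(replicate = rep(1:2, each = length(vals) / 2),
                                      n_bound = vals, concentration_mM = 10)
  # replicate means 3 and 5 with zero within-run scatter
  occ <- mean_occupancy(mk(c(3, 3, 5, 5)))
  expect_equal(occ$mean_bound, 4)
  expect_equal(occ$se_bound, 0)
  # two replicates with per-run SD 2 -> SE = sqrt(8)/2
  v1 <- c(2, 4, 6) - 4 + 10     # sd 2, mean 10
  v2 <- c(8, 10, 12)            # sd 2, mean 10
  occ2 <- mean_occupancy(tibble::tibble(
    replicate = rep(1:2, each = 3), n_bound = c(v1, v2),
    concentration_mM = 10))
  expect_equal(occ2$se_bound, sqrt(8) / 2, tolerance = 1e-12)
  # identical replicates -> SE 0, mean = replicate mean
  occ3 <- mean_occupancy(mk(c(3, 3, 3, 3)))
  expect_equal(occ3$mean_bound, 3)
  expect_equal(occ3$se_bound, 0)
  # replicate order does not matter
  sw <- tibble::tibble(replicate = rep(2:1, each = 3), n_bound = c(v1, v2),
                       concentration_mM = 10)
  expect_equal(mean_occupancy(sw)$se_bound, occ2$se_bound)
  expect_message(m1 <- mean_occupancy(tibble::tibble(
    replicate = 1L, n_bound = c(1, 2), concentration_mM = 3)), "single")
  expect_true(is.na(m1$se_bound))
})

test_that("Langmuir fit recovers exactly planted parameters", {
  K <- 7.4; bmax <- 12
  cs <- c(3, 5, 25, 50)
  rec <- tibble::tibble(concentration_mM = cs,
                        mean_bound = bmax * cs / (K + cs))
  fit <- fit_langmuir(rec)
  expect_equal(fit$K_mM, K, tolerance = 1e-6)
  expect_equal(fit$bmax, bmax, tolerance = 1e-6)
  # half-saturation identity: the fitted curve at c = K gives bmax/2
  expect_equal(predict(fit, fit$K_mM), fit$bmax / 2, tolerance = 1e-9)
  # saturation limit
  expect_equal(predict(fit, 1e9), bmax, tolerance = 1e-4)
})

test_that("Langmuir fit recovers any positive pair from exact data", {
  set.seed(21)
  for (i in 1:10) {
    K <- runif(1, 0.5, 40); bmax <- runif(1, 1, 30)
    cs <- sort(runif(4, 0.5, 80))
    rec <- tibble::tibble(concentration_mM = cs,
                          mean_bound = bmax * cs / (K + cs))
    fit <- fit_langmuir(rec)
    expect_equal(fit$K_mM, K, tolerance = 1e-4)
    expect_equal(fit$bmax, bmax, tolerance = 1e-4)
  }
})

test_that("Langmuir fit guards its preconditions and model adequacy", {
  rec <- tibble::tibble(concentration_mM = c(3, 5),
                        mean_bound = c(1, 2))
  expect_error(fit_langmuir(rec), "distinct concentrations")
  # occupancies decreasing with concentration cannot be Langmuir
  bad <- tibble::tibble(concentration_mM = c(3, 5, 25, 50),
                        mean_bound = c(10, 8, 3, 1))
  expect_error(fit_langmuir(bad), "inadequate|converge")
})

test_that("tidy and glance expose the fit in broom shape", {
  cs <- c(3, 5, 25, 50)
  rec <- tibble::tibble(concentration_mM = cs,
                        mean_bound = 12 * cs / (7.4 + cs) +
                          c(0.05, -0.04, 0.02, -0.01))
  fit <- fit_langmuir(rec)
  td <- tidy(fit, conf.int = TRUE)
  expect_equal(td$term, c("K", "bmax"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$nobs, 4L)
  expect_s3_class(autoplot(fit), "ggplot")
})
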
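test_that("Kabsch superposition is exact on rigid copies", {
  set.seed(4)
  ref <- matrix(rnorm(15, sd = 5), 5, 3)
  sp0 <- superpose_kabsch(ref, ref)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-8)
  rot <- rotation_z(pi / 2)
  moved <- sweep(ref %*% t(rot), 2, c(12, -3, 7), "+")
  sp <- superpose_kabsch(moved, ref)
  expect_lt(sp$rmsd, 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
})

test_that("Kabsch matches a brute-force rotational search on 4-point sets", {
  set.seed(9)
  for (i in 1:5) {
    ref <- matrix(rnorm(12, sd = 3), 4, 3)
    mob <- ref
    mob[1, ] <- mob[1, ] + c(2, 0, 0)   # one point displaced by 2 A
    mob <- sweep(mob %*% t(euler_rotation(0.4, -0.2, 1.1)), 2, c(5, 5, 5),
                 "+")
    sp <- superpose_kabsch(mob, ref)
    bf <- brute_force_fit_rmsd(mob, ref)
    expect_equal(sp$rmsd, bf, tolerance = 1e-5)
    expect_lte(sp$rmsd,
               sqrt(mean(rowSums((mob - ref)^2))) + 1e-12)
  }
})

test_that("degenerate fit geometries are rejected", {
  line <- cbind(1:4, 0, 0)
  expect_error(superpose_kabsch(line, line), "degenerate|collinear")
  expect_error(superpose_kabsch(line[1:2, ], line[1:2, ]), "3 fit atoms")
})

test_that("pairwise RMSD matches the double-loop oracle", {
  set.seed(12)
  coords <- array(rnorm(5 * 6 * 3, sd = 4), c(5, 6, 3))
  m <- pairwise_rmsd(coords)
  expect_equal(m, naive_rmsd_matrix(coords), tolerance = 1e-10)
  expect_equal(diag(m), rep(0, 5))
  expect_equal(m, t(m))
  # duplicates -> zero off-diagonal; single-atom pairs -> plain distance
  dup <- array(coords[c(1, 1), , ], c(2, 6, 3))
  expect_equal(pairwise_rmsd(dup)[1, 2], 0)
  two <- array(c(0, 3, 0, 0, 0, 0), c(2, 1, 3))
  expect_equal(pairwise_rmsd(two)[1, 2], 3)
})

test_that("gromos clustering recovers planted structure and handles ties", {
  # two tight groups far apart
  set.seed(3)
  g1 <- matrix(rnorm(30, sd = 0.1), 10, 3)
  g2 <- matrix(rnorm(24, sd = 0.1), 8, 3) + 50
  coords <- array(NA_real_, c(18, 1, 3))
  coords[1:10, 1, ] <- g1
  coords[11:18, 1, ] <- g2
  m <- pairwise_rmsd(coords)
  res <- gromos_cluster(m, cutoff = 2)
  expect_equal(nrow(res$clusters), 2L)
  expect_true(same_partition(res$labels, rep(c(1, 2), c(10, 8))))
  expect_equal(res$clusters$population, c(10, 8) / 18)
  expect_equal(sum(res$clusters$population), 1)
  # all singletons
  res2 <- gromos_cluster(m, cutoff = 1e-6)
  expect_equal(nrow(res2$clusters), 18L)
  # all identical
  same <- matrix(0, 4, 4)
  res3 <- gromos_cluster(same, cutoff = 1)
  expect_equal(nrow(res3$clusters), 1L)
  expect_equal(res3$clusters$population, 1)
  expect_equal(res3$clusters$centroid, 1L)  # tie broken by lowest index
})

test_that("gromos clustering agrees with the naive oracle on small instances", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    pts <- matrix(runif(n * 3, 0, 6), n, 3)
    coords <- array(pts, c(n, 1, 3))
    m <- pairwise_rmsd(coords)
    cutoff <- runif(1, 0.5, 5)
    fast <- gromos_cluster(m, cutoff)
    slow <- naive_gromos(m, cutoff)
    expect_true(same_partition(fast$labels[order(seq_len(n))],
                               slow$labels))
    # centroid sets must coincide
    expect_setequal(fast$clusters$centroid, slow$centroids)
  }
})

test_that("clustering is invariant under conformer relabeling", {
  set.seed(15)
  coords <- array(rnorm(12 * 2 * 3, sd = 2), c(12, 2, 3))
  m <- pairwise_rmsd(coords)
  perm <- sample(12)
  res1 <- gromos_cluster(m, 1.5)
  res2 <- gromos_cluster(m[perm, perm], 1.5)
  expect_true(same_partition(res1$labels[perm], res2$labels))
})

test_that("conformer extraction matches brute-force window counting", {
  set.seed(31)
  frames <- lapply(1:40, function(f) {
    matrix(c(runif(1, 2, 30), 0, 0), 1, 3)
  })
  traj <- toy_multiframe(frames)
  rs <- replicate_set(list(traj, traj))
  ser <- dnac_series(rs, toy_nac_spec())
  win <- c(18, 20)
  confs <- extract_conformers(rs, ser, win)
  expect_equal(n_conformers(confs),
               sum(ser$dnac > win[1] & ser$dnac < win[2]))
  all_win <- extract_conformers(rs, ser, c(0, Inf))
  expect_equal(n_conformers(all_win), nrow(ser))
  expect_error(extract_conformers(rs, ser, c(20, 18)), "d_lo < d_hi")
  expect_message(
    empty <- extract_conformers(rs, ser, c(1000, 1001)), "no conformers")
  expect_equal(n_conformers(empty), 0L)
})

test_that("contact frequencies count frames with any-atom contacts", {
  # residue 2's atom sits 3 A from the substrate in every frame
  prot <- rbind(c(0, 0, 0), c(10, 0, 0))
  frames <- replicate(6, rbind(c(13, 0, 0)), simplify = FALSE)
  traj <- toy_multiframe(frames, prot_pos = prot)
  rs <- replicate_set(list(traj))
  cf <- contact_frequency(rs, cutoff = 4)
  freq <- setNames(cf$frequency, cf$resnum)
  expect_equal(unname(freq["2"]), 1)
  expect_equal(unname(freq["1"]), 0)
  # contact in exactly half the frames -> 0.5
  frames2 <- c(replicate(3, rbind(c(13, 0, 0)), simplify = FALSE),
               replicate(3, rbind(c(40, 0, 0)), simplify = FALSE))
  traj2 <- toy_multiframe(frames2, prot_pos = prot)
  cf2 <- contact_frequency(replicate_set(list(traj2)), cutoff = 4)
  expect_equal(cf2$frequency[cf2$resnum == 2], 0.5)
  # monotone in cutoff
  cf3 <- contact_frequency(replicate_set(list(traj2)), cutoff = 30)
  expect_true(all(cf3$frequency >=
                    cf2$frequency[order(cf2$resnum)][order(cf3$resnum)] - 1e-12))
  expect_error(contact_frequency(rs, frames = integer()), "empty frame")
})

test_that("cluster results expose tidy/glance views", {
  m <- matrix(c(0, 0.1, 5, 0.1, 0, 5, 5, 5, 0), 3, 3)
  res <- gromos_cluster(m, 1)
  expect_equal(tidy(res)$size, c(2L, 1L))
  gl <- glance(res)
  expect_equal(gl$n_clusters, 2L)
  expect_equal(gl$largest_population, 2 / 3)
})
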
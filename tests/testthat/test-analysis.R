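test_that("Kabsch RMSD is a proper superposition metric", {
  set.seed(31)
  a <- matrix(rnorm(15), 5, 3)
  expect_equal(kabsch_rmsd(a, a), 0)

  b <- random_rigid_motion(a, seed = 2)
  expect_lt(kabsch_rmsd(a, b), 1e-12)

  # symmetry
  set.seed(32)
  c2 <- a + matrix(rnorm(15, sd = 0.3), 5, 3)
  expect_equal(kabsch_rmsd(a, c2), kabsch_rmsd(c2, a), tolerance = 1e-12)

  # independent oracle: optimal-fit RMSD from bio3d on the same point sets
  # (bio3d rounds its result to 3 decimals)
  oracle <- bio3d::rmsd(as.vector(t(a)), as.vector(t(c2)), fit = TRUE)
  expect_lt(abs(kabsch_rmsd(a, c2) - oracle), 1e-3)

  # a mirrored set must NOT superpose to zero (proper rotations only)
  m <- a %*% diag(c(-1, 1, 1))
  expect_gt(kabsch_rmsd(a, m), 1e-3)

  expect_error(kabsch_rmsd(a, a[1:4, ]), "differ in size")
})

test_that("end-to-end distance uses terminal CA atoms", {
  two <- bead_structure(rbind(c(0, 0, 0), c(0.6, 0.8, 0)))
  expect_equal(end_to_end(s = two), 1.0)
  x2 <- random_rigid_motion(coords(two), seed = 3)
  expect_equal(end_to_end(x2, two), 1.0, tolerance = 1e-12)
})

test_that("gyration tensor yields Rg and a normalized asphericity", {
  # two unit-mass points at distance d: Rg = d/2
  two <- rbind(c(0, 0, 0), c(0.8, 0, 0))
  expect_equal(radius_of_gyration(two), 0.4, tolerance = 1e-12)

  # regular octahedron: spherically symmetric inertia, A = 0
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  expect_equal(asphericity(oct), 0, tolerance = 1e-12)

  # collinear points: the rod limit, A = 1
  rod <- cbind(seq(0, 1, length.out = 7), 0, 0)
  expect_equal(asphericity(rod), 1, tolerance = 1e-12)

  # invariance under rigid motion and uniform mass rescaling
  set.seed(33)
  pts <- matrix(rnorm(30), 10, 3)
  expect_equal(radius_of_gyration(random_rigid_motion(pts, 4)),
               radius_of_gyration(pts), tolerance = 1e-9)
  expect_equal(asphericity(pts, masses = rep(7, 10)), asphericity(pts),
               tolerance = 1e-12)

  expect_error(asphericity(matrix(0, 1, 3)), "single point")
})

test_that("time-to-target returns the earliest crossing or NA", {
  times <- seq(0, 9)
  r <- c(1, 0.8, 0.6, 0.5, 0.4, 0.15, 0.3, 0.1, 0.5, 0.6)
  expect_equal(tau_to_target(r, times, 0.2), 5)
  expect_true(is.na(tau_to_target(r + 1, times, 0.2)))
  expect_equal(tau_to_target(r, times, 10), 0)  # threshold above everything
})

test_that("trajectory summaries fill every report field consistently", {
  two <- build_two_state_polymer(12, seed = 1)
  top <- build_topology(two$hairpin, sbm_constants(cutoff = 0.5))
  td <- make_difference_target(two$hairpin, two$extended)
  cfg <- sim_config(temperature = 70, n_steps = 8000L, out_stride = 200L,
                    seed = 2)
  traj <- run_simulation(two$hairpin, top, cfg,
                         bias = bias_config(1e-7, td$dI_exp, td$I_ref))
  rep <- summarize_trajectory(traj, two$hairpin, two$extended)

  nf <- dim(traj$frames)[1]
  expect_length(rep$rmsd_target, nf)
  expect_equal(rep$rmsd_target_min, min(rep$rmsd_target))
  expect_lte(rep$rmsd_target_min, mean(rep$rmsd_target))
  expect_lte(rep$V_XS_min, rep$V_XS_av)
  expect_true(rep$pearson_rho >= -1 && rep$pearson_rho <= 1)
  # the reported rho is the two-pass Pearson coefficient of V_XS against
  # the target-RMSD series
  u <- traj$energies$V_XS; v <- rep$rmsd_target
  rho2 <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(rep$pearson_rho, rho2, tolerance = 1e-12)
  # by definition the global minimum beats the minimum-V_XS frame
  expect_lte(rep$rmsd_target_min, rep$rmsd_target_at_vxs_min)
  expect_true(all(rep$rg > 0))
  expect_true(all(rep$asphericity >= 0 & rep$asphericity <= 1))

  # deterministic: same run summarizes identically
  traj2 <- run_simulation(two$hairpin, top, cfg,
                          bias = bias_config(1e-7, td$dI_exp, td$I_ref))
  rep2 <- summarize_trajectory(traj2, two$hairpin, two$extended)
  expect_identical(rep[names(rep) != "times"], rep2[names(rep2) != "times"])

  # free run: zero bias energy and an undefined correlation
  free <- run_simulation(two$hairpin, top, cfg)
  repf <- summarize_trajectory(free, two$hairpin, two$extended)
  expect_equal(repf$V_XS_av, 0)
  expect_true(is.na(repf$pearson_rho))

  # single-frame trajectory already at the target
  still <- run_simulation(two$extended, build_topology(two$extended,
                                                       sbm_constants(cutoff = 0.5)),
                          sim_config(n_steps = 0))
  reps <- summarize_trajectory(still, two$hairpin, two$extended)
  expect_equal(reps$rmsd_target_min, 0, tolerance = 1e-12)
  expect_equal(reps$tau_to_target, 0)

  # report files round-trip through disk
  pre <- tempfile()
  write_report(rep, pre)
  js <- jsonlite::read_json(paste0(pre, ".json"))
  expect_equal(js$rmsd_target_min, rep$rmsd_target_min, tolerance = 1e-9)
  expect_equal(nrow(utils::read.csv(paste0(pre, ".csv"))), nf)
})
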
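test_that("contact map applies the cutoff and sequence-separation rule", {
  # beads on a line, one per residue, 0.2 nm apart: residue pairs (i, j)
  # within 0.45 nm are (i, i+1) and (i, i+2) only, all with |i-j| <= 3
  xyz <- cbind(seq(0, by = 0.2, length.out = 8), 0, 0)
  s <- bead_structure(xyz)
  expect_equal(nrow(build_contacts(s, 0.45)), 0)

  # put residues 1 and 6 close in space: eligible (separation 5 > 3)
  xyz2 <- xyz; xyz2[6, ] <- c(0.0, 0.40, 0)
  ct <- build_contacts(bead_structure(xyz2), 0.45)
  expect_true(any(ct$i == 1 & ct$j == 6))
  expect_equal(ct$sigma0[ct$i == 1 & ct$j == 6], 0.40, tolerance = 1e-12)

  # the same geometry between residues 2 and 5 (separation 3) is excluded
  xyz3 <- xyz; xyz3[5, ] <- c(0.2, 0.40, 0)
  ct3 <- build_contacts(bead_structure(xyz3), 0.45)
  expect_false(any(ct3$i == 2 & ct3$j == 5))

  # nothing beyond the cutoff
  xyz4 <- xyz; xyz4[6, ] <- c(0.0, 0.60, 0)
  ct4 <- build_contacts(bead_structure(xyz4), 0.45)
  expect_false(any(ct4$i == 1 & ct4$j == 6))
})

test_that("topology construction follows templates and the normalization", {
  s <- build_bent_helix(mixed_sequence)
  top <- build_topology(s)
  n <- top$n_atoms

  # contact : dihedral = 2 : 1 with total n_atoms
  expect_equal(sum(top$contacts[, 4]), 2 / 3 * n, tolerance = 1e-9)
  expect_equal(sum(top$propers[, 6]), 1 / 3 * n, tolerance = 1e-9)
  expect_equal(sum(top$contacts[, 4]) + sum(top$propers[, 6]), n,
               tolerance = 1e-9)

  # every contact pair is excluded from non-native repulsion
  exk <- paste(top$exclusions[, 1], top$exclusions[, 2])
  expect_true(all(paste(top$contacts[, 1], top$contacts[, 2]) %in% exk))

  # di-alanine: bonds are the two residue templates plus one peptide bond,
  # and no contacts can exist
  di <- build_ideal_helix("AA")
  topd <- build_topology(di)
  expect_equal(nrow(topd$bonds), 2 * 4 + 1)
  expect_equal(nrow(topd$contacts), 0)
})

test_that("chain breaks are detected and named", {
  two <- build_ideal_helix("AAAA")
  x <- coords(two)
  x[two$atoms$resid >= 3, ] <- x[two$atoms$resid >= 3, ] + 2
  coords(two) <- x
  expect_error(build_topology(two), "chain break between residues 2 and 3")
})

test_that("closed-form energies match the potential's printed constants", {
  # native configuration: all bonded terms zero, contact energy -sum(Kc)
  s <- build_bent_helix(mixed_sequence)
  top <- build_topology(s)
  ef <- sbm_energy_forces(coords(s), top)
  expect_lt(abs(ef$energy$bond), 1e-20)
  expect_lt(abs(ef$energy$angle), 1e-20)
  expect_lt(abs(ef$energy$improper), 1e-20)
  expect_equal(ef$energy$proper, 0)
  expect_equal(ef$energy$contact, -sum(top$contacts[, 4]), tolerance = 1e-9)

  # bond stretched by 0.01 nm at Kb = 20000 eps/nm^2 costs exactly 2 eps
  topb <- manual_topology(2, bonds = matrix(c(1, 2, 0.38, 20000), 1),
                          exclusions = matrix(c(1, 2), 1))
  x <- rbind(c(0, 0, 0), c(0.39, 0, 0))
  expect_equal(sbm_energy_forces(x, topb)$energy$bond, 2, tolerance = 1e-12)

  # proper dihedral displaced by pi: (1 - cos pi) + (1 - cos 3pi)/2 = 3
  x4 <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  phi0 <- saxsbm:::.vdihedral(x4[1, ], x4[2, ], x4[3, ], x4[4, ])
  topp <- manual_topology(4, props = matrix(c(1, 2, 3, 4, phi0 + pi, 2.5), 1))
  expect_equal(sbm_energy_forces(x4, topp)$energy$proper, 3 * 2.5,
               tolerance = 1e-12)

  # overlapping atoms in a repulsive pair are a singularity
  topo <- manual_topology(2, knc = 0.01)
  expect_error(sbm_energy_forces(rbind(c(0, 0, 0), c(0, 0, 0)), topo),
               "overlapping")
})

test_that("every force term matches central finite differences", {
  set.seed(11)
  x4 <- matrix(rnorm(12), 4, 3)
  cases <- list(
    bond = manual_topology(4, bonds = matrix(c(1, 2, 0.3, 100), 1)),
    angle = manual_topology(4, angles = matrix(c(1, 2, 3, 1.5, 40), 1)),
    improper = manual_topology(4, imps = matrix(c(1, 2, 3, 4, 0.5, 40), 1)),
    proper = manual_topology(4, props = matrix(c(1, 2, 3, 4, 0.5, 2), 1)),
    contact = manual_topology(4, contacts = matrix(c(1, 4, 0.4, 1.5), 1)),
    nonnative = manual_topology(4, knc = 0.01)
  )
  for (nm in names(cases)) {
    top <- cases[[nm]]
    ef <- sbm_energy_forces(x4, top)
    err <- fd_force_error(x4, function(x) sbm_energy_forces(x, top)$energy$total,
                          ef$forces, k = 12)
    expect_lt(err, 1e-6)
  }

  # and the full potential on a realistically perturbed all-atom structure
  s <- build_bent_helix(mixed_sequence)
  top <- build_topology(s)
  set.seed(4)
  x <- coords(s) + matrix(rnorm(3 * top$n_atoms, sd = 0.004), ncol = 3)
  ef <- sbm_energy_forces(x, top)
  err <- fd_force_error(x, function(xx) sbm_energy_forces(xx, top)$energy$total,
                        ef$forces, k = 25)
  expect_lt(err, 1e-6)
})

test_that("the potential is rigid-motion invariant with zero net force/torque", {
  s <- build_bent_helix(mixed_sequence)
  top <- build_topology(s)
  set.seed(5)
  x <- coords(s) + matrix(rnorm(3 * top$n_atoms, sd = 0.01), ncol = 3)
  ef <- sbm_energy_forces(x, top)

  expect_lt(max(abs(colSums(ef$forces))), 1e-9)
  tq <- colSums(t(vapply(seq_len(nrow(x)), function(i) {
    saxsbm:::.vcross(x[i, ], ef$forces[i, ])
  }, numeric(3))))
  expect_lt(max(abs(tq)), 1e-9)

  x2 <- random_rigid_motion(x, seed = 7)
  e2 <- sbm_energy_forces(x2, top)$energy$total
  expect_equal(e2, ef$energy$total, tolerance = 1e-9)

  # with repulsion switched off, the native structure is a stationary point
  top0 <- top; top0$k_nc <- 0
  f0 <- sbm_energy_forces(coords(s), top0)$forces
  expect_lt(max(abs(f0)), 1e-7)
})
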
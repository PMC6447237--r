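test_that("parse_pdb reads heavy atoms, strips hydrogens, converts units", {
  s <- parse_pdb(toy_ala_pdb())
  expect_equal(nrow(s$atoms), 5)
  expect_equal(n_residues(s), 1)
  expect_equal(s$atoms$restype, rep("ALA", 5))
  # x = 1.000 A stored as 0.1000 nm
  expect_equal(s$atoms$x[1], 0.1, tolerance = 1e-9)

  h_line <- "ATOM      6  HB1 ALA A   1       3.500   1.000   1.500  1.00  0.00           H"
  s2 <- parse_pdb(toy_ala_pdb(h_line))
  expect_equal(nrow(s2$atoms), 5)

  het <- "HETATM    7  O   HOH A   2       9.000   9.000   9.000  1.00  0.00           O"
  s3 <- parse_pdb(toy_ala_pdb(het))
  expect_equal(nrow(s3$atoms), 5)
})

test_that("parse_pdb validates records and lookups", {
  bad <- toy_ala_pdb()
  bad[3] <- "ATOM      2  CA  ALA A   1       xx.xxx   2.000   3.000  1.00  0.00"
  expect_error(parse_pdb(bad), "line 3")
  expect_error(parse_pdb(toy_ala_pdb(), model_index = 2), "model 2")
  expect_error(parse_pdb(toy_ala_pdb(), chain = "Z"), "chain Z")
})

test_that("altloc resolves to highest occupancy with ties toward A", {
  two_alt <- c(
    "ATOM      1  N  AALA A   1       1.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       2.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA AALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BALA A   1       4.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  C   ALA A   1       5.000   0.000   0.000  1.00  0.00           C",
    "END")
  s <- parse_pdb(two_alt)
  expect_equal(nrow(s$atoms), 3)
  expect_equal(s$atoms$x[s$atoms$name == "N"], 0.2)   # higher occupancy B
  expect_equal(s$atoms$x[s$atoms$name == "CA"], 0.3)  # tie -> altloc A
})

test_that("write/parse round trip preserves fields to PDB precision", {
  s <- build_ideal_helix("GASV")
  s2 <- parse_pdb(write_structure(s))
  expect_identical(s2$atoms$name, s$atoms$name)
  expect_identical(s2$atoms$restype, s$atoms$restype)
  expect_identical(s2$atoms$resid, s$atoms$resid)
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-3 / 10 / 2 + 1e-12) # 1e-3 A

  # multi-model writing produces one MODEL block per frame
  txt <- write_structure(s, multi_model = list(coords(s), coords(s) + 0.05))
  expect_equal(length(grep("^MODEL", strsplit(txt, "\n")[[1]])), 2)
  m2 <- parse_pdb(txt, model_index = 2)
  expect_equal(mean(coords(m2) - coords(s)), 0.05, tolerance = 1e-3)

  # an empty structure cannot even be constructed
  expect_error(saxsbm:::new_structure(s$atoms[0, ]), "no atoms")
})

test_that("fragment extraction keeps numbering and composes", {
  s <- build_ideal_helix(mixed_sequence)
  f <- extract_fragment(s, 5, 12)
  expect_equal(n_residues(f), 8)
  expect_equal(sort(unique(f$atoms$resid)), 5:12)
  # identity on the full range
  full <- extract_fragment(s, 1, n_residues(s))
  expect_identical(full$atoms[, 1:8], s$atoms[, 1:8])
  # idempotent
  f2 <- extract_fragment(f, 5, 12)
  expect_identical(f2$atoms$name, f$atoms$name)
  expect_error(extract_fragment(s, 1, 0), "empty")
  expect_error(extract_fragment(s, 100, 120), "not present")
})

test_that("ideal helix has canonical geometry and is deterministic", {
  h <- build_ideal_helix(strrep("A", 21))
  ca <- coords(h)[ca_indices(h), ]
  dca <- sqrt(rowSums((ca[-1, ] - ca[-21, ])^2))
  expect_true(all(abs(dca - 0.38) < 0.01))

  # rise per residue from the helix axis (PCA of CA positions): the chosen
  # (-57, -47) torsions give close to the canonical 0.15 nm rise, so the
  # 21-residue end-to-end span is near 20 * rise
  hl <- build_ideal_helix(strrep("A", 40))
  cal <- coords(hl)[ca_indices(hl), ]
  pc <- prcomp(cal)
  axis_t <- cal %*% pc$rotation[, 1]          # position along the axis
  radial <- cal %*% pc$rotation[, 2:3]        # in-plane coordinates
  rise <- abs(mean(diff(axis_t)))
  radius <- mean(sqrt(rowSums(sweep(radial, 2, colMeans(radial))^2)))
  phase <- atan2(radial[, 2] - mean(radial[, 2]),
                 radial[, 1] - mean(radial[, 1]))
  dphase <- abs(mean(atan2(sin(diff(phase)), cos(diff(phase)))))
  expect_gt(rise, 0.14); expect_lt(rise, 0.165)
  # closed-form span prediction from (rise, radius, twist per residue)
  predicted <- sqrt((20 * rise)^2 + (2 * radius * sin(20 * dphase / 2))^2)
  span <- sqrt(sum((ca[21, ] - ca[1, ])^2))
  expect_equal(span, predicted, tolerance = 0.02)

  expect_identical(build_ideal_helix("GASV"), build_ideal_helix("GASV"))
  g <- build_ideal_helix("G")
  expect_equal(n_residues(g), 1)
  expect_error(build_ideal_helix("AXZ"), "unknown residue letter")
  expect_error(build_ideal_helix(""), "empty")
})

test_that("all twenty residue types build with closed rings", {
  s <- build_ideal_helix(mixed_sequence)
  expect_equal(n_residues(s), 21)
  x <- coords(s)
  for (rt in c("PRO", "PHE", "TYR", "HIS", "TRP")) {
    ix <- which(s$atoms$restype == rt)
    for (cl in saxsbm:::.aa_ring_closures[[rt]]) {
      a <- ix[match(cl[1], s$atoms$name[ix])]
      b <- ix[match(cl[2], s$atoms$name[ix])]
      d <- sqrt(sum((x[a, ] - x[b, ])^2))
      expect_gt(d, 0.12); expect_lt(d, 0.16)  # a plausible covalent bond
    }
  }
})

test_that("two-state polymer is deterministic with the stated geometry", {
  two <- build_two_state_polymer(10, seed = 1)
  two2 <- build_two_state_polymer(10, seed = 1)
  expect_identical(two, two2)

  # extended end-to-end distance is exactly (n-1) * bond length
  expect_equal(end_to_end(s = two$extended), 9 * 0.38, tolerance = 1e-12)

  ca_h <- coords(two$hairpin); ca_e <- coords(two$extended)
  expect_gt(kabsch_rmsd(ca_h, ca_e), 0.1)

  # hairpin bonds stay near the nominal length (tiny jitter only)
  bl <- sqrt(rowSums((ca_h[-1, ] - ca_h[-10, ])^2))
  expect_true(all(abs(bl - 0.38) < 0.1))

  expect_error(build_two_state_polymer(3), "n_beads")
})
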
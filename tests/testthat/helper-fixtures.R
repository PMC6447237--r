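# Shared fixtures, built in code so the suite needs no external files.

# A minimal hand-written PDB: one alanine, 5 heavy atoms (+ optional extras)
toy_ala_pdb <- function(extra_lines = character(0)) {
  c("HEADER    TOY",
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.458   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       3.010   3.420   3.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       2.300   4.400   3.200  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       3.000   1.200   1.800  1.00  0.00           C",
    extra_lines,
    "END")
}

# bare topology with hand-chosen terms, for closed-form energy checks
manual_topology <- function(n, bonds = NULL, angles = NULL, imps = NULL,
                            props = NULL, contacts = NULL,
                            exclusions = NULL, knc = 0, sigma_nn = 0.25) {
  z <- function(m, nc) if (is.null(m)) matrix(numeric(0), 0, nc) else m
  structure(list(
    n_atoms = as.integer(n), bonds = z(bonds, 4), angles = z(angles, 5),
    impropers = z(imps, 6), propers = z(props, 6),
    contacts = z(contacts, 4),
    exclusions = if (is.null(exclusions)) matrix(integer(0), 0, 2) else exclusions,
    k_nc = knc, sigma_nn = sigma_nn, constants = sbm_constants(),
    cg = TRUE, atom_names = NULL, resindex = NULL, sequence = NULL),
    class = "sbm_topology")
}

# single-bead and two-bead structures for integrator checks
bead_structure <- function(xyz) {
  n <- nrow(xyz)
  saxsbm:::new_structure(data.frame(
    name = "CA", element = "C", resid = seq_len(n), restype = "GLY",
    chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

# central finite difference of a scalar-valued energy function; returns the
# maximum relative force error over `k` random components
fd_force_error <- function(x, energy_fn, forces, k = 20, h = 1e-6,
                           floor = 1) {
  set.seed(99)
  err <- 0
  for (idx in sample(length(x), min(k, length(x)))) {
    xp <- x; xp[idx] <- xp[idx] + h
    xm <- x; xm[idx] <- xm[idx] - h
    fd <- -(energy_fn(xp) - energy_fn(xm)) / (2 * h)
    err <- max(err, abs(fd - forces[idx]) / max(floor, abs(fd)))
  }
  err
}

random_rigid_motion <- function(x, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  sweep(x %*% t(R), 2, rnorm(3), "+")
}

mixed_sequence <- "ARNDCQEGHILKMFPSTWYVA"
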
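# Synthetic fixture structures: ideal helices, bent two-helix toys, and
# two-state bead polymers. All builders are deterministic so the whole test
# suite runs without any external structure files.

# Backbone ideal geometry (Angstrom / degrees, Engh-Huber-like values).
.bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8
)

# Build an all-atom peptide from per-residue (phi, psi) backbone torsions;
# side chains are placed from the residue z-matrices (extended rotamers).
.build_peptide <- function(seq3, phi, psi, omega = 180, source = "peptide") {
  n <- length(seq3)
  stopifnot(length(phi) == n, length(psi) == n)
  phi <- .deg2rad(phi); psi <- .deg2rad(psi); omega <- .deg2rad(omega)

  pos <- list()   # pos[[i]] named list of atom positions (Angstrom)
  # first residue backbone in the xy-plane
  N1 <- c(0, 0, 0)
  CA1 <- c(.bb$b_n_ca, 0, 0)
  a <- .deg2rad(180 - .bb$ang_n_ca_c)
  C1 <- CA1 + .bb$b_ca_c * c(cos(a), sin(a), 0)
  pos[[1]] <- list(N = N1, CA = CA1, C = C1)

  for (i in seq_len(n)) {
    p <- pos[[i]]
    # carbonyl O is anti to the next backbone N (torsion psi + 180)
    pos[[i]]$O <- .place_atom(p$N, p$CA, p$C, .bb$b_c_o,
                              .deg2rad(.bb$ang_ca_c_o), psi[i] + pi)
    if (i < n) {
      Nn <- .place_atom(p$N, p$CA, p$C, .bb$b_c_n,
                        .deg2rad(.bb$ang_ca_c_n), psi[i])
      CAn <- .place_atom(p$CA, p$C, Nn, .bb$b_n_ca,
                         .deg2rad(.bb$ang_c_n_ca), omega)
      Cn <- .place_atom(p$C, Nn, CAn, .bb$b_ca_c,
                        .deg2rad(.bb$ang_n_ca_c), phi[i + 1])
      pos[[i + 1]] <- list(N = Nn, CA = CAn, C = Cn)
    }
  }

  # side chains
  for (i in seq_len(n)) {
    for (z in .aa_sidechain_zmat[[seq3[i]]]) {
      p <- pos[[i]]
      pos[[i]][[z$atom]] <- .place_atom(p[[z$a1]], p[[z$a2]], p[[z$a3]],
                                        z$b, .deg2rad(z$theta),
                                        .deg2rad(z$phi))
    }
  }

  rows <- list()
  for (i in seq_len(n)) {
    for (nm in names(pos[[i]])) {
      p <- pos[[i]][[nm]]
      rows[[length(rows) + 1]] <- data.frame(
        name = nm, element = .element_from_name(nm), resid = i,
        restype = seq3[i], chain = "A",
        x = p[1] / 10, y = p[2] / 10, z = p[3] / 10,
        stringsAsFactors = FALSE)
    }
  }
  new_structure(do.call(rbind, rows), source = source)
}

#' Build an ideal alpha-helix
#'
#' Places the backbone with ideal helical torsions (phi = -57, psi = -47,
#' omega = 180 degrees) and standard bond geometry; side chains are placed in
#' extended rotamers from internal-coordinate templates. Deterministic: the
#' same sequence always yields bitwise-identical coordinates.
#'
#' @param sequence one-letter amino-acid sequence
#' @param phi,psi backbone torsions in degrees, scalar or per-residue
#' @return an [sbm_structure]
#' @export
build_ideal_helix <- function(sequence, phi = -57, psi = -47) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters1) == 0) stop("empty sequence")
  seq3 <- aa_one_to_three(letters1)
  n <- length(seq3)
  .build_peptide(seq3, rep_len(phi, n), rep_len(psi, n),
                 source = paste0("ideal_helix:", sequence))
}

#' Build a bent two-helix toy structure
#'
#' Two ideal helical segments connected by a short turn (non-helical
#' backbone torsions), emulating a helix-turn-helix polypeptide with a
#' compact bent shape. Useful as the compact partner of a two-state pair
#' whose other state is the straight helix of the same sequence.
#'
#' @param sequence one-letter amino-acid sequence
#' @param turn_start first residue of the turn (default: middle)
#' @param turn_length number of turn residues (default 3)
#' @return an [sbm_structure]
#' @export
build_bent_helix <- function(sequence, turn_start = NULL, turn_length = 3) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  n <- length(letters1)
  if (n < turn_length + 4) stop("sequence too short for a two-helix toy")
  if (is.null(turn_start)) turn_start <- ceiling(n / 2) - 1
  turn <- seq(turn_start, min(n, turn_start + turn_length - 1))
  phi <- rep(-57, n); psi <- rep(-47, n)
  # turn torsions chosen so the second helix runs back antiparallel,
  # giving a compact clash-free bend (end-to-end ~ 1 nm for a 21-mer)
  phi[turn] <- rep_len(c(-9, 97, 177), length(turn))
  psi[turn] <- rep_len(c(112, 48, 125), length(turn))
  .build_peptide(aa_one_to_three(letters1), phi, psi,
                 source = paste0("bent_helix:", sequence))
}

#' Build a two-state bead polymer
#'
#' Returns two conformations of the same coarse-grained bead chain (one CA
#' bead per residue, fixed bond length): a compact hairpin and a fully
#' extended chain. The pair serves as initial/target states for end-to-end
#' tests of scattering-guided transitions. Deterministic for a fixed seed
#' (the seed only sets a tiny reproducible jitter on the hairpin that breaks
#' exact arm collinearity).
#'
#' @param n_beads number of beads (>= 4)
#' @param seed integer seed for the reproducible hairpin jitter
#' @param bond_length bead-bead bond length in nm (default 0.38, the
#'   canonical CA-CA virtual bond)
#' @return list with elements `hairpin` and `extended`, both [sbm_structure]
#' @export
build_two_state_polymer <- function(n_beads, seed = 1L, bond_length = 0.38) {
  if (n_beads < 4) stop("n_beads must be >= 4")
  b <- bond_length
  mk <- function(xyz, tag) {
    new_structure(data.frame(
      name = "CA", element = "C", resid = seq_len(n_beads), restype = "GLY",
      chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE),
      source = paste0("polymer_", tag, ":n=", n_beads))
  }
  # extended: exactly collinear, end-to-end = (n-1) * bond length
  ext <- cbind((seq_len(n_beads) - 1) * b, 0, 0)

  # hairpin: two antiparallel straight arms one bond length apart, plus a
  # small deterministic jitter so no four beads are exactly collinear
  m <- ceiling(n_beads / 2)
  hp <- matrix(0, n_beads, 3)
  hp[seq_len(m), 1] <- (seq_len(m) - 1) * b
  if (m < n_beads) {
    rest <- (m + 1):n_beads
    hp[rest, 1] <- (m - (seq_along(rest))) * b
    hp[rest, 2] <- b
  }
  rs <- .Random.seed_save()
  set.seed(as.integer(seed))
  hp <- hp + matrix(rnorm(3 * n_beads, sd = 0.008), n_beads, 3)
  .Random.seed_restore(rs)

  list(hairpin = mk(hp, "hairpin"), extended = mk(ext, "extended"))
}

# Save/restore the global RNG stream so fixture jitter does not perturb the
# caller's seed bookkeeping.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(rs) {
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
}
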
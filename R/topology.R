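#' Force-field constants of the structure-based model
#'
#' Energetic weights and structural parameters of the all-atom
#' structure-based potential. Defaults: `kb` = 20000 eps/nm^2,
#' `ka` = `ki` = 40 eps/rad^2 (angles handled in radians internally),
#' `knc` = 0.01 eps, excluded-volume radius `sigma_nn` = 0.25 nm, native
#' contact cutoff 0.45 nm, and a 2:1 split of the total contact:dihedral
#' energy whose sum is normalized to the number of atoms.
#'
#' @param kb bond force constant (eps/nm^2)
#' @param ka angle force constant (eps/rad^2)
#' @param ki improper-dihedral force constant (eps/rad^2)
#' @param knc non-native repulsion strength (eps)
#' @param sigma_nn non-native excluded-volume radius (nm)
#' @param cutoff native-contact heavy-atom distance cutoff (nm)
#' @param contact_dihedral_ratio ratio of total contact to total proper
#'   dihedral energy used in the normalization
#' @param chain_break peptide C-N distance (nm) beyond which a chain break
#'   is reported
#' @param cg_chain_break bead-bead bond distance (nm) beyond which a break
#'   is reported for single-bead-per-residue chains
#' @return list of constants
#' @export
sbm_constants <- function(kb = 20000, ka = 40, ki = 40, knc = 0.01,
                          sigma_nn = 0.25, cutoff = 0.45,
                          contact_dihedral_ratio = 2,
                          chain_break = 0.25, cg_chain_break = 0.7) {
  list(kb = kb, ka = ka, ki = ki, knc = knc, sigma_nn = sigma_nn,
       cutoff = cutoff, contact_dihedral_ratio = contact_dihedral_ratio,
       chain_break = chain_break, cg_chain_break = cg_chain_break)
}

#' Native contact map
#'
#' All heavy-atom pairs within `cutoff` whose residues i, j satisfy
#' i > j + 3 in sequence (pairs on different chains are always eligible).
#' Each contact stores its native distance sigma0.
#'
#' @param s an [sbm_structure] (the native structure)
#' @param cutoff distance cutoff in nm (default 0.45)
#' @return data.frame with columns i, j (atom indices) and sigma0 (nm)
#' @export
build_contacts <- function(s, cutoff = 0.45) {
  stopifnot(inherits(s, "sbm_structure"))
  ri <- residue_index(s)
  ch <- match(s$atoms$chain, unique(s$atoms$chain))
  m <- .find_contacts_cpp(coords(s), as.integer(ri), as.integer(ch), cutoff)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), sigma0 = m[, 3])
}

# bonded adjacency list from a 2-column bond index matrix
.adjacency <- function(bonds, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(unique(v)))
}

# all atom pairs within graph distance <= 3 of the bond graph
.local_pairs <- function(adj, n) {
  out_i <- integer(0); out_j <- integer(0)
  for (i in seq_len(n)) {
    seen <- i
    frontier <- i
    for (depth in 1:3) {
      frontier <- setdiff(unique(unlist(adj[frontier])), seen)
      if (length(frontier) == 0) break
      seen <- c(seen, frontier)
    }
    nb <- seen[seen > i]
    out_i <- c(out_i, rep.int(i, length(nb))); out_j <- c(out_j, nb)
  }
  cbind(out_i, out_j)
}

.bond_rows_for_structure <- function(s, const) {
  at <- s$atoms
  n <- nrow(at)
  ri <- residue_index(s)
  nres <- max(ri)
  res_atoms <- split(seq_len(n), ri)
  cg <- all(vapply(res_atoms, function(ix) length(ix) == 1 &&
                     at$name[ix] == "CA", logical(1)))
  pairs <- matrix(integer(0), 0, 2)
  xyz <- coords(s)

  if (cg) {
    for (r in seq_len(nres - 1)) {
      i <- res_atoms[[r]]; j <- res_atoms[[r + 1]]
      if (at$chain[i] != at$chain[j]) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d > const$cg_chain_break) {
        stop("chain break between residues ", at$resid[i], " and ",
             at$resid[j], " (bead distance ", round(d, 3), " nm)")
      }
      pairs <- rbind(pairs, c(i, j))
    }
    return(list(pairs = pairs, cg = TRUE))
  }

  for (r in seq_len(nres)) {
    ix <- res_atoms[[r]]
    nm <- at$name[ix]
    tmpl <- aa_template_bonds(at$restype[ix[1]])
    for (bp in tmpl) {
      a <- ix[match(bp[1], nm)]; b <- ix[match(bp[2], nm)]
      if (!is.na(a) && !is.na(b)) pairs <- rbind(pairs, c(a, b))
    }
    if ("OXT" %in% nm) {
      a <- ix[match("C", nm)]; b <- ix[match("OXT", nm)]
      if (!is.na(a)) pairs <- rbind(pairs, c(a, b))
    }
  }
  for (r in seq_len(nres - 1)) {
    i1 <- res_atoms[[r]]; i2 <- res_atoms[[r + 1]]
    if (at$chain[i1[1]] != at$chain[i2[1]]) next
    ci <- i1[match("C", at$name[i1])]; ni <- i2[match("N", at$name[i2])]
    if (is.na(ci) || is.na(ni)) {
      stop("chain break: residue ", at$resid[i1[1]], " or ", at$resid[i2[1]],
           " lacks backbone C/N")
    }
    d <- sqrt(sum((xyz[ci, ] - xyz[ni, ])^2))
    if (d > const$chain_break) {
      stop("chain break between residues ", at$resid[i1[1]], " and ",
           at$resid[i2[1]], " (C-N distance ", round(d, 3), " nm)")
    }
    pairs <- rbind(pairs, c(ci, ni))
  }
  list(pairs = pairs, cg = FALSE)
}

# atoms belonging to a ring, per atom index (ring torsions get no proper)
.ring_flags <- function(s) {
  at <- s$atoms
  ri <- residue_index(s)
  flag <- rep(FALSE, nrow(at))
  for (r in unique(ri)) {
    ix <- which(ri == r)
    ring <- .aa_ring_atoms[[at$restype[ix[1]]]]
    if (!is.null(ring)) flag[ix[at$name[ix] %in% ring]] <- TRUE
  }
  flag
}

#' Build an all-atom structure-based topology
#'
#' Constructs the full structure-based model from a native structure:
#' covalent bonds (residue templates + peptide links), angles from bonded
#' triplets, improper dihedrals at every center with three or more bonded
#' heavy neighbors (planarity and chirality), one proper dihedral per
#' rotatable non-ring bond, native contacts from [build_contacts()], and
#' the excluded-volume exclusion list. All native reference values (r0,
#' theta0, chi0, phi0, sigma0) are measured from the input coordinates, so
#' the native structure is the global minimum of the potential.
#'
#' The uniform contact weight Kc and dihedral weight Kd are set so that the
#' total contact energy and total proper-dihedral energy are in
#' `contact_dihedral_ratio` (default 2:1) and sum to the number of atoms.
#'
#' @param s an [sbm_structure] (the native structure; at least 2 residues)
#' @param constants force-field constants from [sbm_constants()]
#' @return an `sbm_topology` object
#' @export
build_topology <- function(s, constants = sbm_constants()) {
  stopifnot(inherits(s, "sbm_structure"))
  at <- s$atoms
  n <- nrow(at)
  xyz <- coords(s)
  const <- constants

  br <- .bond_rows_for_structure(s, const)
  bonds_ij <- br$pairs
  adj <- .adjacency(bonds_ij, n)

  r0 <- sqrt(rowSums((xyz[bonds_ij[, 1], , drop = FALSE] -
                      xyz[bonds_ij[, 2], , drop = FALSE])^2))
  bonds <- cbind(bonds_ij, r0, const$kb)

  # angles: every pair of bonded neighbors of each center
  ang <- matrix(numeric(0), 0, 5)
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    for (cidx in seq_len(ncol(cmb))) {
      i <- cmb[1, cidx]; k <- cmb[2, cidx]
      t0 <- .vangle(xyz[i, ], xyz[j, ], xyz[k, ])
      ang <- rbind(ang, c(i, j, k, t0, const$ka))
    }
  }

  # impropers: every atom with >= 3 bonded neighbors (sp2 planarity, CA and
  # branch-center chirality); reference chi0 from the native geometry
  imp <- matrix(numeric(0), 0, 6)
  for (cc in seq_len(n)) {
    nb <- adj[[cc]]
    if (length(nb) < 3) next
    i <- nb[1]; j <- nb[2]; k <- nb[3]
    x0 <- .vdihedral(xyz[i, ], xyz[j, ], xyz[k, ], xyz[cc, ])
    if (!is.finite(x0)) next
    imp <- rbind(imp, c(i, j, k, cc, x0, const$ki))
  }

  # propers: one per rotatable non-ring bond with flanking heavy atoms
  ring <- .ring_flags(s)
  prop <- matrix(numeric(0), 0, 6)
  for (r in seq_len(nrow(bonds_ij))) {
    j <- bonds_ij[r, 1]; k <- bonds_ij[r, 2]
    if (ring[j] && ring[k] && residue_index(s)[j] == residue_index(s)[k]) next
    ni <- setdiff(adj[[j]], k); nl <- setdiff(adj[[k]], j)
    if (length(ni) == 0 || length(nl) == 0) next
    i <- min(ni); l <- min(nl)
    f0 <- .vdihedral(xyz[i, ], xyz[j, ], xyz[k, ], xyz[l, ])
    # degenerate (collinear) native geometry: torsion undefined, drop term
    b1 <- xyz[j, ] - xyz[i, ]; b2 <- xyz[k, ] - xyz[j, ]; b3 <- xyz[l, ] - xyz[k, ]
    if (sum(.vcross(b1, b2)^2) < 1e-12 || sum(.vcross(b2, b3)^2) < 1e-12) next
    prop <- rbind(prop, c(i, j, k, l, f0, NA))
  }

  contacts_df <- if (n_residues(s) >= 5 || br$cg) {
    build_contacts(s, const$cutoff)
  } else {
    data.frame(i = integer(0), j = integer(0), sigma0 = numeric(0))
  }
  nc <- nrow(contacts_df); np <- nrow(prop)

  # ref-49-style normalization: total contact + dihedral energy = n_atoms,
  # split contact:dihedral = ratio:1 with uniform per-term weights
  rho <- const$contact_dihedral_ratio
  kc_tot <- n * rho / (rho + 1)
  kd_tot <- n * 1 / (rho + 1)
  kc <- if (nc > 0) kc_tot / nc else 0
  kd <- if (np > 0) kd_tot / np else 0
  contacts <- cbind(contacts_df$i, contacts_df$j, contacts_df$sigma0,
                    rep(kc, nc))
  if (np > 0) prop[, 6] <- kd

  # exclusions: bonded neighborhood (graph distance <= 3) plus contact pairs
  loc <- .local_pairs(adj, n)
  excl <- rbind(loc, cbind(contacts_df$i, contacts_df$j))
  excl <- unique(excl)

  top <- list(
    n_atoms = n,
    bonds = unname(bonds), angles = unname(ang), impropers = unname(imp),
    propers = unname(prop), contacts = unname(contacts),
    exclusions = unname(excl),
    k_nc = const$knc, sigma_nn = const$sigma_nn,
    constants = const, cg = br$cg,
    atom_names = at$name, resindex = residue_index(s),
    sequence = structure_sequence(s)
  )
  class(top) <- "sbm_topology"
  top
}

#' @export
print.sbm_topology <- function(x, ...) {
  cat(sprintf(paste0("<sbm_topology> %d atoms | %d bonds, %d angles, ",
                     "%d impropers, %d propers, %d contacts\n"),
              x$n_atoms, nrow(x$bonds), nrow(x$angles), nrow(x$impropers),
              nrow(x$propers), nrow(x$contacts)))
  invisible(x)
}

#' Structure-based potential energy and forces
#'
#' Evaluates all terms of the structure-based potential (no extra 1/2
#' factors) and the exact analytic forces (-grad V).
#'
#' @param x coordinates, n_atoms x 3 matrix in nm
#' @param top an `sbm_topology` from [build_topology()]
#' @return list with `energy` (named breakdown: bond, angle, improper,
#'   proper, contact, nonnative, total; in eps) and `forces` (n x 3, eps/nm)
#' @export
sbm_energy_forces <- function(x, top) {
  stopifnot(inherits(top, "sbm_topology"))
  if (!all(is.finite(x))) stop("non-finite coordinates")
  r <- .sbm_eval_cpp(x, unclass(top))
  list(energy = r[c("bond", "angle", "improper", "proper", "contact",
                    "nonnative", "total")],
       forces = r$forces)
}

#' Write a topology to its plain-text serialization
#'
#' Sectioned text format (`meta`, `bonds`, `angles`, `impropers`, `propers`,
#' `contacts`, `exclusions`) so runs can be reproduced without rebuilding.
#'
#' @param top an `sbm_topology`
#' @param path output file path
#' @export
write_topology <- function(top, path) {
  stopifnot(inherits(top, "sbm_topology"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# saxsbm topology v1", con)
  writeLines(sprintf("[meta] n_atoms=%d k_nc=%.10g sigma_nn=%.10g cg=%d",
                     top$n_atoms, top$k_nc, top$sigma_nn, as.integer(top$cg)), con)
  wr <- function(name, m) {
    writeLines(sprintf("[%s] %d", name, nrow(m)), con)
    if (nrow(m) > 0) {
      utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
    }
  }
  wr("bonds", top$bonds); wr("angles", top$angles)
  wr("impropers", top$impropers); wr("propers", top$propers)
  wr("contacts", top$contacts); wr("exclusions", top$exclusions)
  invisible(path)
}

#' Read a topology from its plain-text serialization
#' @param path file written by [write_topology()]
#' @return an `sbm_topology`
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  meta <- lines[grep("^\\[meta\\]", lines)][1]
  getval <- function(key) {
    as.numeric(sub(paste0(".*", key, "=([-0-9.eE+]+).*"), "\\1", meta))
  }
  sec <- function(name, ncol) {
    hdr <- grep(paste0("^\\[", name, "\\] "), lines)[1]
    cnt <- as.integer(sub(paste0("\\[", name, "\\] "), "", lines[hdr]))
    if (cnt == 0) return(matrix(numeric(0), 0, ncol))
    m <- do.call(rbind, lapply(lines[(hdr + 1):(hdr + cnt)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    m
  }
  top <- list(
    n_atoms = as.integer(getval("n_atoms")),
    bonds = sec("bonds", 4), angles = sec("angles", 5),
    impropers = sec("impropers", 6), propers = sec("propers", 6),
    contacts = sec("contacts", 4), exclusions = sec("exclusions", 2),
    k_nc = getval("k_nc"), sigma_nn = getval("sigma_nn"),
    constants = sbm_constants(), cg = getval("cg") == 1,
    atom_names = NULL, resindex = NULL, sequence = NULL
  )
  class(top) <- "sbm_topology"
  top
}
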
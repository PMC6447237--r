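# Amino-acid reference data: 3-/1-letter codes, side-chain internal
# coordinates (NeRF z-matrix rows), ring-closure bonds, residue electron
# counts and mean volumes. Lengths in Angstrom here (converted to nm when
# structures are built), angles in degrees.

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W",
          "Y", "V")

aa_three_to_one <- function(x) {
  i <- match(toupper(x), .aa3)
  if (anyNA(i)) stop("unknown residue type(s): ",
                     paste(unique(x[is.na(i)]), collapse = ", "))
  .aa1[i]
}

aa_one_to_three <- function(x) {
  i <- match(toupper(x), .aa1)
  if (anyNA(i)) stop("unknown residue letter(s): ",
                     paste(unique(x[is.na(i)]), collapse = ", "))
  .aa3[i]
}

# One z-matrix row: atom placed from parent a3 with bond b (Angstrom),
# angle(a2, a3, atom) = theta, dihedral(a1, a2, a3, atom) = phi.
.zrow <- function(atom, a3, a2, a1, b, theta, phi) {
  list(atom = atom, a3 = a3, a2 = a2, a1 = a1,
       b = b, theta = theta, phi = phi)
}

# CB is common to all residues except GLY; L-configuration.
.cb_row <- .zrow("CB", "CA", "N", "C", 1.53, 110.5, 122.5)

.aa_sidechain_zmat <- list(
  GLY = list(),
  ALA = list(.cb_row),
  SER = list(.cb_row, .zrow("OG",  "CB", "CA", "N", 1.42, 110.8, 180)),
  CYS = list(.cb_row, .zrow("SG",  "CB", "CA", "N", 1.81, 113.8, 180)),
  THR = list(.cb_row,
             .zrow("OG1", "CB", "CA", "N", 1.43, 109.6, 180),
             .zrow("CG2", "CB", "CA", "N", 1.52, 110.5, -60)),
  VAL = list(.cb_row,
             .zrow("CG1", "CB", "CA", "N", 1.52, 110.5, 180),
             .zrow("CG2", "CB", "CA", "N", 1.52, 110.5, -60)),
  LEU = list(.cb_row,
             .zrow("CG",  "CB", "CA", "N",  1.53, 116.3, 180),
             .zrow("CD1", "CG", "CB", "CA", 1.52, 110.7, 180),
             .zrow("CD2", "CG", "CB", "CA", 1.52, 110.7, -60)),
  ILE = list(.cb_row,
             .zrow("CG1", "CB",  "CA", "N",  1.53, 110.4, 180),
             .zrow("CG2", "CB",  "CA", "N",  1.52, 110.5, -60),
             .zrow("CD1", "CG1", "CB", "CA", 1.51, 113.8, 180)),
  MET = list(.cb_row,
             .zrow("CG", "CB", "CA", "N",  1.52, 114.1, 180),
             .zrow("SD", "CG", "CB", "CA", 1.81, 112.7, 180),
             .zrow("CE", "SD", "CG", "CB", 1.79, 100.2, 180)),
  PRO = list(.zrow("CB", "CA", "N",  "C",  1.53, 103.2, 115),
             .zrow("CG", "CB", "CA", "N",  1.50, 104.5, -30),
             .zrow("CD", "CG", "CB", "CA", 1.50, 105.5, 30)),
  PHE = list(.cb_row,
             .zrow("CG",  "CB",  "CA",  "N",  1.50, 113.8, 180),
             .zrow("CD1", "CG",  "CB",  "CA", 1.39, 120.7, 90),
             .zrow("CD2", "CG",  "CB",  "CA", 1.39, 120.7, -90),
             .zrow("CE1", "CD1", "CG",  "CB", 1.39, 120.0, 180),
             .zrow("CE2", "CD2", "CG",  "CB", 1.39, 120.0, 180),
             .zrow("CZ",  "CE1", "CD1", "CG", 1.39, 120.0, 0)),
  TYR = list(.cb_row,
             .zrow("CG",  "CB",  "CA",  "N",   1.51, 113.9, 180),
             .zrow("CD1", "CG",  "CB",  "CA",  1.39, 120.8, 90),
             .zrow("CD2", "CG",  "CB",  "CA",  1.39, 120.8, -90),
             .zrow("CE1", "CD1", "CG",  "CB",  1.39, 120.0, 180),
             .zrow("CE2", "CD2", "CG",  "CB",  1.39, 120.0, 180),
             .zrow("CZ",  "CE1", "CD1", "CG",  1.39, 120.0, 0),
             .zrow("OH",  "CZ",  "CE1", "CD1", 1.38, 119.9, 180)),
  TRP = list(.cb_row,
             .zrow("CG",  "CB",  "CA",  "N",   1.50, 113.6, 180),
             .zrow("CD1", "CG",  "CB",  "CA",  1.37, 126.9, 90),
             .zrow("CD2", "CG",  "CB",  "CA",  1.43, 126.8, -90),
             .zrow("NE1", "CD1", "CG",  "CB",  1.38, 110.2, 180),
             .zrow("CE2", "NE1", "CD1", "CG",  1.37, 109.0, 0),
             .zrow("CE3", "CD2", "CE2", "NE1", 1.40, 125.0, 180),
             .zrow("CZ2", "CE2", "CD2", "CE3", 1.40, 118.0, 0),
             .zrow("CZ3", "CE3", "CD2", "CE2", 1.39, 116.0, 0),
             .zrow("CH2", "CZ2", "CE2", "CD2", 1.37, 114.0, 0)),
  ASP = list(.cb_row,
             .zrow("CG",  "CB", "CA", "N",  1.52, 113.0, 180),
             .zrow("OD1", "CG", "CB", "CA", 1.25, 118.5, 0),
             .zrow("OD2", "CG", "CB", "CA", 1.25, 118.5, 180)),
  ASN = list(.cb_row,
             .zrow("CG",  "CB", "CA", "N",  1.52, 112.7, 180),
             .zrow("OD1", "CG", "CB", "CA", 1.23, 120.8, 0),
             .zrow("ND2", "CG", "CB", "CA", 1.33, 116.5, 180)),
  GLU = list(.cb_row,
             .zrow("CG",  "CB", "CA", "N",  1.52, 114.0, 180),
             .zrow("CD",  "CG", "CB", "CA", 1.52, 112.6, 180),
             .zrow("OE1", "CD", "CG", "CB", 1.25, 118.5, 0),
             .zrow("OE2", "CD", "CG", "CB", 1.25, 118.5, 180)),
  GLN = list(.cb_row,
             .zrow("CG",  "CB", "CA", "N",  1.52, 114.0, 180),
             .zrow("CD",  "CG", "CB", "CA", 1.52, 112.6, 180),
             .zrow("OE1", "CD", "CG", "CB", 1.23, 120.8, 0),
             .zrow("NE2", "CD", "CG", "CB", 1.33, 116.5, 180)),
  LYS = list(.cb_row,
             .zrow("CG", "CB", "CA", "N",  1.52, 114.0, 180),
             .zrow("CD", "CG", "CB", "CA", 1.52, 111.3, 180),
             .zrow("CE", "CD", "CG", "CB", 1.52, 111.3, 180),
             .zrow("NZ", "CE", "CD", "CG", 1.49, 111.9, 180)),
  ARG = list(.cb_row,
             .zrow("CG",  "CB", "CA", "N",  1.52, 114.0, 180),
             .zrow("CD",  "CG", "CB", "CA", 1.52, 111.3, 180),
             .zrow("NE",  "CD", "CG", "CB", 1.46, 112.0, 180),
             .zrow("CZ",  "NE", "CD", "CG", 1.33, 124.2, 180),
             .zrow("NH1", "CZ", "NE", "CD", 1.33, 120.0, 0),
             .zrow("NH2", "CZ", "NE", "CD", 1.33, 120.0, 180)),
  HIS = list(.cb_row,
             .zrow("CG",  "CB",  "CA",  "N",  1.49, 113.8, 180),
             .zrow("ND1", "CG",  "CB",  "CA", 1.38, 122.7, 90),
             .zrow("CD2", "CG",  "CB",  "CA", 1.36, 131.0, -90),
             .zrow("CE1", "ND1", "CG",  "CB", 1.32, 109.0, 180),
             .zrow("NE2", "CE1", "ND1", "CG", 1.32, 108.0, 0))
)

# Bonds that close rings (not implied by z-matrix parent relations).
.aa_ring_closures <- list(
  PRO = list(c("CD", "N")),
  PHE = list(c("CZ", "CE2")),
  TYR = list(c("CZ", "CE2")),
  HIS = list(c("NE2", "CD2")),
  TRP = list(c("CE2", "CD2"), c("CH2", "CZ3"))
)

# Intra-residue heavy-atom bonds: backbone + z-matrix parents + closures.
aa_template_bonds <- function(restype) {
  restype <- toupper(restype)
  if (!restype %in% .aa3) stop("unknown residue type: ", restype)
  bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
  for (z in .aa_sidechain_zmat[[restype]]) bonds <- c(bonds, list(c(z$a3, z$atom)))
  if (!is.null(.aa_ring_closures[[restype]]))
    bonds <- c(bonds, .aa_ring_closures[[restype]])
  bonds
}

# Atoms that are part of a ring, per residue type (ring torsions are not
# given proper-dihedral terms; ring geometry is held by angles + impropers).
.aa_ring_atoms <- list(
  PRO = c("N", "CA", "CB", "CG", "CD"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

# Residue electron counts (free amino acid minus one water) and mean residue
# volumes in Angstrom^3 (Zamyatnin-type consensus values). Used for
# solvent-corrected residue form factors.
.aa_electrons <- c(
  ALA = 38, ARG = 84, ASN = 60, ASP = 60, CYS = 54, GLN = 68, GLU = 68,
  GLY = 30, HIS = 72, ILE = 62, LEU = 62, LYS = 70, MET = 70, PHE = 78,
  PRO = 52, SER = 46, THR = 54, TRP = 98, TYR = 86, VAL = 54
)

.aa_volumes_A3 <- c(
  ALA = 88.6, ARG = 173.4, ASN = 114.1, ASP = 111.1, CYS = 108.5,
  GLN = 143.8, GLU = 138.4, GLY = 60.1, HIS = 153.2, ILE = 166.7,
  LEU = 166.7, LYS = 168.6, MET = 162.9, PHE = 189.9, PRO = 112.7,
  SER = 89.0, THR = 116.1, TRP = 227.8, TYR = 193.6, VAL = 140.0
)

# Element of a PDB heavy-atom name within a standard residue.
.element_from_name <- function(name) {
  first <- substr(gsub("^[0-9]", "", name), 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "P"), first, first)
}
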
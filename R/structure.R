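#' @title Molecular structure container
#' @description An `sbm_structure` holds heavy atoms of a (poly)peptide:
#' one row per atom with atom name, element, residue index, 3-letter residue
#' type, chain id and position in nm. Hydrogens are never stored; they are
#' treated implicitly by the structure-based model.
#' @name sbm_structure
NULL

new_structure <- function(atoms, title = "", source = "") {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "element", "resid", "restype", "chain", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("structure has no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom positions")
  }
  bad <- !atoms$restype %in% .aa3
  if (any(bad)) {
    stop("unknown residue type(s): ", paste(unique(atoms$restype[bad]), collapse = ", "))
  }
  for (ch in unique(atoms$chain)) {
    r <- atoms$resid[atoms$chain == ch]
    if (is.unsorted(r)) stop("residue indices not non-decreasing in chain ", ch)
  }
  atoms$resid <- as.integer(atoms$resid)
  structure(list(atoms = atoms, title = title, source = source),
            class = "sbm_structure")
}

#' Atom coordinates of a structure
#'
#' @param s an `sbm_structure`
#' @return numeric matrix, one row per atom, columns x/y/z in nm
#' @export
coords <- function(s) {
  stopifnot(inherits(s, "sbm_structure"))
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace atom coordinates of a structure
#' @param s an `sbm_structure`
#' @param value numeric n x 3 matrix in nm
#' @export
`coords<-` <- function(s, value) {
  stopifnot(inherits(s, "sbm_structure"),
            is.matrix(value), nrow(value) == nrow(s$atoms), ncol(value) == 3)
  s$atoms$x <- value[, 1]; s$atoms$y <- value[, 2]; s$atoms$z <- value[, 3]
  s
}

#' @export
print.sbm_structure <- function(x, ...) {
  cat(sprintf("<sbm_structure> %d atoms, %d residues, %d chain(s)%s\n",
              nrow(x$atoms), n_residues(x), length(unique(x$atoms$chain)),
              if (nzchar(x$source)) paste0(" [", x$source, "]") else ""))
  invisible(x)
}

#' Number of residues in a structure
#' @param s an `sbm_structure`
#' @export
n_residues <- function(s) {
  length(unique(paste(s$atoms$chain, s$atoms$resid)))
}

# Integer residue identifier per atom (1..n_res, in file order).
residue_index <- function(s) {
  key <- paste(s$atoms$chain, s$atoms$resid)
  match(key, unique(key))
}

#' CA atom indices of a structure (in residue order)
#' @param s an [sbm_structure]
#' @param strict error if some residue lacks a CA atom
#' @export
ca_indices <- function(s, strict = TRUE) {
  idx <- which(s$atoms$name == "CA")
  if (strict && length(idx) != n_residues(s)) {
    stop("structure has residues without a CA atom")
  }
  idx
}

# One-letter sequence of the structure.
structure_sequence <- function(s) {
  first <- !duplicated(paste(s$atoms$chain, s$atoms$resid))
  paste(aa_three_to_one(s$atoms$restype[first]), collapse = "")
}

.is_hydrogen <- function(name, element) {
  el <- toupper(element)
  el == "H" | el == "D" | grepl("^[0-9]*H", toupper(name))
}

#' Parse a PDB-format structure
#'
#' Reads PDB text into an [sbm_structure]: heavy `ATOM` records only
#' (hydrogens are stripped since the force field treats them implicitly),
#' `HETATM` records including waters and ligands are dropped, alternate
#' locations are resolved to the highest-occupancy copy (ties take altloc
#' `"A"`), and coordinates are converted from Angstrom to nm.
#'
#' @param text PDB-format content as a single string or character vector of
#'   lines.
#' @param model_index which model of a multi-model (NMR) entry to use,
#'   counted in file order; default the first.
#' @param chain optional chain id to restrict to.
#' @return an [sbm_structure]
#' @export
parse_pdb <- function(text, model_index = 1L, chain = NULL) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text

  # Line-level validation before delegating to the reader: every ATOM record
  # must carry parseable fixed-column coordinates.
  atom_lines <- grep("^ATOM  ", lines)
  for (ln in atom_lines) {
    l <- lines[ln]
    if (nchar(l) < 54) stop("malformed ATOM record at line ", ln, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (anyNA(xyz)) stop("malformed ATOM record at line ", ln, ": bad coordinates")
  }
  if (length(atom_lines) == 0) stop("no ATOM records in input")

  n_models <- max(1L, length(grep("^MODEL", lines)))
  if (model_index < 1 || model_index > n_models) {
    stop("model ", model_index, " not present (file has ", n_models, " model(s))")
  }

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = n_models > 1L, rm.alt = FALSE,
                         verbose = FALSE)

  at <- pdb$atom
  xyz <- if (n_models > 1L) pdb$xyz[model_index, ] else pdb$xyz[1, ]
  at$x <- xyz[seq(1, length(xyz), 3)][seq_len(nrow(at))]
  at$y <- xyz[seq(2, length(xyz), 3)][seq_len(nrow(at))]
  at$z <- xyz[seq(3, length(xyz), 3)][seq_len(nrow(at))]

  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) {
    at <- at[at$chain %in% chain, , drop = FALSE]
    if (nrow(at) == 0) stop("chain ", chain, " not present")
  }

  el <- at$elesy
  el[is.na(el) | !nzchar(el)] <- .element_from_name(at$elety[is.na(el) | !nzchar(el)])
  keep <- !.is_hydrogen(at$elety, el)
  at <- at[keep, , drop = FALSE]
  el <- el[keep]
  if (nrow(at) == 0) stop("no heavy atoms left after filtering")

  # Altloc resolution: highest occupancy per (chain, residue, atom name),
  # ties resolved toward altloc "A" (then alphabetical).
  alt <- at$alt; alt[is.na(alt)] <- ""
  occ <- at$o; occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -occ, alt != "" & alt != "A", alt)
  at <- at[ord, , drop = FALSE]; el <- el[ord]
  dup <- duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "|"))
  at <- at[!dup, , drop = FALSE]; el <- el[!dup]
  # restore file order
  ord2 <- order(at$eleno)
  at <- at[ord2, , drop = FALSE]; el <- el[ord2]

  atoms <- data.frame(
    name = at$elety, element = toupper(el),
    resid = as.integer(at$resno), restype = toupper(at$resid),
    chain = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
    x = at$x / 10, y = at$y / 10, z = at$z / 10,
    stringsAsFactors = FALSE
  )
  new_structure(atoms, source = "parse_pdb")
}

#' Write a structure as PDB-format text
#'
#' Round-trip safe with [parse_pdb()]: atom names, residues and coordinates
#' are preserved to the PDB precision of 1e-3 Angstrom. If `multi_model` is
#' given, each coordinate frame is written as its own MODEL/ENDMDL block.
#'
#' @param s an [sbm_structure]
#' @param multi_model optional list of n x 3 coordinate matrices (nm)
#' @return PDB text as a single string
#' @export
write_structure <- function(s, multi_model = NULL) {
  stopifnot(inherits(s, "sbm_structure"))
  if (nrow(s$atoms) == 0) stop("empty structure")
  fmt_frame <- function(xyz) {
    a <- s$atoms
    nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            seq_len(nrow(a)), nm, a$restype, a$chain, a$resid,
            xyz[, 1] * 10, xyz[, 2] * 10, xyz[, 3] * 10, 1, 0, a$element)
  }
  if (is.null(multi_model)) {
    out <- c(fmt_frame(coords(s)), "END")
  } else {
    out <- character(0)
    for (i in seq_along(multi_model)) {
      out <- c(out, sprintf("MODEL     %4d", i), fmt_frame(multi_model[[i]]),
               "ENDMDL")
    }
    out <- c(out, "END")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Extract a contiguous residue range
#'
#' Returns the sub-structure covering residues `first_residue` to
#' `last_residue` (inclusive, original numbering preserved).
#'
#' @param s an [sbm_structure]
#' @param first_residue,last_residue residue numbers as in the structure
#' @return an [sbm_structure]
#' @export
extract_fragment <- function(s, first_residue, last_residue) {
  stopifnot(inherits(s, "sbm_structure"))
  if (last_residue < first_residue) stop("empty residue range")
  keep <- s$atoms$resid >= first_residue & s$atoms$resid <= last_residue
  if (!any(keep)) stop("residue range ", first_residue, "-", last_residue,
                       " not present")
  new_structure(s$atoms[keep, , drop = FALSE], title = s$title,
                source = paste0(s$source, ":", first_residue, "-", last_residue))
}
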
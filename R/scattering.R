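# Residue-level Debye scattering: scatterer sites at residue centers of
# mass, solvent-corrected residue form factors, intensity I(q) and its
# analytic coordinate gradient.

.rho_solvent <- 334  # bulk water electron density, e/nm^3

#' Default momentum-transfer grid
#'
#' 50 equidistant q points on \[0.1, 5\] 1/nm — the small-angle range; the
#' model is not meant for wide angles and q is capped at 5 1/nm.
#'
#' @param n number of points
#' @param qmin,qmax range in 1/nm (`qmax` must be <= 5)
#' @export
default_q_grid <- function(n = 50, qmin = 0.1, qmax = 5) {
  if (qmax > 5 + 1e-9) stop("q grid capped at 5 nm^-1 (small-angle regime)")
  if (qmin <= 0 || qmin >= qmax) stop("need 0 < qmin < qmax")
  seq(qmin, qmax, length.out = n)
}

#' Scattering curve container
#'
#' @param q strictly increasing, positive momentum transfer grid (1/nm)
#' @param I intensities (arbitrary units)
#' @param err optional per-point standard deviations (>= 0)
#' @return a `scattering_curve`
#' @export
scattering_curve <- function(q, I, err = NULL) {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I)) stop("q and I lengths differ")
  if (any(q <= 0) || any(diff(q) <= 0)) stop("q must be positive and strictly increasing")
  if (!all(is.finite(I))) stop("non-finite intensities")
  if (!is.null(err)) {
    err <- as.numeric(err)
    if (length(err) != length(q)) stop("err length differs from q")
    if (any(err < 0)) stop("negative errors")
  }
  structure(list(q = q, I = I, err = err), class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %d q points on [%.3g, %.3g] nm^-1%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$err)) "" else " (with errors)"))
  invisible(x)
}

#' Residue scatterer sites
#'
#' One virtual scatterer per residue at the residue's center of mass (unit
#' atom masses, hence the heavy-atom centroid). The atom-to-site weights are
#' kept for chain-ruling scattering gradients back onto atoms.
#'
#' @param x coordinates (n_atoms x 3 nm); default the structure's own
#' @param s an [sbm_structure]
#' @return list with `sites` (m x 3), `site_of_atom`, `weight`, `restype`
#' @export
residue_sites <- function(x = NULL, s) {
  stopifnot(inherits(s, "sbm_structure"))
  if (is.null(x)) x <- coords(s)
  ri <- residue_index(s)
  m <- max(ri)
  cnt <- tabulate(ri, m)
  if (any(cnt == 0)) stop("empty residue in site map")
  w <- 1 / cnt[ri]
  sites <- matrix(0, m, 3)
  for (d in 1:3) sites[, d] <- as.numeric(tapply(x[, d] * w, ri, sum))
  first <- !duplicated(ri)
  list(sites = sites, site_of_atom = ri, weight = w,
       restype = s$atoms$restype[first])
}

#' Solvent-corrected residue form factors
#'
#' Single-Gaussian contrast model: `f_i(q) = c_i exp(-(q R_i)^2 / 2)` with
#' `c_i` the residue electron count minus the displaced-solvent term
#' (bulk water at 334 e/nm^3 times the mean residue volume) and `R_i` the
#' effective residue radius of gyration of a uniform sphere of that volume.
#' The provider is pluggable: any matrix of the same shape (site x q) can
#' replace the default wherever a form-factor table is accepted.
#'
#' @param residue_types character vector of 3-letter codes, one per site
#' @param q momentum-transfer grid (1/nm)
#' @return matrix (length(residue_types) x length(q)) with attributes
#'   `contrast` and `radius`
#' @export
default_form_factors <- function(residue_types, q) {
  residue_types <- toupper(residue_types)
  bad <- !residue_types %in% names(.aa_electrons)
  if (any(bad)) stop("unknown residue type(s): ",
                     paste(unique(residue_types[bad]), collapse = ", "))
  vol_nm3 <- .aa_volumes_A3[residue_types] * 1e-3
  contrast <- .aa_electrons[residue_types] - .rho_solvent * vol_nm3
  r_sphere <- (3 * vol_nm3 / (4 * pi))^(1 / 3)
  radius <- sqrt(3 / 5) * r_sphere
  Fm <- outer(seq_along(residue_types), seq_along(q), function(i, k) {
    contrast[i] * exp(-(q[k] * radius[i])^2 / 2)
  })
  attr(Fm, "contrast") <- unname(contrast)
  attr(Fm, "radius") <- unname(radius)
  Fm
}

.as_sites_matrix <- function(sites) {
  if (is.list(sites) && !is.null(sites$sites)) sites$sites else as.matrix(sites)
}

#' Debye scattering intensity
#'
#' Exact double-sum Debye formula
#' `I(q) = sum_ij f_i(q) f_j(q) sin(q r_ij) / (q r_ij)` with the
#' `sin(x)/x -> 1` limit at coincident sites and q -> 0.
#'
#' @param sites m x 3 site positions (nm) or the result of [residue_sites()]
#' @param ff form-factor matrix (m x length(q)), e.g.
#'   [default_form_factors()]
#' @param q momentum-transfer grid (1/nm)
#' @return a [scattering_curve()]
#' @export
debye_intensity <- function(sites, ff, q) {
  sm <- .as_sites_matrix(sites)
  if (nrow(sm) < 1) stop("need at least one site")
  I <- .debye_intensity_cpp(sm, ff, q)
  scattering_curve(q, I)
}

#' Gradient of the Debye intensity with respect to site positions
#'
#' @inheritParams debye_intensity
#' @return array with dim (length(q), m, 3): dI(q)/d(site i, coordinate d)
#' @export
debye_gradient <- function(sites, ff, q) {
  sm <- .as_sites_matrix(sites)
  .debye_gradient_cpp(sm, ff, q)
}

#' Scattering curve of a structure
#'
#' Convenience wrapper: residue sites + default form factors + Debye sum.
#'
#' @param s an [sbm_structure]
#' @param q momentum-transfer grid (default [default_q_grid()])
#' @param x optional coordinates overriding the structure's own
#' @return a [scattering_curve()]
#' @export
structure_intensity <- function(s, q = default_q_grid(), x = NULL) {
  rs <- residue_sites(x, s)
  ff <- default_form_factors(rs$restype, q)
  debye_intensity(rs, ff, q)
}

#' Read a scattering curve from a 2-3 column text file
#'
#' Whitespace- or comma-separated columns: q (1/nm), I, and optionally the
#' per-point standard deviation.
#'
#' @param path input file
#' @return a [scattering_curve()]
#' @export
read_curve <- function(path) {
  first <- readLines(path, n = 5)
  sep <- if (any(grepl(",", first))) "," else ""
  d <- utils::read.table(path, sep = sep, comment.char = "#")
  if (ncol(d) < 2) stop("curve file needs at least 2 columns (q, I)")
  scattering_curve(d[[1]], d[[2]], if (ncol(d) >= 3) d[[3]] else NULL)
}

#' Write a scattering curve as plain text
#' @param curve a [scattering_curve()]
#' @param path output file
#' @export
write_curve <- function(curve, path) {
  m <- cbind(curve$q, curve$I)
  if (!is.null(curve$err)) m <- cbind(m, curve$err)
  utils::write.table(format(m, digits = 12), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
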
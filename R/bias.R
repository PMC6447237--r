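# The chi-square scattering bias: target-data construction (clean and
# noisy), per-q weighting from experimental errors, the bias energy
# V_XS = (k_chi / 2) chi^2 and its analytic forces on atoms.

#' Artificial difference-scattering target from two structures
#'
#' The reference intensity is the Debye curve of the initial structure; the
#' difference target is the target-state curve minus that reference, so by
#' construction `dI_exp + I_ref` equals the target intensity exactly.
#'
#' @param init initial-state [sbm_structure] (the simulation's reference)
#' @param target target-state [sbm_structure]
#' @param q momentum-transfer grid (1/nm)
#' @return list with `dI_exp` and `I_ref`, both [scattering_curve()]
#' @export
make_difference_target <- function(init, target, q = default_q_grid()) {
  I_ref <- structure_intensity(init, q)
  I_tgt <- structure_intensity(target, q)
  list(dI_exp = scattering_curve(q, I_tgt$I - I_ref$I), I_ref = I_ref)
}

#' Blur a scattering curve with counting-statistics noise
#'
#' Each intensity is replaced by a Gaussian draw with mean the clean value
#' and standard deviation its square root; the stored per-point error is
#' that standard deviation. Deterministic for a fixed seed.
#'
#' @param curve a [scattering_curve()] with non-negative intensities
#' @param seed integer seed
#' @return a [scattering_curve()] with `err` filled in
#' @export
add_noise <- function(curve, seed) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (any(curve$I < 0)) stop("negative input intensity")
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(as.integer(seed))
  sdv <- sqrt(curve$I)
  scattering_curve(curve$q, stats::rnorm(length(curve$I), curve$I, sdv), sdv)
}

#' Noisy difference data from two blurred absolute curves
#'
#' The difference is blurred target minus blurred reference; its error is
#' propagated as the sum of the two Gaussians' absolute standard deviations.
#'
#' @param ref_blur,target_blur blurred [scattering_curve()]s with errors
#' @return list with `dI_exp` (difference curve carrying `err` = sigma_Delta)
#' @export
noisy_difference <- function(ref_blur, target_blur) {
  if (!isTRUE(all.equal(ref_blur$q, target_blur$q))) stop("q grids differ")
  if (is.null(ref_blur$err) || is.null(target_blur$err)) {
    stop("blurred curves must carry errors (see add_noise)")
  }
  scattering_curve(ref_blur$q, target_blur$I - ref_blur$I,
                   ref_blur$err + target_blur$err)
}

#' Per-q weights from experimental errors
#'
#' `sigma_q = sigma(q) / max(|signal(q)|, delta) + 1`, computed preferably
#' from errors in the difference data (signal = dI_exp), falling back to
#' errors in the reference curve (signal = I_ref). With no errors all
#' weights are 1. Relative errors grow with scattering angle, so wide-angle
#' points are naturally down-weighted.
#'
#' @param errors per-q standard deviations, or NULL for unweighted data
#' @param signal the matching curve values (difference or reference
#'   intensities)
#' @param guard_frac the zero-crossing guard delta as a fraction of
#'   max(|signal|)
#' @return numeric vector sigma_q (>= 1)
#' @export
sigma_weights <- function(errors, signal, guard_frac = 1e-6) {
  n <- length(signal)
  if (is.null(errors)) return(rep(1, n))
  if (length(errors) != n) stop("errors and signal lengths differ")
  delta <- guard_frac * max(abs(signal))
  if (delta == 0) delta <- guard_frac
  errors / pmax(abs(signal), delta) + 1
}

#' Scattering-bias configuration
#'
#' Bundles everything the chi-square bias needs: the coupling `k_chi` (in
#' eps), the transition fraction `alpha`, the difference target, the
#' reference intensity of the initial structure, and the per-q weights. By
#' default the weights come from the difference curve's own errors
#' ([sigma_weights()]), or are all 1 for clean data.
#'
#' @param k_chi bias weight in eps (0 switches the bias off)
#' @param dI_exp difference-scattering target, a [scattering_curve()]
#'   (its `err`, when present, provides sigma_Delta)
#' @param I_ref reference intensity of the initial structure
#' @param alpha fraction of the sample undergoing the transition, in (0, 1]
#' @param sigma optional explicit per-q weights (overrides the default)
#' @param weight_from use `"difference"` errors (preferred) or
#'   `"reference"` errors for the weights
#' @return a `bias_config`
#' @export
bias_config <- function(k_chi, dI_exp, I_ref, alpha = 1, sigma = NULL,
                        weight_from = c("difference", "reference")) {
  weight_from <- match.arg(weight_from)
  stopifnot(inherits(dI_exp, "scattering_curve"),
            inherits(I_ref, "scattering_curve"))
  if (!isTRUE(all.equal(dI_exp$q, I_ref$q))) stop("q grids differ")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (k_chi < 0) stop("k_chi must be >= 0")
  if (is.null(sigma)) {
    sigma <- if (weight_from == "difference") {
      sigma_weights(dI_exp$err, dI_exp$I)
    } else {
      sigma_weights(I_ref$err, I_ref$I)
    }
  }
  if (any(sigma <= 0)) stop("sigma_q must be > 0")
  structure(list(k_chi = k_chi, alpha = alpha, q = dI_exp$q,
                 dI_exp = dI_exp$I, I_ref = I_ref$I, sigma = sigma),
            class = "bias_config")
}

#' @export
print.bias_config <- function(x, ...) {
  cat(sprintf("<bias_config> k_chi=%.3g eps, alpha=%g, %d q points\n",
              x$k_chi, x$alpha, length(x$q)))
  invisible(x)
}

#' Chi-square dissimilarity of a computed curve to the target
#'
#' `chi^2 = sum_q [ (dI_exp - alpha (I_calc - I_ref)) / sigma_q ]^2`
#'
#' @param I_calc computed intensities: a [scattering_curve()] or numeric
#'   vector on the config's q grid
#' @param cfg a [bias_config()]
#' @return non-negative scalar
#' @export
chi_square <- function(I_calc, cfg) {
  stopifnot(inherits(cfg, "bias_config"))
  I <- if (inherits(I_calc, "scattering_curve")) {
    if (!isTRUE(all.equal(I_calc$q, cfg$q))) stop("q grids differ")
    I_calc$I
  } else {
    if (length(I_calc) != length(cfg$q)) stop("q grids differ")
    as.numeric(I_calc)
  }
  sum(((cfg$dI_exp - cfg$alpha * (I - cfg$I_ref)) / cfg$sigma)^2)
}

# Assemble the C++-facing bias description for a structure.
.bias_cpp_spec <- function(s, cfg, ff = NULL) {
  rs <- residue_sites(NULL, s)
  if (is.null(ff)) ff <- default_form_factors(rs$restype, cfg$q)
  if (nrow(ff) != nrow(rs$sites) || ncol(ff) != length(cfg$q)) {
    stop("form-factor table shape does not match sites/q")
  }
  list(site_of_atom = as.integer(rs$site_of_atom), weight = rs$weight,
       F = ff, q = cfg$q, I_ref = cfg$I_ref, dI_exp = cfg$dI_exp,
       sigma = cfg$sigma, k_chi = cfg$k_chi, alpha = cfg$alpha)
}

#' Bias energy and forces on atoms
#'
#' `V_XS = (k_chi / 2) chi^2` of the current conformation's residue-level
#' Debye curve; forces are the exact analytic gradient, chain-ruled from the
#' scatterer sites onto each residue's atoms with the site weights.
#'
#' @param x atom coordinates, n x 3 (nm)
#' @param s the [sbm_structure] defining the residue-site map
#' @param cfg a [bias_config()]
#' @param ff optional form-factor matrix overriding the default
#' @return list with `V_XS` (eps), `chi2`, `forces` (n x 3, eps/nm)
#' @export
bias_energy_forces <- function(x, s, cfg, ff = NULL) {
  stopifnot(inherits(cfg, "bias_config"))
  spec <- .bias_cpp_spec(s, cfg, ff)
  r <- .bias_eval_cpp(x, spec)  # sites are recomputed from x inside
  list(V_XS = r$V_XS, chi2 = r$chi2, forces = r$forces)
}
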
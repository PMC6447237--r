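# Trajectory and result metrics: optimal-superposition RMSD, shape
# descriptors from the gyration tensor, end-to-end statistics, bias/RMSD
# correlation, time-to-target, and the summary report.

#' Kabsch RMSD under optimal superposition
#'
#' Minimal root-mean-square deviation between two point sets over all rigid
#' superpositions (optimal translation plus proper rotation via SVD).
#'
#' @param a,b coordinate matrices of equal size (>= 3 points, nm)
#' @return RMSD in nm
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  if (nrow(a) < 3) stop("need at least 3 points")
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  H <- crossprod(ac, bc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  dif <- bc - ac %*% t(R)
  sqrt(sum(dif^2) / nrow(a))
}

#' Per-frame CA RMSD of a trajectory to a reference structure
#'
#' @param traj an `sbm_trajectory`
#' @param ref reference [sbm_structure] with the same residues
#' @return numeric vector, one RMSD (nm) per frame
#' @export
rmsd_series <- function(traj, ref) {
  sel_t <- ca_indices(traj$structure)
  sel_r <- ca_indices(ref)
  if (length(sel_t) != length(sel_r)) stop("CA selections differ in size")
  xr <- coords(ref)[sel_r, , drop = FALSE]
  vapply(seq_len(dim(traj$frames)[1]), function(i) {
    kabsch_rmsd(frame_coords(traj, i)[sel_t, , drop = FALSE], xr)
  }, numeric(1))
}

#' End-to-end distance
#'
#' Euclidean distance between the first and last CA atoms.
#'
#' @param x coordinates (n x 3 nm); default the structure's own
#' @param s an [sbm_structure] with >= 2 residues
#' @return distance in nm
#' @export
end_to_end <- function(x = NULL, s) {
  stopifnot(inherits(s, "sbm_structure"))
  if (is.null(x)) x <- coords(s)
  idx <- ca_indices(s)
  if (length(idx) < 2) stop("need at least 2 residues with CA atoms")
  sqrt(sum((x[idx[1], ] - x[idx[length(idx)], ])^2))
}

.gyration_eigs <- function(x, masses = NULL) {
  x <- as.matrix(x)
  if (is.null(masses)) masses <- rep(1, nrow(x))
  w <- masses / sum(masses)
  mu <- colSums(x * w)
  xc <- sweep(x, 2, mu)
  S <- crossprod(xc * w, xc)  # mass-weighted gyration tensor
  sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Radius of gyration
#'
#' From the gyration-tensor eigenvalues: Rg^2 = l1 + l2 + l3.
#'
#' @param x coordinates (n x 3 nm)
#' @param masses optional weights (default: unit masses)
#' @return Rg in nm
#' @export
radius_of_gyration <- function(x, masses = NULL) {
  sqrt(sum(.gyration_eigs(x, masses)))
}

#' Asphericity
#'
#' Normalized gyration-tensor anisotropy
#' `A = [(l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2] / (2 (l1+l2+l3)^2)`, in
#' \[0, 1\]: 0 for spherically symmetric mass distributions, 1 for a rod.
#'
#' @inheritParams radius_of_gyration
#' @return dimensionless asphericity
#' @export
asphericity <- function(x, masses = NULL) {
  if (nrow(as.matrix(x)) < 2) stop("asphericity undefined for a single point")
  l <- .gyration_eigs(x, masses)
  s <- sum(l)
  if (s == 0) stop("degenerate (zero-extent) configuration")
  ((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[3] - l[1])^2) / (2 * s^2)
}

#' Earliest time below a target-RMSD threshold
#'
#' @param rmsd per-frame target RMSD series (nm)
#' @param times matching frame times (reduced units)
#' @param threshold RMSD threshold in nm (default 0.2)
#' @return earliest time with RMSD < threshold, or NA if never reached
#' @export
tau_to_target <- function(rmsd, times, threshold = 0.2) {
  if (length(rmsd) != length(times)) stop("series lengths differ")
  hit <- which(rmsd < threshold)
  if (length(hit) == 0) return(NA_real_)
  times[hit[1]]
}

#' Summarize a (guided) trajectory against initial and target structures
#'
#' Computes the standard result parameters of a scattering-guided run:
#' per-frame initial and target RMSD (CA level), the minimum target RMSD
#' and its frame, the minimum and average bias energy, average chi^2,
#' the Pearson correlation of V_XS with target RMSD, the time to first
#' reach a target RMSD below `threshold`, the target RMSD at the
#' minimum-V_XS frame, the RMSD between the best-by-RMSD and best-by-V_XS
#' structures, and per-frame radius of gyration, asphericity and
#' end-to-end series.
#'
#' @param traj an `sbm_trajectory`
#' @param initial,target reference [sbm_structure]s
#' @param threshold target-RMSD threshold for the time-to-target (nm)
#' @param burn_in fraction of initial frames excluded from the V_XS and
#'   chi^2 averages (default 0: full-trajectory averages)
#' @return an `sbm_report` (list; see Details)
#' @export
summarize_trajectory <- function(traj, initial, target, threshold = 0.2,
                                 burn_in = 0) {
  stopifnot(inherits(traj, "sbm_trajectory"))
  nf <- dim(traj$frames)[1]
  keep <- seq_len(nf) > floor(burn_in * nf)
  rmsd_tgt <- rmsd_series(traj, target)
  rmsd_ini <- rmsd_series(traj, initial)
  vxs <- traj$energies$V_XS
  chi2 <- traj$energies$chi2
  i_best <- which.min(rmsd_tgt)
  i_vmin <- which.min(vxs)
  sel <- ca_indices(traj$structure)
  x_best <- frame_coords(traj, i_best)[sel, , drop = FALSE]
  x_vmin <- frame_coords(traj, i_vmin)[sel, , drop = FALSE]

  rho <- if (nf > 1 && sd(vxs) > 0 && sd(rmsd_tgt) > 0) {
    stats::cor(vxs, rmsd_tgt)
  } else NA_real_

  shape <- t(vapply(seq_len(nf), function(i) {
    xi <- frame_coords(traj, i)
    c(radius_of_gyration(xi), asphericity(xi),
      end_to_end(xi, traj$structure))
  }, numeric(3)))

  structure(list(
    times = traj$times,
    rmsd_target = rmsd_tgt, rmsd_initial = rmsd_ini,
    rmsd_target_min = rmsd_tgt[i_best], frame_rmsd_min = i_best,
    rmsd_initial_at_min = rmsd_ini[i_best],
    V_XS_min = vxs[i_vmin], frame_vxs_min = i_vmin,
    V_XS_av = mean(vxs[keep]), chi2_av = mean(chi2[keep]),
    rmsd_target_at_vxs_min = rmsd_tgt[i_vmin],
    rmsd_between_best = kabsch_rmsd(x_best, x_vmin),
    pearson_rho = rho,
    tau_to_target = tau_to_target(rmsd_tgt, traj$times, threshold),
    rg = shape[, 1], asphericity = shape[, 2], end_to_end = shape[, 3]
  ), class = "sbm_report")
}

#' @export
print.sbm_report <- function(x, ...) {
  cat("<sbm_report>\n")
  cat(sprintf("  min target RMSD   : %.3f nm (frame %d)\n",
              x$rmsd_target_min, x$frame_rmsd_min))
  cat(sprintf("  target RMSD @Vmin : %.3f nm\n", x$rmsd_target_at_vxs_min))
  cat(sprintf("  V_XS av / min     : %.3g / %.3g eps\n", x$V_XS_av, x$V_XS_min))
  cat(sprintf("  chi2 av           : %.3g\n", x$chi2_av))
  cat(sprintf("  Pearson rho       : %s\n",
              ifelse(is.na(x$pearson_rho), "-", sprintf("%.2f", x$pearson_rho))))
  cat(sprintf("  tau to target     : %s\n",
              ifelse(is.na(x$tau_to_target), "-",
                     sprintf("%.4g", x$tau_to_target))))
  invisible(x)
}

#' Write a trajectory report to CSV (per-frame series) and JSON (scalars)
#'
#' @param report an `sbm_report`
#' @param prefix output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`
#' @export
write_report <- function(report, prefix) {
  stopifnot(inherits(report, "sbm_report"))
  series <- data.frame(time = report$times, rmsd_target = report$rmsd_target,
                       rmsd_initial = report$rmsd_initial, rg = report$rg,
                       asphericity = report$asphericity,
                       end_to_end = report$end_to_end)
  utils::write.table(series, paste0(prefix, ".csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  scalars <- report[c("rmsd_target_min", "rmsd_initial_at_min", "V_XS_min",
                      "V_XS_av", "chi2_av", "rmsd_target_at_vxs_min",
                      "rmsd_between_best", "pearson_rho", "tau_to_target")]
  jsonlite::write_json(scalars, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(prefix)
}
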
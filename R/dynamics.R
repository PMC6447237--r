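# Langevin dynamics in reduced units driving V = V_SB + V_XS, plus the
# (T, k_chi) grid-search driver used for parameter calibration.

# Boltzmann constant in eps per reduced temperature unit. With the
# contact+dihedral normalization, folding temperatures sit near k_B T = 1,
# i.e. around 120 reduced temperature units.
.kB <- 0.00831451

#' Boltzmann constant of the reduced unit system
#' @return eps per reduced temperature unit (0.00831451)
#' @export
boltzmann_constant <- function() .kB

#' Simulation configuration
#'
#' @param temperature reduced temperature (thermal energy = 0.00831451 *
#'   temperature eps, so T = 120 corresponds to about 1 eps)
#' @param dt integration time step in reduced time (default 5e-4)
#' @param friction Langevin friction in inverse reduced time (default 1;
#'   0 gives NVE velocity-Verlet dynamics)
#' @param n_steps number of integration steps
#' @param out_stride record every `out_stride` steps (frame 0 included)
#' @param seed integer seed controlling initial velocities and the
#'   thermostat noise; identical (config, seed) gives bitwise-identical
#'   trajectories
#' @param bias_stride recompute the scattering bias every `bias_stride`
#'   steps (forces are reused in between)
#' @return a `sim_config`
#' @export
sim_config <- function(temperature = 90, dt = 5e-4, friction = 1,
                       n_steps = 10000L, out_stride = 100L, seed = 1L,
                       bias_stride = 1L) {
  stopifnot(dt > 0, n_steps >= 0, temperature >= 0, friction >= 0,
            out_stride >= 1, bias_stride >= 1)
  structure(list(temperature = temperature, dt = dt, friction = friction,
                 n_steps = as.integer(n_steps),
                 out_stride = as.integer(out_stride),
                 seed = as.integer(seed),
                 bias_stride = as.integer(bias_stride)),
            class = "sim_config")
}

.energy_cols <- c("bond", "angle", "improper", "proper", "contact",
                  "nonnative", "V_SB", "V_XS", "chi2", "kinetic",
                  "kT_inst", "total")

#' Run a (scattering-guided) structure-based simulation
#'
#' Langevin (BAOAB) dynamics with unit masses under the structure-based
#' potential, optionally extended by the chi-square scattering bias.
#' Initial coordinates are the structure's own; initial velocities are
#' Maxwell-Boltzmann at the run temperature under the run seed. Per output
#' frame the full energy breakdown, V_XS and chi^2 are recorded (0 and the
#' unbiased chi^2 when `bias` has `k_chi = 0`; both absent-as-zero without
#' a bias).
#'
#' @param s initial [sbm_structure]
#' @param top `sbm_topology` built from the native structure
#' @param cfg a [sim_config()]
#' @param bias optional [bias_config()]
#' @param x0 optional initial coordinates overriding `coords(s)`
#' @param ff optional form-factor matrix for the bias
#' @return an `sbm_trajectory`: `frames` (n_frames x n_atoms x 3), `times`,
#'   `energies` (data.frame with one row per frame), plus the run metadata
#' @export
run_simulation <- function(s, top, cfg, bias = NULL, x0 = NULL, ff = NULL) {
  stopifnot(inherits(s, "sbm_structure"), inherits(top, "sbm_topology"),
            inherits(cfg, "sim_config"))
  n <- top$n_atoms
  if (nrow(s$atoms) != n) stop("structure does not match topology")
  if (is.null(x0)) x0 <- coords(s)
  kT <- .kB * cfg$temperature

  set.seed(cfg$seed)
  v0 <- matrix(stats::rnorm(3 * n, sd = sqrt(max(kT, 0))), n, 3)

  bias_spec <- if (!is.null(bias)) .bias_cpp_spec(s, bias, ff) else NULL
  raw <- .run_langevin_cpp(x0, v0, unclass(top), cfg$dt, cfg$friction, kT,
                           cfg$n_steps, cfg$out_stride, bias_spec,
                           cfg$bias_stride)

  nf <- raw$n_frames_recorded
  frames <- raw$frames[seq_len(nf), , , drop = FALSE]
  en <- as.data.frame(raw$energies[seq_len(nf), , drop = FALSE])
  names(en) <- .energy_cols
  traj <- structure(list(
    frames = frames, times = raw$times[seq_len(nf)], energies = en,
    structure = s, config = cfg, bias = bias,
    status = raw$status, last_stable_step = raw$last_stable_step
  ), class = "sbm_trajectory")

  if (raw$status != "ok") {
    cond <- structure(class = c("saxsbm_integration_error", "error",
                                "condition"),
                      list(message = paste0(
                        "integrator failure (non-finite state) at step ",
                        raw$last_stable_step + 1,
                        "; excessive bias weight is the usual cause"),
                        call = sys.call(-1), trajectory = traj))
    stop(cond)
  }
  traj
}

#' @export
print.sbm_trajectory <- function(x, ...) {
  cat(sprintf("<sbm_trajectory> %d frames x %d atoms, t = [0, %.4g], status %s\n",
              dim(x$frames)[1], dim(x$frames)[2], max(x$times), x$status))
  invisible(x)
}

#' Coordinates of one trajectory frame
#' @param traj an `sbm_trajectory`
#' @param i frame index (1-based)
#' @return n_atoms x 3 matrix (nm)
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "sbm_trajectory"))
  matrix(traj$frames[i, , ], ncol = 3)
}

#' Grid search over temperature and bias weight
#'
#' Runs one (or `reps`) guided simulations per (T, k_chi) combination and
#' tabulates the quantities used to calibrate the coupling: minimum
#' target RMSD, average bias energy and average chi^2 over the run.
#' Integrator blow-ups (excessive k_chi) are recorded as NA rows rather
#' than aborting the scan.
#'
#' @param s initial [sbm_structure]
#' @param top topology of the native (initial) structure
#' @param target target-state [sbm_structure] (same atoms)
#' @param dI_exp,I_ref difference target and reference intensity, as from
#'   [make_difference_target()]
#' @param T_list temperatures to scan (reduced units)
#' @param kchi_list bias weights to scan (eps)
#' @param cfg base [sim_config()] (temperature/seed fields are overridden)
#' @param reps replicate runs per grid point (seeds seed, seed+1, ...)
#' @param seed base seed
#' @return data.frame with one row per (T, k_chi, rep)
#' @export
grid_search <- function(s, top, target, dI_exp, I_ref, T_list, kchi_list,
                        cfg = sim_config(), reps = 1L, seed = 1L) {
  stopifnot(length(T_list) >= 1, length(kchi_list) >= 1)
  sel_ref <- ca_indices(s)
  sel_tgt <- ca_indices(target)
  xt <- coords(target)[sel_tgt, , drop = FALSE]
  rows <- list()
  run_id <- 0L
  for (temp in T_list) for (kchi in kchi_list) for (rep in seq_len(reps)) {
    run_id <- run_id + 1L
    cfg_i <- cfg
    cfg_i$temperature <- temp
    cfg_i$seed <- as.integer(seed + rep - 1L)
    b <- bias_config(kchi, dI_exp, I_ref)
    res <- tryCatch({
      traj <- run_simulation(s, top, cfg_i, bias = b)
      rmsd <- vapply(seq_len(dim(traj$frames)[1]), function(i) {
        kabsch_rmsd(frame_coords(traj, i)[sel_ref, , drop = FALSE], xt)
      }, numeric(1))
      data.frame(T = temp, k_chi = kchi, rep = rep,
                 min_target_rmsd = min(rmsd),
                 V_XS_av = mean(traj$energies$V_XS),
                 chi2_av = mean(traj$energies$chi2),
                 status = "ok", stringsAsFactors = FALSE)
    }, saxsbm_integration_error = function(e) {
      data.frame(T = temp, k_chi = kchi, rep = rep,
                 min_target_rmsd = NA_real_, V_XS_av = NA_real_,
                 chi2_av = NA_real_, status = "blowup",
                 stringsAsFactors = FALSE)
    })
    rows[[run_id]] <- res
  }
  do.call(rbind, rows)
}
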
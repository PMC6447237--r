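# saxsbm — scattering-guided structure-based molecular dynamics

`saxsbm` refines atomistic protein models against small-angle X-ray
scattering (SAXS) difference data by running native structure-based
("Gō-type") molecular dynamics under a differentiable scattering bias. It
is aimed at structural biologists and method developers who have an
initial structure and a (measured or synthetic) difference-scattering
curve for a conformational transition, and want physically plausible
atomistic models of the end state at a fraction of the cost of biased
explicit-solvent MD.

The total potential is

    V = V_SB + (k_chi / 2) * chi^2,

where `V_SB` is an all-atom structure-based potential (harmonic bonds,
angles and impropers, a 1/3-multiplicity torsion term, Lennard-Jones-like
native contacts with `i > j + 3` sequence separation, and `(sigma/r)^12`
non-native repulsion; contact and dihedral energies normalized 2:1 with
total equal to the atom count), and

    chi^2 = sum_q [ (dI_exp(q) - alpha * (I_calc(q) - I_ref(q))) / sigma_q ]^2

compares the residue-level Debye intensity `I_calc` of the current
conformation against the difference target `dI_exp` relative to the
initial structure's reference curve `I_ref`. Bias forces are exact
analytic gradients of the Debye sum, chain-ruled from residue
center-of-mass scatterers onto atoms. Dynamics are Langevin (BAOAB) in
reduced units with `kB = 0.00831451` energy units per reduced temperature
unit. Everything is seed-deterministic.

## Worked example

A 12-bead two-state polymer (compact hairpin vs fully extended chain),
guided from the hairpin toward the extended state's scattering:

```r
library(saxsbm)

two <- build_two_state_polymer(12, seed = 1)
top <- build_topology(two$hairpin, sbm_constants(cutoff = 0.5))
td  <- make_difference_target(two$hairpin, two$extended)

cfg  <- sim_config(temperature = 70, n_steps = 3e4, out_stride = 200, seed = 1)
traj <- run_simulation(two$hairpin, top, cfg,
                       bias = bias_config(1e-7, td$dI_exp, td$I_ref))
summarize_trajectory(traj, two$hairpin, two$extended)
```

```
<sbm_report>
  min target RMSD   : 0.188 nm (frame 98)
  target RMSD @Vmin : 0.210 nm
  V_XS av / min     : 4.96 / 0.272 eps
  chi2 av           : 9.93e+07
  Pearson rho       : 0.98
  tau to target     : 8.6
```

The two states differ by 1.32 nm RMSD; the guided run approaches the
target to 0.19 nm (a free simulation of the same length never gets below
~1.1 nm), the bias energy tracks the target RMSD (Pearson rho 0.98), and
the first sub-0.2 nm structure appears at 8.6 reduced time units. The
same workflow applies to real two-state proteins parsed from PDB files
with `parse_pdb()`; calibrate `(T, k_chi)` per system with
`grid_search()` because the useful coupling scale depends on the
form-factor parameterization and the system size.

A command-line interface wrapping the same functions (subcommands
`fixtures`, `build`, `scatter`, `makediff`, `addnoise`, `run`,
`gridsearch`, `analyze`, `pipeline`) is installed at
`system.file("cli", "saxsbm", package = "saxsbm")`.

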
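---
title: "Scattering-guided structure-based simulations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scattering-guided structure-based simulations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsbm)
```

## The problem

Small-angle X-ray scattering (SAXS) measures a spatially averaged,
one-dimensional intensity $I(q)$ from macromolecules in solution. The curve
encodes low-resolution size and shape information — typically only tens of
independent points — so it cannot by itself determine an atomistic model.
`saxsbm` interprets such data by integrating it into molecular simulation:
a native structure-based ("Gō-type") model supplies the physico-chemical
prior, and a differentiable bias term pulls the simulation toward
conformations whose computed scattering matches a target *difference*
curve. The result is a physically plausible atomistic trajectory that
reconciles a known starting structure with the scattering signature of an
unknown (or target) state.

## The potential

The total potential is $V = V_\mathrm{SB} + V_\mathrm{XS}$.

**Structure-based part.** $V_\mathrm{SB}$ is an all-atom (heavy atoms only,
unit masses) structure-based potential whose global minimum is the input
native structure:

$$V_\mathrm{SB} = \sum_\mathrm{bonds} K_b (r - r_0)^2
 + \sum_\mathrm{angles} K_a (\vartheta - \vartheta_0)^2
 + \sum_\mathrm{impropers} K_i (\chi - \chi_0)^2
 + \sum_\mathrm{dihedrals} K_d \left[(1 - \cos\Delta\phi)
   + \tfrac12 (1 - \cos 3\Delta\phi)\right]$$
$$\quad + \sum_\mathrm{contacts} K_c \left[\left(\tfrac{\sigma^0_{ij}}{r_{ij}}\right)^{12}
   - 2 \left(\tfrac{\sigma^0_{ij}}{r_{ij}}\right)^{6}\right]
 + \sum_\mathrm{non\text{-}native} K_{nc} \left(\tfrac{\tilde\sigma}{r_{ij}}\right)^{12}.$$

All reference values ($r_0$, $\vartheta_0$, $\chi_0$, $\phi_0$,
$\sigma^0_{ij}$) are measured from the native coordinates. Native contacts
are heavy-atom pairs within 0.45 nm whose residues are more than three
positions apart in sequence. Defaults (in the reduced energy unit
$\varepsilon$): $K_b = 20000\ \varepsilon/\mathrm{nm}^2$,
$K_a = K_i = 40\ \varepsilon/\mathrm{rad}^2$,
$K_{nc} = 0.01\ \varepsilon$, $\tilde\sigma = 0.25$ nm. The per-term
contact and dihedral weights are uniform and normalized so that the total
contact energy and total dihedral energy stand in a 2:1 ratio and sum to
the number of atoms — the conventional calibration that places folding
temperatures near $k_BT = 1$, i.e. near 120 reduced temperature units with
$k_B = 0.00831451\ \varepsilon$ per temperature unit.

**Scattering bias.** With a residue-level Debye model of the intensity,
$$I(q) = \sum_{i,j} f_i(q) f_j(q)\,
  \frac{\sin(q r_{ij})}{q r_{ij}},$$
the bias is $V_\mathrm{XS} = \frac{k_\chi}{2} \chi^2$ with
$$\chi^2 = \sum_q \left[\frac{\Delta I_\mathrm{exp}(q)
  - \alpha\,\{I_\mathrm{calc}(q) - I_\mathrm{ref}(q)\}}{\sigma_q}\right]^2 .$$
$I_\mathrm{ref}$ is the intensity of the initial structure,
$\Delta I_\mathrm{exp}$ the difference target, $\alpha \in (0, 1]$ the
fraction of the sample undergoing the transition (default 1: in the
validation setting the whole simulated system transitions), and $k_\chi$
(in $\varepsilon$) the coupling. Forces are the exact analytic gradient:
the Debye gradient with respect to the residue scatterer sites is
chain-ruled onto atoms through the center-of-mass site weights.

Scatterers sit at each residue's heavy-atom centroid. Form factors use a
single-Gaussian contrast model $f_i(q) = c_i e^{-(q R_i)^2/2}$, where
$c_i$ is the residue electron count minus displaced solvent
(334 e/nm$^3$ bulk water times the mean residue volume) and $R_i$ the
radius of gyration of an equivalent uniform sphere. Published multi-term
residue form-factor tables differ in detail; the table is therefore a
plain matrix argument that can be swapped for any other parameterization.
Two consequences are worth keeping in mind. First, difference-curve
guiding is robust to the solvation detail, which is why no hydration-shell
term is included anywhere. Second, the absolute intensity scale — and
hence the useful magnitude of $k_\chi$ — is parameterization-dependent:
couplings must be calibrated per system and per form-factor table with
`grid_search()`, not copied between studies.

The momentum-transfer grid is capped at $q \le 5\ \mathrm{nm}^{-1}$: the
model is residue-grained and only the small-angle regime carries the
global shape information being fitted. The default grid has 50 equidistant
points on $[0.1, 5]\ \mathrm{nm}^{-1}$.

## Error model and per-point weights

Synthetic "experimental" targets can be blurred with counting-statistics
noise: each clean intensity is replaced by a Gaussian draw with standard
deviation $\sqrt{I}$ (`add_noise()`), and difference-curve errors
propagate as the *sum* of the two standard deviations
(`noisy_difference()`). Weights follow
$\sigma_q = \sigma_\Delta(q)/|\Delta I_\mathrm{exp}(q)| + 1$ (difference
errors preferred; the analogous reference-curve form is available behind
the `weight_from` switch), so noisy wide-angle points are naturally
down-weighted and error-free data reduce exactly to $\sigma_q \equiv 1$.
A guard of $10^{-6} \max_q |\Delta I|$ in the denominator protects the
zero crossings of difference curves.

## Dynamics

Langevin dynamics in reduced units with the BAOAB splitting; with friction
zero this reduces exactly to velocity Verlet, which is how the NVE
conservation test exercises the integrator core. Defaults:
$dt = 5\times10^{-4}$ reduced time, friction $1$ per reduced time, initial
velocities Maxwell–Boltzmann at the run temperature. All randomness
(velocities and thermostat noise) flows from one integer seed; identical
configurations and seeds give bitwise-identical trajectories. The bias can
be re-evaluated every `bias_stride` steps, with forces reused in between;
the default is every step.

An excessive $k_\chi$ produces forces the integrator cannot follow. The
engine detects the resulting non-finite (or absurdly distant, beyond
$10^4$ nm) coordinates and raises a structured
`saxsbm_integration_error` carrying the last stable frames; `grid_search()`
records such runs as undefined cells rather than aborting the scan.

## Synthetic fixtures and what they do (not) show

All tests run offline on generated structures:

- **Ideal helices** (`build_ideal_helix()`): backbone at
  $(\phi, \psi) = (-57^\circ, -47^\circ)$, side chains in extended
  rotamers from internal-coordinate templates, rings placed as closed
  planar polygons.
- **Bent two-helix toys** (`build_bent_helix()`): the same helix with a
  three-residue turn whose torsions were chosen once so that the second
  helix runs back antiparallel without steric clashes (end-to-end
  ~1.2 nm for a 21-mer versus ~3.1 nm straight). This emulates the
  compact-versus-elongated two-state setting of a helical polypeptide.
- **Two-state bead polymers** (`build_two_state_polymer()`): a CA-bead
  chain with a compact hairpin and an exactly straight extended state
  (end-to-end exactly $(n-1) \times 0.38$ nm). The hairpin carries a tiny
  seeded jitter because perfectly collinear geometry leaves torsions
  undefined; for the same reason `build_topology()` drops any torsion
  whose native geometry is degenerate and guards the
  $1/\sin\vartheta$ singularity in the angle force.

These fixtures reproduce the method's mechanics — topology construction,
gradient correctness, transition recovery, coupling calibration — at
minutes of CPU. They do not reproduce real-protein energetics: contact
networks of crystallographic structures are denser and heterogeneous, real
difference curves carry instrument systematics beyond counting noise, and
absolute $\chi^2$ scales differ by orders of magnitude between a 12-bead
polymer and a several-thousand-atom enzyme. Quantitative values measured
on fixtures (e.g. the guided minimum RMSD) therefore characterize the
implementation, not any particular protein system. For work on real
two-state systems (e.g. open/closed enzyme forms from their PDB entries),
the same pipeline applies unchanged: parse both states, build the topology
from the initial state, create the difference target, calibrate
$(T, k_\chi)$ by grid search, run guided simulations, and summarize.

## Numerical and design choices

- **Angle constants.** The force-field convention states angle and
  improper weights "per degree"; dimensional consistency and common
  practice in all-atom structure-based models point to
  $\varepsilon/\mathrm{rad}^2$ with radians internally, which is the
  default here (the constants are plain arguments of `sbm_constants()`,
  so the literal per-degree reading can be tested by passing the
  converted value).
- **Contact map.** A plain heavy-atom cutoff map at 0.45 nm. Shadow-map
  style definitions are deliberately out of scope; the cutoff is a
  configuration knob.
- **Dihedral assignment.** One proper torsion per rotatable non-ring
  bond with deterministically chosen flanking atoms (lowest index);
  impropers at every center with three or more bonded heavy neighbors,
  covering sp² planarity and CA/branch chirality uniformly with native
  reference values.
- **Weight partition.** The published derivation of the contact/dihedral
  weight split is not reproducible from the available description, so
  uniform per-term weights with the 2:1 contact:dihedral ratio are used;
  the ratio is configurable. With no contacts (peptides shorter than
  five residues) the dihedral share is still normalized to one third of
  the atom count.
- **Averages.** Trajectory averages ($V_\mathrm{XS}$, $\chi^2$) are
  full-trajectory by default with an optional `burn_in` fraction, since
  whether equilibration frames belong in such averages is a
  reporting-style choice.
- **NMR entries.** Multi-model files default to the first model;
  alternate locations resolve to highest occupancy with ties toward
  altloc A; HETATM records (waters, ligands) are dropped so holo forms
  are modeled unliganded.
- **Problem sizes.** The test suite and the acceptance script use a
  12-bead polymer (3 × 10⁴ steps per run, three seeds) and 21-residue
  all-atom toys (~170 atoms), with a seven-point temperature scan for
  the folding-transition location. These sizes were chosen so the full
  validation cycle completes in a few minutes on one core while leaving
  every phenomenon of interest (transition recovery, coupling
  calibration, folding transition) measurable.

## Parameter guide

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `temperature` | reduced temperature | 90 | $k_BT = 0.00831451\,T\ \varepsilon$; folding $\approx 120$ |
| `k_chi` | bias coupling ($\varepsilon$) | — | calibrate by `grid_search()`; scale depends on form factors |
| `alpha` | transitioning fraction | 1 | $(0, 1]$ |
| `dt` | time step (reduced) | 5e-4 | stability-limited by $K_b$ |
| `friction` | Langevin friction | 1 | 0 gives NVE |
| `cutoff` | contact cutoff (nm) | 0.45 | heavy-atom distances |
| `bias_stride` | bias refresh (steps) | 1 | forces reused in between |

## Known limitations

- The Debye sum is $O(N^2)$ in residues per evaluation and the non-native
  repulsion $O(N^2)$ in atoms per step; the engine is intended for
  coarse validation systems and small-to-medium proteins, not for
  large complexes or long production runs.
- Single-basin potential: the model funnels toward one native structure,
  and the bias must out-compete that funnel. Multi-basin extensions are
  out of scope.
- Scattering observables with near-degenerate shape signatures (changes
  that barely alter the molecular envelope) cannot be resolved by any
  small-angle bias; the method shares this fundamental limit.
- Time is reported in reduced units; no attempt is made to map simulated
  time onto physical seconds.
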
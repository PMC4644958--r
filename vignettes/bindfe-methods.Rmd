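---
title: "Methods: end-state binding free energies and bidirectional-work PMFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: end-state binding free energies and bidirectional-work PMFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindfe)
```

`bindfe` is a post-simulation analysis toolkit for protein–inhibitor binding
studies. It implements the two free-energy methods most often paired in that
literature — single-trajectory MM-GBSA end-state analysis with per-residue
decomposition and normal-mode entropy, and potential-of-mean-force (PMF)
estimation from segmented bidirectional steered-work samples — together with
the structural analyses (RMSD, hydrogen-bond occupancy, distance series)
that support them. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic testbeds do and do
not demonstrate.

## The MM-GBSA model

The binding free energy of a complex is estimated from snapshots of a single
complex trajectory as

$$\Delta G_{bind} = \Delta H - T\Delta S, \qquad
\Delta H = \Delta E_{ele} + \Delta E_{vdw} + \Delta G_{pol} + \Delta G_{nonpol}.$$

In the single-trajectory scheme the complex, receptor and ligand are all
evaluated on the same snapshot, so intramolecular gas-phase terms cancel:
$\Delta E_{ele}$ and $\Delta E_{vdw}$ reduce to the receptor × ligand
pairwise Coulomb and Lennard-Jones sums (`intermolecular_energy()`), with no
cutoff and no periodicity — the end-state convention, regardless of how the
trajectory itself was produced. The Coulomb constant is 332.0637
kcal·Å/(mol·e²).

The polar solvation term $\Delta G_{pol}$ is a generalized Born difference
(complex − receptor − ligand, each on the same frame). Effective Born radii
come from Hawkins–Cramer–Truhlar pairwise descreening with a 0.09 Å
intrinsic-radius offset (`effective_born_radii()`); the closed-form pairwise
integral is validated in the tests against direct numerical quadrature of
the $r^{-4}$ descreening volume integral, including the regime where one
atom's scaled sphere engulfs another. Energies use the Still interaction
form with self terms,

$$\Delta G_{pol} = -\frac{K}{2}\Big(\frac{1}{\varepsilon_{in}} -
\frac{1}{\varepsilon_{out}}\Big) \sum_{ij}
\frac{q_i q_j}{f_{GB}(r_{ij}, R_i, R_j)},\qquad
f_{GB} = \sqrt{r^2 + R_iR_j e^{-r^2/4R_iR_j}}.$$

The dielectrics default to $\varepsilon_{in} = 1$, $\varepsilon_{out} = 80$,
the conventional end-state values; both are fields of the topology and can
be overridden. Which GB flavour a given simulation package used is rarely
knowable in detail, so the GB choice is isolated behind
`effective_born_radii()` — absolute $\Delta G_{pol}$ values from other codes
should be treated as comparable only in ranking, not bit-for-bit.

The nonpolar term is the linear surface-area model $\gamma \cdot SASA +
\beta$ with $\gamma = 0.005$ kcal/mol/Ų and $\beta = 0$, probe radius 1.4 Å.
SASA uses Shrake–Rupley quadrature on a deterministic Fibonacci lattice (960
points per atom by default), with the Lennard-Jones Rmin/2 doubling as the
atomic SASA radius. The lattice makes results reproducible to the bit for a
given `n_points`; its resolution is about $\gamma \cdot 4\pi r^2 / 960
\approx 10^{-3}$ kcal/mol per atom, which is why equality assertions on the
nonpolar term are never made below 0.01 kcal/mol.

### Per-residue decomposition

Every receptor × ligand pair term (Coulomb, LJ, GB cross term) is split
half/half between the two partners; GB self terms and per-atom SASA
differences are assigned to the owning atom. Receptor atoms aggregate into
residue buckets and ligand atoms into one ligand bucket. Because the split
is a partition of exactly the terms that make up the snapshot totals, the
bucket sums reconcile with `snapshot_breakdown()` to numerical precision
(the tests require 1e-6 kcal/mol on every snapshot; in practice agreement is
~1e-13). The half/half convention is itself a choice — published tables
rarely state theirs — and only bucket totals, not the split rule, are
comparable across implementations.

### Normal-mode entropy

$-T\Delta S$ comes from standard ideal-gas / rigid-rotor /
harmonic-oscillator statistical thermodynamics at 1 atm on each of the three
species. The toy force field (harmonic bonds and angles plus non-excluded
Coulomb/LJ pairs) supplies analytic gradients; Hessians are central
differences of those gradients (step 1e-4 Å, symmetrized after a relative
asymmetry check, since the truncation error scales with the local third
derivatives). Mass-weighted eigenvalues convert to wavenumbers; modes with
$|\tilde\nu| < 1$ cm⁻¹ are counted and removed as rigid-body modes — the
1 cm⁻¹ threshold separates the six rigid modes cleanly on toy systems
without swallowing soft vibrations — and any surviving imaginary mode draws
a "not at a minimum" warning.

Minimization before normal-mode analysis is the caller's job via
`minimize_energy()`. The helper runs L-BFGS-B on the analytic gradient and
finishes with projected-Newton polish steps in the non-rigid subspace,
because quasi-Newton line searches alone stall near 1e-5 kcal/mol/Å on
stiff toy surfaces; the combination reaches the 1e-6 kcal/mol/Å default
tolerance with quadratic endgame convergence. Inside `mmgbsa_run()` each
species' per-snapshot minimization is warm-started from the previous
snapshot's minimum: consecutive snapshots of a jittered bound pose relax
into the same basin, so the warm start changes nothing but the cost.

### Snapshot protocol and aggregation

`select_snapshots()` implements the evenly-spaced window protocol: on a
20 ns trajectory saved every 1 ps, the window (15, 20] ns at 10 ps spacing
yields 500 snapshots; the entropy term is evaluated on 125 evenly spaced
snapshots by default, mirroring the usual 4:1 enthalpy:entropy sampling
ratio. Which 125 of the 500 a given study used is usually unstated; evenly
spaced is this package's convention. Aggregation reports means and standard
errors with the $\sigma = sd/\sqrt{N}$ convention (sample sd, $n-1$
denominator). Cross-compound spreads quoted as "root-mean-square deviation"
in the literature are reproduced here by the sample standard deviation —
verified against the packaged printed table, where the $n-1$ convention
matches the printed 2.79/6.51 values and the $n$ denominator does not.

### The packaged compound table

`table1_fixture()` ships the published per-compound component table for the
nine 14-3-3σ inhibitors (R1…R9) verbatim, with experimental affinities for
R1…R8. It exists because the absolute component values depend on undeposited
trajectories and cannot be recomputed at desk scale; the package's
aggregation, summary and correlation code runs on the printed numbers
instead, reproducing the published cross-compound statistics
(mean/sd −15.65/2.79, −25.53/6.51, 20.31/0.78) and correlations (0.93 with
experiment; 0.92, 0.83, 0.30 for the component terms — the 0.30 is $|r|$,
the signed value on the printed data being negative, which is why
`correlate()` has an explicit `mode` argument and reports default to the
signed convention). One honest wrinkle: from the 2-dp printed table the
$-T\Delta S$ spread evaluates to 0.785 where the original prints 0.78,
presumably computed from unrounded values; checks on that quantity use a
0.01 tolerance.

Experimental $\Delta G$ can also be derived from a dissociation constant via
$RT\ln K_d$ at 300 K (`dg_from_kd()`) when $K_d$ values are available.

## Structural analyses

RMSD series use Kabsch (SVD) superposition with the proper-rotation
correction, fitting on one atom set (protein backbone by convention) and
measuring on another without refitting — the convention that makes pocket-
and ligand-RMSD curves well defined. Pocket membership for "within R"
selections is frozen on a designated reference frame rather than
re-evaluated per frame, so the measured atom set is constant along the
series; the reference frame is an explicit argument, since published
analyses rarely state whether pocket atoms were re-selected per compound.

Hydrogen bonds use the geometric criteria: donor–acceptor distance
strictly below 3.5 Å and donor–H–acceptor angle strictly above 120°, both
boundaries exclusive. The angle is measured at the hydrogen; occupancy is
the percentage of frames in which a donor/acceptor pair passes via any of
the donor's bonded hydrogens (bond-table assignment, no distance-based
inference), and mean distances are computed over passing frames only.

## PMF from bidirectional steered work

The pulling coordinate is divided into contiguous segments (16 × 1 Å in the
emulated protocol). Within each segment, forward paths steer the ligand away
from the binding site and reverse paths steer it back; cumulative work is
recorded on a displacement grid. The free energy at grid point $r$ relative
to the segment entry $A$ is the half-exponential-average ratio

$$\Delta G(A\!\to\!r) = -k_BT \ln
\frac{\langle e^{-W_F/2k_BT}\rangle_F}{\langle e^{-W_R/2k_BT}\rangle_R},$$

with $W_F$ the work $A\to r$ and $W_R$ the work $r\to A$ (obtained from the
reverse path's cumulative work re-indexed from the segment's far end). On
Crooks-consistent Gaussian work with equal forward/reverse variance this
estimator is exact in expectation — the property the synthetic sampler is
built around, and the package's validation of the implemented form.
Evaluation uses log-sum-exp stabilization throughout. Segments are stitched
by cumulative offset addition and anchored at zero displacement; gaps or
overlaps in segment coverage are errors, not warnings.

Jarzynski (one-sided exponential average) and Bennett acceptance ratio
(self-consistent solution by safeguarded Newton iteration to 1e-8) are
provided as reference estimators; on the synthetic regime all three agree
within bootstrap uncertainty. Uncertainties are percentile bootstrap over
whole paths within each segment/direction (200 resamples, seeded);
resampling is implemented as multinomial weights, which is algebraically
identical to index resampling. Published PMF analyses of this kind rarely
report uncertainties; the bootstrap is this package's addition.

## The synthetic testbeds

The generators produce every input the pipeline needs with known ground
truth; they emulate the statistical structure of the real inputs, not their
chemistry.

**Host–guest complex** (`make_host_guest()`): a three-residue ring host —
two arginine-like +1 side chains and one tyrosine-like hydroxyl — closing
around a 5-atom phosphate-like guest of charge −2, net charge zero, 17
atoms. Three donor–H/acceptor pairs sit at hydrogen-bond geometry (N/O···O
2.85 Å, collinear), so H-bond detection and occupancy have real work to do.
Bond and angle equilibria equal the built geometry. Because the bonded terms
carry no torsions, arm rotations would otherwise be nearly free; the host
heavy atoms are therefore braced by an elastic network (k = 50 kcal/mol/Ų
at the built distances, plus each hydrogen to its residue's CB), emulating
folded-scaffold stiffness and giving every species a single well-defined
minimum — minimizations from jittered starts agree to ~1e-13 kcal/mol,
which is what makes the per-snapshot normal-mode entropy a constant with a
known reference value.

**Jittered trajectories** (`jitter_trajectory()`): i.i.d. Gaussian
displacement per coordinate around the bound pose, frames 1 ps apart,
seed-deterministic. The default σ = 0.004 Å defines the generator's
operating regime as a parameter-recovery testbed: mean energies over the
ensemble must coincide with the static-pose values within sampling error,
and since the anharmonic bias grows as σ² (dominated by the $r^{-12}$
repulsive wall at H-bond contact) while the standard error grows only as σ,
the default was calibrated so the worst component's bias stays well inside
the 3×sem band (floored at the 0.01 kcal/mol quadrature resolution) at 500
snapshots. Larger σ is useful for RMSD-style analyses but biases mean
energies; it is a parameter, not a hidden constant. What these trajectories
do **not** emulate: correlated thermal motion, conformational transitions,
solvent degrees of freedom, or force-field realism — passing recovery tests
here validates the analysis machinery, not any claim about real proteins.

**Crooks-consistent work samples** (`crooks_work_sampler()`): within each
segment, cumulative works are sums of i.i.d. Gaussian increments with means
$\pm\delta g + \beta\sigma_\delta^2/2$, so forward/reverse distributions
satisfy the Crooks relation with equal variances at every grid point —
whole-segment works are $N(\pm\Delta G_s + \sigma_W^2/2k_BT,\,\sigma_W^2)$.
Defaults: 16 × 1 Å segments with planted per-segment free energies summing
to −13.0 kcal/mol, front-loaded over the first 7 segments to mimic a
pocket-exit profile; σ_W = 1 kcal/mol; 4 paths per direction per segment
(the emulated pulling protocol). At 4 paths the estimators are only
CI-accurate — the bootstrap interval spans several kcal/mol — which is
itself the instructive result: the protocol's precision is
sampling-limited. At 10⁴ paths the planted endpoint is recovered to better
than 0.1 kcal/mol. Real steered-work data would add dissipation
heterogeneity along the path and non-Gaussian tails; the sampler
deliberately stays in the estimator's exactness regime so that deviations
indicate implementation errors, not modelling error.

## Problem sizes and numerical defaults

The validation suite and the acceptance script run the toy complex at 500
snapshots (125 for entropy), the dense work ensemble at 10⁴ paths/segment,
and bootstraps at 200 resamples — sizes chosen so every statistical check
has the power it needs while the whole suite completes in a few minutes on
one core. Other defaults collected in one place: Coulomb constant 332.0637;
ε_in/ε_out 1/80; GB offset 0.09 Å; SASA probe 1.4 Å, 960 lattice points;
γ/β 0.005/0.0; snapshot window (15, 20] ns at 10 ps; entropy on 125
snapshots at 300 K, zero-mode threshold 1 cm⁻¹, minimizer tolerance 1e-6
kcal/mol/Å; H-bond cutoffs 3.5 Å / 120°, strict; BAR tolerance 1e-8;
bootstrap 200 resamples. Every one of these is an argument of the relevant
function.

## Known limitations

- Absolute MM-GBSA component values are GB-flavour- and radii-set-dependent;
  only differences and rankings transfer across implementations.
- No Poisson–Boltzmann polar term, no explicit solvent, no
  multi-trajectory (separate receptor/ligand simulation) scheme, and no
  quasi-harmonic entropy.
- The toy force field has no torsional terms; rigidity on the synthetic
  systems comes from the elastic-network braces.
- PDB support covers the ATOM/HETATM/MODEL/ENDMDL subset (plus multi-frame
  XYZ); there is no reader for binary trajectory or native topology
  formats — parameters arrive through the documented JSON sidecar.
- Work-based PMF estimation assumes cumulative works are given; the package
  does not integrate raw force traces and does not implement WHAM.
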
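# bindfe

End-state binding free energies and bidirectional-work potentials of mean
force, in R.

`bindfe` is for computational chemists and structural bioinformaticians who
run molecular-dynamics or steered-MD simulations of protein–inhibitor
complexes and need the downstream analysis: it implements single-trajectory
**MM-GBSA** (molecular-mechanics energies with generalized-Born and
surface-area solvation) with per-residue decomposition and normal-mode
entropy, **PMF estimation** from segmented forward/reverse pulling work via
the Brownian-dynamics fluctuation–dissipation theorem (with Jarzynski and
Bennett-acceptance-ratio cross-checks), and the supporting structural
analyses — Kabsch-superposed RMSD series, geometric hydrogen-bond occupancy,
and distance time series. Seed-deterministic synthetic systems with planted
ground truth (a toy host–guest complex, jittered trajectories,
Crooks-consistent work samples) make every estimator testable end to end.

## The models in brief

Binding free energy from snapshots of the complex trajectory:

    ΔG_bind = ΔE_ele + ΔE_vdw + ΔG_pol + ΔG_nonpol − TΔS

with gas-phase terms as full receptor × ligand pairwise sums (intramolecular
terms cancel in the single-trajectory scheme), ΔG_pol from
Hawkins–Cramer–Truhlar generalized Born radii under the Still interaction
form (ε_in = 1, ε_out = 80), and ΔG_nonpol = γ·SASA + β (Shrake–Rupley,
probe 1.4 Å, γ = 0.005 kcal/mol/Å², β = 0). −TΔS comes from
ideal-gas/rigid-rotor/harmonic-oscillator thermochemistry on mass-weighted
normal modes. Aggregates report σ = sd/√N.

Free energy from bidirectional pulling work, per segment and grid point r:

    ΔG(A→r) = −k_B T · ln( ⟨exp(−W_F/2k_BT)⟩_F / ⟨exp(−W_R/2k_BT)⟩_R )

with W_F the work A→r along forward paths and W_R the work r→A along
reverse paths; segment profiles are stitched into a global PMF with
percentile-bootstrap uncertainties over paths.

## Worked example

```r
library(bindfe)

# a 17-atom host-guest complex with a phosphate-like -2 guest bound in a
# hydrophilic +2 pocket, and a jittered bound-pose trajectory around it
sys  <- make_host_guest()
traj <- jitter_trajectory(sys$frame, sys$topology, n_frames = 100, seed = 42)
res  <- mmgbsa_run(traj, sys$partition, entropy = TRUE, n_entropy = 25)
print(res$aggregate)
#> aggregate over 100 snapshots (25 for entropy):
#>   e_ele          -365.706 +- 0.043 kcal/mol
#>   e_vdw             1.095 +- 0.007 kcal/mol
#>   g_pol           343.849 +- 0.027 kcal/mol
#>   g_nonpol         -1.011 +- 0.000 kcal/mol
#>   g_ele_pol       -21.858 +- 0.017 kcal/mol
#>   g_vdw_nonpol      0.083 +- 0.007 kcal/mol
#>   h               -21.774 +- 0.013 kcal/mol
#>   minus_t_ds       13.997 +- 0.000 kcal/mol
#>   g_bind           -7.777 +- 0.013 kcal/mol
```

The complex is electrostatically driven: the gas-phase attraction (−365.7
kcal/mol) is mostly paid back by desolvation (+343.8), leaving a net
electrostatic-plus-polar contribution of −21.9; entropy loss on binding
(+14.0) brings ΔG_bind to −7.8 kcal/mol. Per-residue decomposition shows
where it comes from — the two charged arginine-like residues dominate, and
the bucket totals reconcile exactly with ΔH:

```r
per_residue_decomposition(sys$frame, sys$topology, sys$partition)
#>    label  e_ele     e_vdw  g_pol g_nonpol total
#> 1 ligand -182.9  0.554404 174.40   -0.523 -8.46
#> 2  ARG60  -86.2  0.277253  81.18   -0.164 -4.89
#> 3 ARG133  -86.2  0.277253  81.18   -0.169 -4.89
#> 4 TYR134  -10.5 -0.000102   7.13   -0.154 -3.55
```

The packaged published compound table (nine 14-3-3σ inhibitors) feeds the
same aggregation and correlation machinery:

```r
ct <- table1_fixture()
m  <- paste0("R", 1:8)
correlate(table_component(ct, "g_bind", m), table_component(ct, "exp", m))
#> r(dG_bind, dG_exp) = 0.93
```

And a PMF from bidirectional work at the emulated pulling protocol's scale
(16 × 1 Å segments, 4 paths per direction, planted total −13.0 kcal/mol):

```r
works <- crooks_work_sampler(seed = 7)
prof  <- pmf_profile(works, seed = 8)
#> PMF endpoint: -13.10 kcal/mol (95% CI [-15.90, -10.77], planted -13.0)
```

Four paths locate the answer but with a several-kcal/mol interval — the
protocol is sampling-limited; at 10⁴ paths the same estimator recovers the
planted value to better than 0.1 kcal/mol.

A thin command-line wrapper (`inst/cli/bindfe`) exposes the same
functionality as subcommands `simulate`, `mmgbsa`, `hbonds`, `rmsd`, `pmf`
and `report`, writing TSV outputs plus a JSON run manifest.

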
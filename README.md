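# hydroshape

Shape-dependent hydrophobic interaction analysis in R.

When a nonpolar solute is dissolved in water it perturbs only the topmost
water layer at the solute–water interface. Hydrophobic attraction between
two such solutes then amounts to bookkeeping on that layer: as the solutes
approach, interfacial waters are expelled into the bulk, each expelled
molecule recovering roughly one tetrahedral (DDAA) hydrogen-bond free
energy. Because the number of expelled waters depends on how the two
surfaces fit together, the strength of the interaction depends on the
*shape* of the solute surface — a sphere binds a concave pocket more
strongly than a flat face, and a flat face more strongly than a convex
bump. `hydroshape` packages the three layers of analysis this picture
needs, for people studying hydrophobic association with molecular
simulation or closed-form hydration models:

1. **Hydration thermodynamics** (closed form). For a spherical solute of
   radius *R* the hydration free energy is

   ΔG_hydration = ΔG_water–water + 8 ΔG_DDAA r_H2O / R,

   the second term being the interfacial-layer cost
   ΔG_solute–water = ΔG_DDAA · (4 r_H2O/R) · n_HB with n_HB = 2. The two
   terms balance at the critical radius

   R_c = 8 |ΔG_DDAA| r_H2O / |ΔG_water–water|,

   the crossover between the dispersed (initial-solvation) and aggregated
   (hydrophobic-solvation) regimes. The module also provides the geometric
   factor γ = (SA/V)_aggregate / (SA/V)_separate (γ = 1 until surfaces
   touch at the hydrophobic radius R_H), the transfer energy
   ΔG_H = n_interfacial→bulk · ΔG_DDAA, the hyperbolic distance model
   ΔG_water-induced(r) = a + γ·b/(r − r0) with a least-squares fitter, and
   the surfactant packing-parameter rule v0/(a·l0) → sphere/cylinder/bilayer.

2. **Water structure.** Geometric hydrogen-bond detection (O–O < 3.5 Å and
   donor ∠OOH < 30°, minimum-image aware), local network classes
   (DDAA/DDA/DAA/DA/free), interfacial/bulk partitioning against implicit
   signed-distance solute surfaces, and interfacial→bulk transition
   counting along trajectories.

3. **PMF reconstruction.** Self-consistent single-temperature WHAM over
   harmonic umbrella windows, water-induced decomposition
   ΔG_water-induced = ΔG_total − ΔG_solute-in-vacuum, minimum/barrier
   extraction with prominence filtering, surface ranking by
   contact-minimum depth and first-barrier height, and the
   energy-vs-transitions regression.

All inputs can be produced synthetically with known ground truth:
parametric solute shapes (sphere, slab, concave pocket, convex bump,
composites), water-like packings at bulk density, Metropolis umbrella
samples drawn from an analytic double-well PMF, and association
trajectories with planted interfacial→bulk transition counts. Every
generator is deterministic under a seed.

## Worked example

```r
library(hydroshape)

tc <- thermo_constants()   # dG_DDAA = -2.66 kJ/mol, dG_water_water = -1500 cal/mol, r_H2O = 1.9 A
tc
#> Hydration model constants
#>   dG_DDAA        :   -2.660 kJ/mol
#>   dG_water_water :   -6.276 kJ/mol
#>   r_H2O          :     1.90 Angstrom
#>   T, P           : 293 K, 0.1 MPa
critical_radius(tc)
#> [1] 6.44232
```

The critical radius of 6.4 Å marks the solute size above which the
bulk-water term dominates hydration and solutes aggregate.

Reconstructing a PMF from synthetic umbrella windows (11 windows spaced
1 Å, spring constant 25 kJ/mol/Å², 5000 samples each, drawn from the
built-in double-well ground truth):

```r
truth <- ground_truth_pmf()
win   <- generate_umbrella_samples(truth, centers = 2:12, spring_k = 25,
                                   n_samples = 5000, seed = 1)
prof  <- wham(win)
find_minima_barriers(prof, prominence_min = 1)
#> pmf_features: 2 minima, 1 barriers
#>   minima (position A, depth kJ/mol):
#>     #1 at 3.050: -6.673
#>     #2 at 6.150: -3.035
#>   barriers (position A, height kJ/mol above preceding minimum):
#>     at 4.450: 7.616
pmf_rmse(prof, truth_profile(truth, prof$grid[is.finite(prof$values)]))
#> [1] 0.1884632
```

The contact minimum (3.05 Å), the solvent-separated minimum (6.15 Å) and
the intervening expulsion barrier are recovered; the profile matches the
generating truth to 0.19 kJ/mol RMSE at this sampling depth.

A command-line wrapper over the same functions is installed at
`inst/cli/hydroshape.R` (subcommands `thermo`, `gen-box`, `gen-umbrella`,
`gen-assoc`, `hbonds`, `layers`, `wham`, `decompose`, `features`,
`fit-distance`, `correlate`; `show-config` prints all defaults as YAML).

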
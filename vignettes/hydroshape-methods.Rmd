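---
title: "Methods: models, conventions and synthetic validation in hydroshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and synthetic validation in hydroshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroshape)
```

# The hydration model

`hydroshape` works with an interfacial-water account of hydrophobicity.
A dissolved solute perturbs only the topmost water layer at its surface;
every interfacial molecule loses part of its tetrahedral (DDAA)
hydrogen-bond free energy. For a spherical solute of radius $R$ the
number ratio of the interfacial layer to the volume is $4 r_{H_2O}/R$, so

$$\Delta G_{hydration}(R) = \Delta G_{ww} + \Delta G_{DDAA}\,
\frac{4 r_{H_2O}}{R}\, n_{HB},$$

with $\Delta G_{ww}$ the free energy of bulk water. The package defaults
are $\Delta G_{DDAA} = -2.66$ kJ/mol and $\Delta G_{ww} = -1500$ cal/mol
(at 293 K, 0.1 MPa) and $r_{H_2O} = 1.9$ Å, the spherical-equivalent
radius of the ambient molecular volume of water
($\approx 3\times10^{-29}$ m$^3$). The two free-energy terms balance at
the critical radius $R_c = 8\,|\Delta G_{DDAA}|\,r_{H_2O} /
|\Delta G_{ww}|$, which these constants put at 6.44 Å.

Three conventions in this module were genuinely open and are fixed as
follows:

* **Units.** Everything is converted to kJ/mol on entry
  (1 cal = 4.184 J exactly). Mixing the two printed units is the easiest
  way to get $R_c$ silently wrong by a factor of 4.184.
* **Signs.** Both constants are negative under the bonding convention,
  yet the critical radius is a positive length; $R_c$ is therefore
  evaluated as a ratio of magnitudes. `hydration_free_energy()` itself
  returns the raw (signed) sum, so users can inspect either form.
* **$n_{HB}$.** The number of hydrogen bonds an interfacial molecule
  loses is an explicit parameter defaulting to 2: with the interfacial
  ratio $4 r_{H_2O}/R$, only $n_{HB}=2$ reproduces the factor of 8 in the
  hydration expression. A flat-cut interface removing half of a
  tetrahedral molecule's four bond-ends is the physical reading.

The geometric factor $\gamma$ (aggregate over separate
surface-area-to-volume ratio) is exactly 1 whenever the solute separation
exceeds the hydrophobic radius $R_H$ — before surfaces touch, no
interfacial area has been lost — and is computed as a plain ratio below
it. The transfer energy is strictly linear,
$\Delta G_H = n_{interfacial \to bulk}\,\Delta G_{DDAA}$; the
$\gamma$-weighted sums that motivate it are stated in the source model
only as a proportionality and are not computed.

The water-induced distance model
$\Delta G(r) = a + \gamma b/(r - r_0)$ is fitted by ordinary least
squares in the transformed regressor $x = 1/(r - r_0)$, with $r_0$ held
fixed (it is the vacuum contact minimum, known independently of the
solvated data; default 1.75 Å) and $\gamma$ held fixed (1 in the H1w
regime). Freezing $r_0$ keeps the fit linear and removes the strong
$b$–$r_0$ degeneracy a free-knot fit would have. `fit_water_induced()`
returns a classed object with `coef`, `predict`, `residuals`, `summary`
and `simulate` methods; standard errors of $a$ and $b$ come from the
linear-model covariance (the $b$ error is divided by the fixed
$\gamma$).

The packing-parameter rule maps $p = v_0/(a\,l_0)$ to sphere
($p \le 1/3$), cylinder ($1/3 < p \le 1/2$), bilayer ($1/2 < p \le 1$)
or out-of-range. The classical intervals overlap at their endpoints;
boundary values are assigned to the lower-curvature class on the left
(closed-left rule) so the map is deterministic.

# Water structure

A hydrogen bond between two waters requires an oxygen–oxygen distance
below 3.5 Å *and* an angle below 30° at the donor oxygen between the O→O
vector and the donating O–H bond. The angle is measured at the donor —
the standard reading of geometric ∠OOH criteria. Distances use the
minimum-image convention when the frame carries an orthorhombic box;
solute shapes are never imaged (the intended setup is a slab or cluster
plus surrounding water). One donated hydrogen can satisfy the cone
criterion for two acceptors at once; the detector keeps the nearest
acceptor, so each (donor, hydrogen) pair donates at most once and donor
counts never exceed 2.

Local network classes follow the donor/acceptor count map: (2,2) → DDAA,
(2,1) → DDA, (1,2) → DAA, (1,1) → DA, (0,0) → free. Combinations outside
the five named classes — e.g. a double donor with no acceptor — are
reported as `other` rather than being forced into a listed class, so
DDAA statistics are never silently inflated.

Interfacial water is defined by one number: a molecule is interfacial
when its oxygen's signed distance to the solute surface lies in
$[0, d_{cut}]$. The default $d_{cut} = 3.5$ Å is one water diameter
($\approx 2 r_{H_2O}$) and coincides with the hydrogen-bond O–O cutoff —
the natural single-layer scale when the source material defines the
layer only as "the top layer". The boundary is closed (distance exactly
$d_{cut}$ is interfacial) as a deterministic tie-break, and a water found
*inside* the solid is flagged with a warning but counted as interfacial
so the partition stays total. Transition counting reports the forward
interfacial→bulk count, the reverse count, and their difference.

# PMF reconstruction

`wham()` implements the standard self-consistent weighted-histogram
estimator for a single temperature: with window biases
$u_i(x) = \tfrac12 k_i (x - c_i)^2$, bin probabilities
$P(x_b) \propto \sum_i n_i(b) \big/ \sum_i N_i e^{(f_i - u_i(x_b))/k_BT}$
and window constants $f_i = -k_BT \ln \sum_b P(x_b) e^{-u_i(x_b)/k_BT}$
are iterated until the largest absolute change in any $f_i$ falls below
the tolerance (default $10^{-7}$ kJ/mol, the conventional setting;
`max_iter` defaults to $10^5$). Empty bins inside the sampled range are
masked, never interpolated — interpolation in `water_induced_pmf()` is
confined to resampling two profiles onto their grid overlap. Mixed
window temperatures are rejected. The default bin width of 0.1 Å against
the conventional 1.0 Å window spacing gives about ten bins per window and
comfortable histogram overlap, which is checked explicitly (a gap between
adjacent windows' sampled ranges raises an error naming the gap).

A PMF is defined up to an additive constant. Profiles are pinned to zero
at the largest sampled bin — large separation is the physical zero.
That bin is, however, also the most thinly sampled, so when *comparing*
profiles (`pmf_rmse()`, used throughout the tests) the default removes
the mean difference over the common support before computing the RMSE;
otherwise the comparison measures the noise of one edge bin rather than
the recovered shape.

Minima are filtered by topographic prominence (default 0.5 kJ/mol) to
keep histogram ripple out of the feature list; the barrier between two
adjacent retained minima is the highest intervening value above the
left minimum, which is non-negative by construction.
`rank_surface_interactions()` orders labelled water-induced profiles by
first-minimum depth and by first-barrier height, reports exact ties, and
excludes (with a warning) profiles in which no minimum survives the
prominence filter.

# Synthetic data: what it does and does not emulate

The generators exist so that every analysis path can be validated against
a known answer; they are geometric stand-ins, not physical water.

* `generate_water_box()` rejection-samples oxygens at bulk number density
  (0.0334 Å⁻³) with a hard minimum O–O distance (default 2.4 Å) outside
  the solute, and attaches hydrogens at 0.96 Å with uniformly random
  orientations (104.5° internal angle). It reproduces packing exclusion
  and interface truncation — enough to make interfacial hydrogen-bond
  counts drop below bulk counts near a wall, which is the property the
  tests assert — but has no orientational correlations, so absolute
  hydrogen-bond numbers are far below real water's ~3.5 and nothing
  about real interfacial structure should be inferred from them.
* `generate_umbrella_samples()` runs a 1-D Metropolis random walk per
  window targeting $e^{-(U(r) + \frac12 k (r-c)^2)/k_BT}$, with the step
  size tuned to 30–50% acceptance over a 5000-step burn-in and one
  sample kept every 10 steps. Any correctly targeted sampler suffices
  for WHAM validation; molecular dynamics is deliberately out of scope.
  Acceptance rates are recorded in each window's metadata, and the
  sampler is checked against closed forms (Gaussian limit under a stiff
  spring; variance $k_BT/(k_{truth}+k_{bias})$ for harmonic truth) and
  by a Kolmogorov–Smirnov test against the analytic biased density.
* The default `ground_truth_pmf()` is two Gaussian wells (depths 10 and
  4 kJ/mol at 3 and 6 Å, widths 0.6 and 0.8 Å) plus a repulsive
  $8/(r-1)$ kJ/mol contact tail on $[1.8, 13]$ Å — a contact minimum, an
  expulsion barrier and a solvent-separated minimum of realistic
  magnitudes for nanoscale association. Its extrema are located at
  construction by derivative root refinement and carried with the
  object, so feature detection has exact references.
* `generate_association_trajectory()` plants the interfacial→bulk
  bookkeeping directly: interfacial waters occupy lattice sites within
  the layer cutoff of the target surface, and a site dies permanently
  once the descending probe comes within a margin (0.6 Å) of it, its
  water jumping to a distant bulk reservoir. Occupancy is therefore
  monotone: per-frame interfacial counts never increase and cumulative
  transition counts never decrease, which is the qualitative structure
  of an association run. Both whole-box counts and a between-solutes
  sub-region count are recorded, since either counting convention may be
  wanted. Waters teleport rather than diffuse; only the counts, not the
  kinetics, are meaningful. The concave ≥ flat ≥ convex ordering of
  planted transitions is a geometric consequence of the construction
  (the pocket wraps the probe, the bump curves away from it) — the same
  premise that makes shape-dependent hydrophobicity interesting — and is
  asserted, not assumed, in the tests.

Default geometry: a 30 × 30 × 10 Å slab patch; a probe sphere of radius
5 Å; a concave pocket with 2.5 Å radial clearance over the probe; a
convex bump of radius 4 Å; separations from 8 Å to contact in 0.5 Å
steps. These are chosen so all three targets present comparable
interfacial areas to the same probe within a lattice of ~1.5 Å spacing.

Shapes are implicit signed-distance solids. Sphere and slab distances
are exact; pocket, bump and composites use CSG min/max combinations,
which are exact away from intersection curves (the usual CSG bound) —
ample for layer classification at 3.5 Å. Pocket and bump surface areas
and volumes are closed-form hemisphere corrections; composites fall back
to low-discrepancy (Halton) Monte Carlo with a reported standard error,
conservatively computed with the binomial formula ($2\times10^5$ points
give well under 0.5% relative error on the volume).

# Problem sizes and determinism

The validation suite runs on deliberately modest sizes: water boxes of a
few hundred molecules (22–25 Å cubes), hydrogen-bond oracle checks on
frames of up to 50 waters, WHAM recovery on 11 windows with $10^3$ to
$5\times10^4$ samples per window (the recovery RMSE at the top size is
well under 0.1 kJ/mol against a 0.5 kJ/mol requirement), and association
schedules of 17 frames. All generators accept a single integer seed and
are bit-reproducible for a fixed package version; the command-line
dispatcher threads one seed through every stage, so pipeline outputs are
byte-identical across reruns.

# Known limitations

* The hydration model's sign bookkeeping is inherited as printed: with
  both constants negative the raw hydration sum *decreases* for small
  solutes, so the initial/hydrophobic regime split should be read off
  magnitudes (as `critical_radius()` does), not off the raw sum.
* WHAM here is single-temperature with harmonic biases only; no MBAR
  generalisation, no 2-D coordinates. Uncertainty on the profile is not
  produced by default.
* Interfacial layer thickness is a single global cutoff; no
  instantaneous-interface or density-based definitions.
* The H-bond criterion is purely geometric; energetic or orbital
  definitions, and water-model internal geometry enforcement, are out of
  scope.
* Synthetic water has no dynamics: residence times, autocorrelations and
  dewetting kinetics cannot be studied with these generators, only
  counting and energetic bookkeeping.
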
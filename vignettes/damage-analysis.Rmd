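---
title: "Radiation-damage analysis for raster-scanned serial crystallography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiation-damage analysis for raster-scanned serial crystallography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sosdamage)
```

# The problem

Serial crystallography distributes the X-ray dose over thousands of
microcrystals: one still snapshot per crystal, merged afterwards. On an
unpatterned sheet-on-sheet fixed target the crystal slurry sits between two
polymer foils with no walls between exposure sites, so the products of one
exposure — heat, radicals, hydrogen gas — can diffuse into material that
will be probed later. Radiation damage can therefore appear in two places:

* **within** an exposure (global loss of lattice order, visible as an
  inflated Wilson B factor; local photoreduction of redox centres such as a
  heme iron, visible in metal–ligand geometry), and
* **between** exposures, where the serpentine scan's time structure matters:
  in-line neighbours are separated by `1/rate` seconds but spatial
  neighbours in adjacent lines by up to `(2N − 1)/rate`.

The package models both, and — importantly — puts *uncertainties* on the
refined geometry through an image bootstrap, so that "the Fe–Wat bond did
not change with step size" can be a statistical statement rather than an
impression.

# Models and procedures

## Scan model

`build_serpentine_scan()` expands a grid (fast/slow steps, counts, rate,
explicit fast axis, since facilities differ in which laboratory axis is
fast) into exposure events with zero-based times `index/rate`; the first
exposure is the coordinate origin and the first line runs in the +fast
direction. Damage spread is evaluated **at exposure instants only**,
matching the discrete character of the schedule, under either a
constant-radial-speed front (`r = v t`) or a diffusive scale
(`r = √(4Dt)`). `affected_fraction()` counts exposures lying inside the
spread radius of any earlier exposure; it is monotone in the spread
parameter by construction.

Crystals are modelled as discs in the chip plane (the slurry layer is
quasi-two-dimensional) with lognormal or truncated-normal diameters
(default mean 20 µm, the typical batch average for this kind of slurry).
`multi_hit_fraction()` estimates by Monte Carlo the fraction of illuminated
crystals intersected by two or more beam positions; the beam is a point
unless a diameter is supplied. Note one honest finite-size effect: for
step ≪ diameter every disc on the *infinite* lattice covers ≥ 2 positions,
but discs clipping the scanned area's edge can cover one, so the estimate
approaches 1 without reaching it.

`thermal_increment()` is an instantaneous conduction kernel,
`ΔT = E/(ρc(4πκt)^{3/2})·exp(−r²/4κt)` (3-D point source), with a 2-D
variant for a sheet of stated thickness. It is a deliberately simple
stand-in for a full heterogeneous-medium transport calculation — the
defining equations of the more elaborate treatment live outside the main
literature record we model — and is validated by energy conservation under
spatial quadrature (to 1%). With a typical synchrotron pulse energy
(~9×10⁻⁵ J), water-like constants and one in-line period of delay, a
neighbour 25 µm away sees a temperature increment of order ten kelvin;
treat this as order-of-magnitude only.

## Synthetic data: the stated world

`make_toy_structure()` builds a heme-like site whose measured geometry
equals the requested parameters to 1e-9 Å: four exactly coplanar pyrrole
nitrogens (plane radius 2 Å), the iron displaced `feoop` toward the distal
side, a proximal His nitrogen, and either a water + WatX pair (defaults:
Fe–Wat 2.45 Å, Wat–WatX 2.7 Å, Fe–Wat–WatX 117°) or a diatomic O–O ligand
(default Fe–O–O 160°). Defaults are the published resting-state values for
this class of site; bystander carbons make the refinement problem
realistically sized. Scattering uses **flat per-element form factors**
(f = Z): Wilson statistics and refinement behaviour are the targets, not
absolute intensities. The default toy cell is a compact triclinic box
(18 × 20 × 22 Å) rather than a protein-sized cell, keeping full HKL spheres
in the thousands of reflections.

`simulate_image_set()` draws, per image: a uniform random subset of the
Friedel-unique HKL sphere (no partiality model — Monte-Carlo merging
averages over partiality identically, so uniform subsetting reproduces the
statistics that matter), a lognormal scale (σ = `scale_sd`), additive
Gaussian noise proportional to the true intensity, optionally saturation
clipping at a cap, and a cell population: with probability
`fraction_large_cell` the image gets the expanded cell
(a = 75.0, b = 68.4, c = 77.6 Å, β = 107.6° scaled onto the toy cell) plus
`large_cell_extra_B` of extra attenuation, emulating the
lower-resolution-diffracting expanded-lattice population; the compact
reference population is a = 73.4, b = 68.8, c = 75.9 Å, β = 105.7°.

Two baseline intensity models are provided. The default (`"structure"`)
uses `|F_calc|²` of the toy structure, per the generator's contract. For
tests of Wilson-B recovery itself there is `"wilson"`, which draws each
unique reflection's true intensity from the acentric Wilson (exponential)
distribution with mean Σf². The reason is worth recording: a ~16-atom toy
site has a strongly structured molecular transform, so its bin-averaged
`|F|²` is *systematically* resolution-dependent and a straight Wilson fit
on it is biased by several Å² — a property of tiny models, not a defect of
the fit. Real structures approach the flat-baseline regime through sheer
atom count.

What a green test on this generator does **not** establish: behaviour under
partiality, spot-shape/bandwidth effects, background, indexing ambiguity,
or detector geometry — all deliberately outside the generator.

## Merging

`mc_merge()` takes the **unweighted mean** of all observations per unique
reflection (the Monte-Carlo merging convention; `weighted = TRUE` switches
to 1/σ² weights), with `sem = sd/√n`. Symmetry folding is `P1` (none) or
`monoclinic_2` (point group 2, unique axis b, Friedel mates included).
Negative merged intensities are kept — downstream Wilson fits use shell
means, which stay positive at realistic noise. Cells must agree within 1%
per axis (and β); beyond that the merge aborts and directs the caller to
`cluster_cells()`, because averaging across a lattice phase transition is
meaningless. Shells are equal-volume in 1/d³; completeness is counted
against the enumerated full sphere. `snr_resolution()` interpolates the
per-shell mean I/σ against 1/d² and flags geometry-limited datasets whose
signal never crosses the threshold.

## Toy refinement

The engine minimizes `Σ w (I_obs − k|F_calc|²)²` by Levenberg–Marquardt
with analytic Jacobians, refining an overall scale plus optional
coordinates, B factors and occupancies. Choices, and why:

* **Intensity-based target** (not amplitudes): avoids the negative-intensity
  square-root problem, equivalent at toy scale.
* **No geometric restraints**: the customary 0.3 Å coordinate scramble is
  small enough for unrestrained convergence on toy data. This is the
  largest deliberate divergence from production refinement programs.
* **Damping schedule**: λ ×10 on step rejection, ÷10 on acceptance; steps
  with equal residual are accepted. Convergence on parameter-shift norm
  (`convergence_tol`) or on a residual plateau (five accepted steps with
  < 1e-9 relative improvement) — the latter catches jitter at the numeric
  floor of noiseless problems.
* **Origin pinning**: in P1 the intensity target is *exactly* invariant
  under rigid translation of the model, so coordinates are only defined up
  to an origin. `refine()` returns the representative whose centroid
  matches the pre-scramble reference model; without this convention
  "recovery to 1e-3 Å" would be unattainable in principle.

`refine_two_state_water()` refines the occupancy partition of a distal
water present in two alternative positions. The default (`"constrained"`)
mode imposes `occ_pos2 = 1 − occ_pos1` and `occ_watx = occ_pos1`: the
displaced water position sterically clashes with WatX, so WatX must vacate
as the far position fills. This anti-correlated reading is one of several
defensible interpretations of such density; an `"independent"` mode that
decouples WatX is provided as the alternative. The scale is profiled
analytically and the occupancy found by bounded 1-D (or 2-D) minimization.

## Geometry

The heme plane is the total-least-squares plane of the **four pyrrole
nitrogens** by default (`"core"` switches to all heme atoms except Fe);
the four-N convention is the common minimal choice and which convention
published values used is generally unstated, so the choice is exposed.
FeOOP is signed **positive toward the distal (water) side**, making
"FeOOP decreases upon reduction" comparable across chains. Role assignment
on parsed PDB files finds HEM FE, NA/NB/NC/ND, the nearest His NE2, and the
distal ligand: a diatomic residue (O1/O2 of OOH-type codes) or two waters
within 2.2 Å of each other are treated as diatomic, otherwise the nearest
distal water becomes Wat and its nearest water neighbour WatX. First
alternate locations are used unless requested otherwise. All measurements
are rigid-motion invariant (property-tested at 1e-9).

## Resampling statistics

`draw_with_replacement()` resamples the image list with replacement, same
size as the original, the standard image bootstrap (100 replicas is the
customary count; the pipeline default of 20 is a documented desk-scale
reduction). `bootstrap_pipeline()` runs merge → scramble → refine →
measure per replica, drops and counts failed replicas (aborting above 50%),
and reports per-parameter means and SDs. Per-replica seeds are split from
the master seed by a label hash, so adding a parameter or stage does not
perturb the other draws.

`combine_gaussians()` forms the equal-weight mixture of per-dataset
(mean, SD) pairs — components are equally weighted because no defensible
weighting is available — with the closed form
`var = mean(σᵢ² + μᵢ²) − μ̄²`, cross-checked internally by grid summation
(skipped, silently, only when the narrowest component would need a grid
beyond 2×10⁶ points). `welch_test()` is the summary-statistics Welch test
with Welch–Satterthwaite fractional degrees of freedom; the `n` used when
comparing beamtimes (number of datasets per beamtime, by default) is the
caller's explicit choice and should be reported with the p-value, since
other effective-n conventions are defensible. `step_trend()` is
inverse-variance-weighted linear regression of a parameter on step size
with the slope SE taken from the known weights (fixed-effect convention)
and a normal reference distribution.

No BCa or percentile intervals are provided (SDs are the reporting
convention here), and no multiple-testing correction is applied across the
many geometric parameters — both stated limitations.

## Wilson plots and cell populations

One slope convention is used everywhere: `⟨I⟩ ∝ exp(−B/2d²)`, i.e.
`B = −2 × slope` of ln⟨I⟩ vs 1/d². Observed fits exclude 1/d² < 0.1 Å⁻²
by default because observed Wilson plots are routinely non-linear at low
resolution for reasons (background, bulk solvent) unrelated to Bragg
falloff; **the fit range is part of the reported result** and is carried in
the `wilson_fit` object. Bin abscissae are the mean 1/d² of contributing
reflections, which removes the leading binning bias. Calculated-intensity
fits (`wilson_calculated()`) are immune to background/scaling artefacts
and are the preferred basis for cross-dataset comparisons;
`falloff_ratio()` compares two fits after matching intercepts at 1/d² = 0
(so only slopes matter): `ratio = exp(−ΔB/2 · x)` — a ΔB of 11 Å² is a
factor ~5 at 1/d² = 0.3 (1.8 Å).

`cluster_cells()` k-means-clusters standardized (a, b, c, β) — β enters
standardized like the lengths — with 25 restarts under a fixed seed,
k = 2 by default (compact vs expanded population). Clusters are reported
sorted by cell volume so labels are deterministic. A per-image assignment
margin and a `degenerate` flag (centre separation under twice the
within-cluster spread, or fewer distinct cells than k) expose the k-means
failure mode of splitting a single population.

## Dose

`photons_per_pulse()` scales a reference flux linearly in ring current —
linear scaling reproduces the published counts to three significant
figures, so no tail-loss correction beyond it is applied.
Diffraction-weighted doses are **authoritative inputs**, never recomputed:
they require beam/crystal profile integration of the RADDOSE class, out of
scope. `simple_absorbed_dose()` is a clearly-labelled top-surface
uniform-beam estimate `nE(1−e^{−µt})/(A t ρ)`. The equilibrium
crystal-heating model sometimes quoted for microsecond exposures is *not*
implemented, since its defining equations live in an external reference;
only the conduction kernel above is.

# Numerical conventions and degenerate inputs

* Seeds: one master seed, split per stage/replica by a deterministic
  label hash (`split_seed()`), all below 2³¹; every writer stamps its
  output with version, seed and a config hash, and identical configs give
  byte-identical outputs.
* d-spacings come from the reciprocal metric of the general (triclinic)
  cell; `1/d² → d` conversion refuses non-positive input.
* σ values must be positive; the generator floors them at 10⁻⁶ of the
  median intensity in noiseless runs.
* `t = 0` in the conduction kernel returns 0 off-source and errors at the
  source point; zero-variance crystal-size models are honoured exactly.
* Welch's test with both SDs zero and equal means returns p = 1 by
  convention; unequal means with zero SDs is an error.
* k-means on fewer distinct cells than k returns a single cluster flagged
  degenerate instead of failing.

# What the defaults mean

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| scramble SD | 0.3 | Å | customary decorrelation before replica refinement |
| bootstrap replicas | 100 (pipeline: 20) | — | convention; pipeline scaled down for desk runs |
| scan rates | 231.25 / 100 | Hz | microsecond-SSX and XFEL fixed-target rates |
| crystal diameter | 20 ± 8 | µm | typical batch slurry |
| cell populations | see above | Å, ° | published compact/expanded monoclinic pair |
| Wilson fit floor | 0.1 | Å⁻² | excludes the non-linear low-resolution region |
| cell tolerance | 1 | % per axis | beyond it, populations must be split |
| noise, scale spread | 0.05–0.1, 0.2 | — | well-measured serial data regime |

# Known limitations

The toy refinement engine has no restraints, bulk solvent, anisotropy or
likelihood target; the generator has no partiality, background or detector
model; dose estimates are not diffraction-weighted; clustering assumes a
known k; and the synthetic stand-ins used where deposited reference data
would be required validate the measurement machinery, not the deposited
data themselves. Every empirical number quoted in this vignette is
computed by the test suite or the acceptance script; none is asserted from
memory.
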
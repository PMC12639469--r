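---
title: "Transmission PBS planning and FLASH dose-rate quantification with flashPBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission PBS planning and FLASH dose-rate quantification with flashPBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashPBS)
```

## The problem

The FLASH effect is the sparing of healthy tissue observed when dose is
delivered at ultra-high dose rates (UHDR, here taken as at least
40 Gy/s) without loss of anti-tumour efficacy. Pencil-beam scanning
(PBS) can reach UHDR only if energy-layer switching is avoided, which is
why *transmission* (shoot-through) fields at the highest available
energy are the natural FLASH delivery mode for protons (250 MeV,
cyclotron-driven continuous scanning) and a candidate mode for
very-high-energy electrons (VHEE, 150-200 MeV, pulsed linacs).

Whether a plan actually delivers its dose under UHDR conditions is a
property of the *delivery time structure*, not of the dose distribution
alone. `flashPBS` implements the full chain needed to quantify this at
desk scale: synthetic phantoms, analytic transmission kernels, spot
placement and weight optimization, delivery-time models for both
machine types, per-voxel PBS dose-rate maps, and the FLASH index.

## The FLASH index

For a structure, a dose threshold $X$ and a dose-rate threshold $Y$,

$$\mathrm{FI}(X\,\mathrm{Gy}, Y\,\mathrm{Gy/s}) =
  \frac{\mathrm{Vol}_{\mathrm{DRDVH}}(X, Y)}{\mathrm{Vol}_{\mathrm{DVH}}(X)},$$

where $\mathrm{Vol}_{\mathrm{DVH}}(X)$ is the fraction of the
structure's voxels receiving dose strictly above $X$, and
$\mathrm{Vol}_{\mathrm{DRDVH}}(X, Y)$ the fraction receiving dose above
$X$ *at a PBS dose rate of at least* $Y$ (accumulated over fields and
fractions by `flashDoseMap()`). FI is 1 when every above-threshold
voxel met the UHDR condition, and is defined as exactly 0 when no voxel
exceeds the dose threshold (the ratio degenerates; the numerator is
bounded by the denominator, so 0 is the continuous choice). The index
is agnostic to the magnitude of any radiobiological FLASH effect: it
only reports which part of the relevant volume satisfied the UHDR
conditions. Conventions: strict `>` for dose thresholds, `>=` for
dose-rate thresholds, and the two thresholds are independent parameters
(`flashIndex(dose, flashDose, mask, X, Y)`).

## The PBS dose rate

Dose rate under scanned or pulsed irradiation is ill-defined without a
convention. `pbsDoseRateMap()` uses the trimmed-window construction:
for voxel $j$, build the cumulative dose-versus-time curve $D_j(t)$ (a
linear ramp during each beam-on interval that doses the voxel, flat
between), and with total dose $D_j$ and trim dose $\hat d$ define

$$\mathrm{DR}_j = \frac{D_j - 2\hat d}
  {t_j(D_j - \hat d) - t_j(\hat d)},$$

with crossing times at the earliest crossing of the piecewise-linear
curve. The trim suppresses the arbitrarily long tails contributed by
far-away spots. Voxels with $D_j \le 2\hat d$ are assigned rate 0:
they cannot carry a meaningful window and sit far below any FLASH dose
threshold. The implementation is event-based (two passes over the spot
intervals) and exact for the piecewise-linear curve; the test suite
checks it against a 10 microsecond time-stepping oracle to better than
1 %. The default $\hat d$ is 0.1 Gy, a common literature value; it is
configuration (`doseRateConfig(thresholdDoseGy = ...)`) and results
should always be reported alongside it. Under this definition the
instantaneous (intra-pulse) dose rate plays no role, which is what
makes continuous proton scanning and microsecond linac pulses
comparable at all.

Two useful consequences, both asserted as properties in the tests: the
UHDR dose map never exceeds the total dose map (so DRDVH $\le$ DVH
pointwise and FI $\in [0,1]$), and for a pulsed delivery on a $1/f$
lattice every per-voxel dose rate is non-decreasing in the pulse
repetition frequency $f$.

## Delivery models

*Proton (continuous scanning)*: dwell time = weight / nozzle dose rate;
travel between consecutive spots at finite per-axis scan speed (the
slower axis decides) plus a fixed overhead; no dose during travel.
Spots are scanned in serpentine order over beam's-eye-view rows.

*VHEE (pulsed linac)*: pulses of width $\tau$ fire consecutively on the
global $1/f$ lattice, one spot per pulse; a spot whose weight exceeds
the per-pulse maximum takes the ceiling number of pulses. Beam
deflection is assumed faster than the pulse gap, so the PRF alone sets
the pace - the regime in which PRF is the critical FLASH parameter for
a VHEE machine.

Machine defaults are deliberately simple surrogates, set once from the
orders of magnitude of existing FLASH-capable systems and preliminary
linac designs: nozzle output $10^4$ MU/s (a typical optimized spot of
~30 MU dwells ~3 ms), scan speed $10^4$ mm/s, zero overhead,
$\tau = 4\,\mu$s, 100 MU per pulse (so typical spots fit in one
pulse). They are configuration, not measured machine data.

## Beam models

Transmission kernels are separable: dose per unit weight =
calibration $\times$ PDD(radiological depth) $\times$ lateral profile.
The lateral profile is a normalized single Gaussian (protons,
$\sigma_0$ = 10 mm FWHM / 2.355 = 4.25 mm) or double Gaussian (VHEE,
core $\sigma_1$ = 5 mm, halo $\sigma_2 = 3\sigma_1$ with 10 % of the
fluence), with widths broadened linearly in radiological depth (0.05
mm/mm protons; 0.10 / 0.07 mm/mm for 150 / 200 MeV VHEE). The core
sigmas are the published spot sizes for these modalities; the halo
fraction and broadening rates are unconstrained configuration with
documented defaults. Depth doses are tabulated and replaceable: a
gently rising proton transmission curve (0.95 to 1.10 over 0-300 mm)
and VHEE curves with 30 mm build-up followed by linear decline
(0.7 %/cm at 150 MeV, 0.4 %/cm at 200 MeV - the 150 MeV curve falls
faster, which is what makes it slightly better at sparing distal
tissue and slightly worse at depth).

These kernels replace clinical dose engines. That is a deliberate
scope decision: the quantities this package exists to study - FI
behaviour, PRF thresholds, proton-vs-VHEE UHDR coverage - are driven
by delivery timing and geometry, not by sub-percent dosimetric
fidelity. Nothing here should be used for clinical dose prediction.

Radiological depth is the line integral of relative density from the
body surface to the voxel along the beam axis. Axis-aligned gantry
angles (0/90/180/270) use an exact midpoint-rule cumulative sum along
the grid axis; arbitrary angles resample the density on a BEV-aligned
lattice at half the smallest voxel spacing. The batch path and the
single-voxel `radiologicalDepth()` agree with fine-step (0.1 mm) ray
marching to 2 % on heterogeneous grids.

## Spot placement and optimization

Spots are placed in the projected PTV: interior positions by a
centroidal Voronoi tessellation (`round(area / spacing^2)` generators,
Lloyd iterations until the largest movement is below 0.1 mm, uniform
seeded initialization over region pixels, out-of-region centroids
snapped back), plus border spots at equal arc-length steps along the
region contour. The default 5 mm spacing balances spot count against
dose homogeneity; border spots substitute for lateral margins
(margin-free by default). Border spots are fixed after placement and do
not participate in the Lloyd relaxation - spacing regularity at the
boundary matters more there than centroidality.

Dose-influence matrices are precomputed on a 2 mm spot-grid lattice;
columns for arbitrary spot positions are bilinear combinations of the
four surrounding node columns, exact at nodes. Weights are fitted by
projected gradient descent (nonnegativity by projection,
Barzilai-Borwein step seeding, monotone backtracking line search) on a
scorecard of quadratic one-sided penalties: `min_dose`, `max_dose`,
`mean_dose_max` and `uniform` objectives, priority-weighted. The
objective trace is non-increasing by construction, the minimizer is
invariant under rescaling all priorities, and a representable target
dose is recovered to 0.1 % RMS. Shipped scorecards are surrogates
(uniform + minimum-dose PTV objectives, maximum/mean dose per OAR);
they stand in for protocol-based clinical scorecards, which are not
reproduced here. Optional position refinement alternates per-spot
finite-difference moves on interpolated columns (step capped at half
the node pitch, only improving moves kept) with weight re-fits.

Initialization is deterministic: uniform weights scaled so the mean PTV
dose equals the uniform-objective level. Optimizing against a 1 mm
node grid instead of the 2 mm default changes the PTV D95 by less than
0.5 % on the brain-like preset, so the coarser grid is the default.

## Synthetic phantoms

Four presets emulate the geometry classes that drive the PRF findings,
not any patient anatomy: `brain_like` (15 mm radius sphere, 40 mm
deep, one small box OAR), `lung_like` (20 mm sphere inside a
0.3-density lung-like ellipsoid), `liver_like` (22.5 mm sphere, offset
laterally), `prostate_like` (40 mm sphere at centre with two abutting
box OARs). The radii were chosen so the PTV volumes are strictly
ordered brain < lung < liver <= prostate, reproducing the
small-vs-large target contrast that separates the easy from the hard
UHDR-coverage cases; no clinical volumes were available to copy, so
the presets are declared surrogates. Density is relative to water
(water = 1, air = 0, lung insert 0.3); BODY is an ellipsoid; there is
no CT calibration. Prescriptions default to 30 Gy in one fraction so
that the 10 Gy FI threshold is genuinely exercised.

What the phantoms deliberately do not have: anatomical texture, CT
noise, positioning uncertainty, realistic OAR topology. Tests passing
on these phantoms therefore demonstrate the *mechanics* of the method -
ordering, monotonicity, conservation and definitional properties - and
the qualitative modality contrasts, not clinical dosimetric accuracy
on real patients.

## Desk-scale problem sizes

`comparePlans()` plans on 3 mm phantoms of full 200 mm extent
(~300 000 voxels), restricts the optimization to the scored voxels
(all structures plus a 15 mm ring around the PTV) and to the lattice
nodes needed by the placed spots, and then recomputes the final
per-field dose and dose-rate maps on the full grid with exact kernels
at the optimized positions. A full prostate-like comparison (proton
plan + VHEE plan + four-PRF sweep) runs in about a minute on one CPU.
The phantom generator's own default stays at 2 mm / 100^3, matching the
spot-grid scale.

## Numerical conventions

- Dose quantiles $D_{x\%}$: voxel doses sorted descending,
  linear interpolation at rank $1 + (x/100)(N-1)$ - i.e.
  `quantile(d, 1 - x/100, type = 7)`. A uniform structure gives
  $D_2 = D_{98} = D_{\mathrm{mean}}$ and HI98 = 1 exactly.
- Conformity $CI_X$ uses the BODY mask as the total volume and `>=` at
  the isodose; an empty denominator reports `NA` rather than a value.
- Sparse columns truncate below $10^{-4}$ of the column maximum; no
  dose is scored in air (relative density below 0.05).
- The CVT is deterministic for a fixed seed; all pipeline randomness
  descends from one top-level seed and the manifest records it.
- Grids are congruence-checked before any map is combined; mismatched
  grids are an error, never a silent resample.

## Known limitations

- One PBS dose-rate definition is implemented (the trimmed-window
  construction). Average, percentile and sliding-window definitions
  from the literature are future configuration hooks; conclusions can
  shift under other definitions.
- The exact trim dose used in published clinical analyses varies;
  results here are always relative to the configured $\hat d$.
- Fractions are identical and infinitely separated: no cross-fraction
  dose-rate accumulation.
- Transmission only: no energy-layer handling, no range modulators, no
  LET or robustness analysis, no radiobiological FLASH-effect model.

## A minimal session

```{r example, eval = FALSE}
ph <- generatePhantom(phantomSpec("brain_like", dims = rep(67L, 3),
                                  spacingMm = 3))
plan <- planPhantom(ph, defaultVheeModel(200), seed = 1)
dl <- planDoseRate(plan, vheeMachine(prfHz = 500))
s <- planFlashSummary(plan, dl, ph$structures)
s$fi

## or the whole sweep in one call
cmp <- comparePlans("prostate_like", prfHz = c(100, 250, 500, 1000),
                    seed = 1)
cmp$fiTable
```
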
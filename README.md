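# flashPBS

Transmission pencil-beam-scanning (PBS) planning and FLASH dose-rate
quantification at desk scale.

FLASH radiotherapy spares healthy tissue when dose arrives at
ultra-high dose rates (UHDR, here ≥ 40 Gy/s). PBS can hold UHDR only
with *transmission* (shoot-through) fields: 250 MeV protons from a
continuously scanned cyclotron beam, or very-high-energy electrons
(VHEE, 150/200 MeV) from a pulsed linac. Whether a plan actually
delivers its dose under UHDR conditions depends on the delivery time
structure — for a pulsed linac essentially on the pulse repetition
frequency (PRF). `flashPBS` is an R package for medical-physics
researchers who want to study exactly that question without a clinical
TPS: it plans both modalities on synthetic phantoms with identical
objectives, models their delivery timelines, maps per-voxel PBS dose
rates, and quantifies UHDR coverage.

## The core quantities

**PBS dose rate** (per voxel, trimmed-window construction): with
cumulative dose-vs-time curve `D_j(t)`, total dose `D_j` and trim dose
`d̂` (default 0.1 Gy),

    DR_j = (D_j − 2d̂) / ( t_j(D_j − d̂) − t_j(d̂) )

computed event-exactly from the delivery timeline; `DR_j = 0` when
`D_j ≤ 2d̂`.

**FLASH index** of a structure, thresholds `X` Gy and `Y` Gy/s:

    FI(X, Y) = Vol_DRDVH(X, Y) / Vol_DVH(X)

the fraction of voxels with dose > `X` delivered at dose rate ≥ `Y`,
over the fraction with dose > `X`; `FI = 0` when `Vol_DVH(X) = 0`.
`FI ∈ [0, 1]`, non-increasing in `Y`, and the DRDVH never exceeds the
DVH. The index says nothing about the magnitude of any radiobiological
FLASH effect — it reports which part of the relevant volume met the
UHDR conditions.

## Worked example

A full proton-vs-VHEE comparison with a PRF sweep on the
prostate-like preset (large deep target with two abutting OARs):

```r
library(flashPBS)
cmp <- comparePlans("prostate_like", prfHz = c(100, 250, 500, 1000),
                    seed = 1)
cmp$fiTable
```

prints (seed 1, ~1 min on one CPU):

```
      delivery modality prfHz structure    volDVH    volDRDVH          fi
1       proton   proton    NA      BODY 0.3949670 0.359960390 0.911368185
3       proton   proton    NA   OAR_ANT 1.0000000 0.998615917 0.998615917
7   vhee_100Hz     vhee   100   OAR_ANT 1.0000000 0.000000000 0.000000000
11  vhee_250Hz     vhee   250   OAR_ANT 1.0000000 0.002422145 0.002422145
15  vhee_500Hz     vhee   500   OAR_ANT 1.0000000 0.807958478 0.807958478
19 vhee_1000Hz     vhee  1000   OAR_ANT 1.0000000 1.000000000 1.000000000
```

(excerpt; one row per structure per delivery). Reading it: `volDVH` is
the fraction of the structure above 10 Gy, `volDRDVH` the fraction
above 10 Gy delivered at ≥ 40 Gy/s, `fi` their ratio. The scanned
proton beam keeps nearly the whole 10 Gy volume at UHDR
(FI ≈ 0.91–1.0). The pulsed VHEE delivery covers essentially nothing
at 100 Hz, becomes useful around 500 Hz (FI ≈ 0.65–0.81) and fully
covers the 10 Gy volume at 1000 Hz — the PRF is the critical machine
parameter, and the proton FI stays at or above the VHEE FI at 500 Hz.
On the small shallow `brain_like` preset the target's FI is already
1.0 at 100 Hz.

Lower-level entry points: `generatePhantom()`, `placeSpots()`,
`buildInfluence()`/`interpolateColumn()`, `optimizeWeights()`,
`scheduleProton()`/`scheduleVhee()`, `pbsDoseRateMap()`,
`flashDoseMap()`, `dvhCurve()`/`drdvhCurve()`, `planMetrics()`,
`flashIndex()`, `fiRobustnessScan()`. `runCompare(outDir, ...)` writes
the report (CSV tables, NIfTI dose maps, a reproducibility manifest);
`inst/scripts/run_compare.R` is a command-line wrapper. The methods
vignette (`vignettes/flash-quantification.Rmd`) documents the models,
conventions and limitations.

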
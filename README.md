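# synmorph

Quantitative morphometry of inhibitory synapses formed by Purkinje-cell
recurrent axon collaterals, for anyone who measures synapse
ultrastructure on electron micrographs or bouton morphology on confocal
z-stacks and wants those bespoke measurement rules as tested, reusable
code. The package implements:

* **Standardized synaptic cleft width.** Five parallel 100-nm
  electron-density line profiles, 10 nm apart, perpendicular to the
  membranes, are averaged; on the average, each cleft boundary is the
  first point, walking from a membrane peak toward the inter-membrane
  valley minimum *v*, where the density falls below
  *peak − 0.10 (peak − v)*. The width is the distance between the two
  boundaries (sub-sample precision). The conventional manual
  measurement — peak-to-peak distance — is included as a comparator and
  is never smaller.
* **Bouton detection and volumetry.** Boutons are stretches of a
  traced collateral whose local diameter exceeds 2× the baseline axon
  diameter; their volume is (fluorescent voxels) × (voxel volume),
  0.00004 μm³ per voxel on the default 0.01 × 0.01 × 0.4 μm grid.
* **Bouton density maps.** Per-cell arbors are rigidly superimposed
  (soma to origin, main axon to a common direction) and binned into
  20-μm squares; densities in boutons/μm² render as a heat map.
* **Vesicle pools at active zones.** Vicinity = vesicle centre inside
  the presynaptic half-disc of diameter equal to the AZ length; docked
  = vesicle membrane < 10 nm from the AZ chord. Vesicle count vs AZ
  length is summarized by OLS slope *S* and Pearson *r*.
* **Statistics.** Pooled Student / Welch *t*, two-sample
  Kolmogorov–Smirnov, Hartley F<sub>max</sub> homoscedasticity with
  embedded critical values (k = 2–12, df = 2–60, α = 0.05), the
  sqrt(SD/mean) coefficient of variation, and disc/cylinder contact
  geometry comparisons.

Every measurement stage has a synthetic-data generator
(`gen_cleft_profile()`, `gen_em_patch()`, `gen_bouton_stack()`,
`gen_vesicle_scene()`, `gen_point_pattern()`) whose outputs carry
analytic ground truth, so the whole pipeline is testable without any
real micrograph.

## Worked example

Simulate a curved EM patch with a known cleft geometry, then measure it
the standardized and the manual way:

```r
library(synmorph)

spec <- cleft_profile_spec(membrane_separation = 24, membrane_shape = "gaussian",
                           membrane_width_param = 5, noise_sd = 0.1, seed = 42)
patch <- gen_em_patch(spec, curvature = 0.002)

measure_synapse(patch$image, patch$anchor)
#> <cleft_measurement> standardized width 20.81 nm (peaks 38.0 / 61.0 nm)
patch$truth$width           # noise-free drop-rule ground truth
#> 19.69
measure_synapse(patch$image, patch$anchor, method = "manual")
#> <cleft_measurement> manual width 23.00 nm (peaks 38.0 / 61.0 nm)
```

The standardized width lands ~1 nm from the noise-free truth at this
noise level (SD = 10% of the peak–valley range), while the manual
peak-to-peak width overshoots by construction — it includes part of
both membrane densities.

Carrying published group means (AZ length 237.01 vs 292.08 nm, cleft
width 21.17 vs 23.8 nm) through the derived contact geometry:

```r
geometry_comparison(wt = c(237.01, 21.17), ko = c(292.08, 23.8))
#> <geometry_summary> AZ length +23.2%, contact area +51.9%, cleft width +12.4%, cleft volume +70.7%
```

i.e. a ~23% longer active zone translates into a ~50% larger circular
contact area and, together with the wider cleft, a ~70% larger cleft
cylinder volume. And a homoscedasticity check of per-mouse cleft-width
variances:

```r
f <- fmax_test(values = c(rnorm(10, 21, 0.9), rnorm(12, 21.4, 1.1)),
               subgroup = rep(c("mouse1", "mouse2"), c(10, 12)))
f
#> <fmax_result> F_max = 3.222 vs critical 3.720 (k = 2, df = 10, alpha = 0.05, table): variances equal (null accepted)
```

## Command-line tools

A thin dispatcher over the same functions lives at
`inst/cli/synmorph.R` (installed under `system.file("cli", "synmorph.R",
package = "synmorph")`), with subcommands `simulate`, `cleft`,
`bouton`, `density`, `vesicles` and `stats` reading TIFF/CSV inputs and
writing CSV/PNG/JSON outputs; see the header of that script for the
column conventions.

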
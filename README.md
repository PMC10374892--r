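# igisml

Closed-loop simulation and control for image-guided in-situ maskless
lithography (IGIs-ML) of microfluidic devices.

In-situ maskless lithography projects UV patterns with a DMD into a
pre-polymer-filled blank device and photopolymerizes features in place.
Densely packed features suffer from the **proximity effect**: the projector
halo decays gradually outside the pattern and photogenerated radicals
diffuse, so every exposure partially cures a wide skirt around its feature
and nearby or subsequent exposures broaden and bridge. `igisml` implements
the image-guided closed-loop remedy entirely in software: a finite-difference
reaction-diffusion simulator of free-radical photopolymerization stands in
for the physical device, and the control layer runs against it.

The curing model tracks photoinitiator *S*, radicals *R*, monomer *M* and
polymer *P* on a plan-view or axisymmetric grid:

    dS/dt = -k_i I S
    dR/dt = D_R lap R + k_i I S - 2 k_t_eff R^2
    dM/dt = D_M lap M - k_p R M
    dP/dt =             k_p R M

with no-flux boundaries, frozen (gelled) solids, an exponential illumination
tail `I(d) = I_peak exp(-d / 33.4 um)` outside the pattern, and normalized
cure level `P / P_ref` where `P_ref` is the fully cured reference. On top of
the simulator the package provides:

* annular-mask greyscale **edge tracking** with cutoff and two-peak
  triggering (each pattern switches off independently);
* **d_critical slicing**: greedy conflict-graph coloring so each projected
  slice only contains features at least `d_critical` apart, with flush-flow
  events between slices;
* the four **exposure modes** (single, sequential, flush-only,
  tracked+flush) and their fidelity comparison;
* offline **optical proximity correction** of polygon corners via
  Fernandez-Guasti squircle transforms, and the online iterative
  **tip/trench dynamic shape correction** loop;
* a **layout compiler** (DXF in, tiled projection units, stitching
  expansion, channel protection, PNG masks + schedule index out) and a
  parametric **DLD array generator**;
* **metrology**: 100-ray radial profiles, pooled RMS roughness,
  diameter-broadening series, row-shift recovery.

## Worked example

Calibrate the critical distance in silico (four rows of twenty 35 um
circles at 25/50/100/150 um gaps, exposed sequentially; each circle measured
from the live image at the end of its own exposure):

```r
library(igisml)
cal <- calibrate_d_critical(fabrication_config("sequential", seed = 1))
print(cal)
#> d_critical calibration: 150 um (tolerance 5%)
#>   gap deviation_pct
#> 1  25    46.0950374
#> 2  50    42.8009885
#> 3 100     7.0649068
#> 4 150     0.4801382
```

The 20th circle grows 46% at a 25 um gap but only 0.48% at 150 um, so
150 um is the smallest tested gap at which sequential exposures no longer
measurably enlarge each other -- that is the `d_critical` the slicer uses.

The axisymmetric reference exposure (radius 17.5 um, height 20 um, 1 s at
22 mW/cm^2) shows why: with the graded illumination tail the partially
cured zone reaches far beyond the pattern edge, while perfectly uniform
light leaves only a thin reaction-driven skirt:

```r
run_reference_simulation("graded")$extent    # 141.2 um beyond the edge
run_reference_simulation("uniform")$extent   # 9.6 um
```

Closed-loop dynamic correction of a five-point star (project, cure, measure
the tips and trenches along rays from the centre, adjust, flush, repeat):

```r
st <- run_star_correction(max_iters = 6)
#> converged after 2 iterations, max |deviation| = 4.21 um
```

Comparing the four exposure modes on a 3x3 grid of 25 um pillars at a 30 um
gap (fidelity = mean |measured - designed| equivalent diameter, um):

```r
compare_exposure_modes(seed = 1)
#>              mode fidelity
#> 1   tracked_flush      8.7
#> 2      flush_only     21.0
#> 3      sequential     29.0
#> 4 single_exposure     30.0
```

A command-line front end wraps the same functions
(`inst/cli/igisml.R compile | fabricate | calibrate | simulate | measure |
fixtures`); designs round-trip as DXF (closed LWPOLYLINE / CIRCLE on layers
`CURE` and `CHANNEL`), masks as 8-bit PNG, configuration as YAML, reports as
JSON/CSV.

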
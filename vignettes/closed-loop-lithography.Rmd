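---
title: "Closed-loop image-guided maskless lithography: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop image-guided maskless lithography: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(igisml)
```

## The problem

In-situ maskless lithography cures microfluidic device features directly in a
pre-polymer-filled blank channel: a DMD projects a UV pattern through a
microscope, free-radical photopolymerization gels the illuminated volume, and
partially cured material is washed away. Two physical facts make dense
feature placement hard. First, projector illumination does not cut off at the
pattern edge; it decays gradually outward, so every exposure deposits a weak
dose over a wide skirt around the feature. Second, photogenerated radicals
diffuse, carrying reactivity beyond the illuminated zone. Together these
produce the *proximity effect*: features printed near each other, or one
after another, grow beyond their drawn size and eventually bridge.

The closed-loop answer implemented here is image guidance with flush-flow:
watch each feature cure through the camera, switch its light off the moment
its edge reaches the target outline, flush away sub-gel material before the
next exposure, and schedule exposures so that simultaneously accumulating
features are at least a critical distance `d_critical` apart. This package
implements the whole loop in software, with a reaction-diffusion simulator
standing in for the physical device so every control algorithm can be
exercised and measured.

## The polymerization model

Four species live on a 2-D grid (plan view, depth-averaged) or an r-z grid
(axisymmetric): photoinitiator $S$, radicals $R$, monomer $M$, polymer $P$,
in monomer-equivalent concentration units with $S_0 = M_0 = 1$:

$$
\begin{aligned}
\partial_t S &= -k_i I S \\
\partial_t R &= D_R \nabla^2 R + k_i I S - 2 k_{t,\mathrm{eff}} R^2 \\
\partial_t M &= D_M \nabla^2 M - k_p R M \\
\partial_t P &= k_p R M
\end{aligned}
$$

with no-flux boundaries, no dissolved terminator, zero polymer diffusion,
and $k_{t,\mathrm{eff}} = k_t / (1 + \gamma_t P / M_0)^2$ (a
conversion-dependent termination slowdown, the classic gel effect; the
calibrated defaults use $\gamma_t = 0$, see below). Cells that have gelled
and survived a flush are frozen: no reaction inside them and no diffusive
flux across their boundary, modelling anchored solid material.

Integration is explicit FTCS with one refinement: the stiff quadratic
termination sink is folded into the radical update semi-implicitly
($R^{n+1} = (R^n + \Delta t\,(\text{gen} + \text{diff})) / (1 + 2 \Delta t\,
k_{t,\mathrm{eff}} R^n)$), which preserves positivity at any step size. The
step is selected automatically at 0.9x the binding stability bound
(`stability_bounds()`): the FTCS diffusion bound $h^2 / 4 D_{\max}$ and a
reaction-rate bound. The scheme conserves $\sum (M + P)$ to round-off under
no-flux boundaries, and a property test holds it against an independent
stiff-ODE integration (deSolve) at $10^{-4}$ relative error.

## Illumination

A pattern mask is rasterized at pixel centres (row 1 at the top, micrometre
origin at the lower-left corner, an explicit um-to-pixel mapping on every
object). The top-hat profile is `peak` inside the pattern and exactly zero
outside. The graded profile adds the measured-in-spirit halo: intensity
decays as $\exp(-d/L)$ with Euclidean boundary distance $d$, with
$L = 33.4\,\mu m$ so the tail reaches 5% of peak at 100 um, clamped to zero
below 1% of peak. The tail is phenomenological -- there is no diffraction or
lens model -- and it is the dominant proximity channel. When several
patterns are projected simultaneously their halos superpose, capped at the
projector peak.

## Calibration: what the defaults mean

No physical rate constants are available for this resin system, so the
kinetic defaults are a *calibrated operating point* chosen once so that the
simulator reproduces the documented system-level behaviours, and frozen:

* `k_i = 0.08 /(s mW/cm^2)`, `k_p = 3`, `k_t = 0.5`, `gamma_t = 0`,
  `D_R = 30 um^2/s`, `D_M = 0`.
* `theta_gel = 0.5`, `theta_partial = 0.05`: the field's normalized cure
  level distinguishes only fully cured (1) from partially cured (<1), so the
  gel and detectability thresholds are unavoidable implementation constants;
  both are exposed in the configuration.
* working dose: exposures print at `dose_scale = 0.24` of the 22 mW/cm^2
  full power for 1 s. The *fully cured* reference level `P_ref` is defined
  by an isolated exposure at full reference dose; gelation is treated as an
  absolute material threshold `theta_gel * P_ref`, not a per-exposure
  relative one. The working dose is the dose at which an isolated 35 um
  circle prints at near-nominal size, exactly how the physical working dose
  would be chosen.

The deliberate choice of *weak* termination (`k_t = 0.5`, generation-limited
radicals) matters. With strong termination the quasi-steady radical level
scales as $\sqrt I$, so the cure deposited by the illumination tail decays
with *twice* the optical decay length; inter-feature coupling then persists
far beyond 150 um and no parameter choice reproduces the measured gap
ladder. With weak termination cure responds approximately linearly in local
intensity, the partial-cure skirt follows the optical tail, and the
calibration experiment behaves: the 20-circle rows at 25/50/100/150 um gaps
give strictly decreasing 20th-vs-1st diameter deviations
(about 46%, 43%, 7%, 0.5% at the defaults), so the critical distance
calibration returns 150 um.

Two further modelling decisions shape multi-exposure runs:

* **In-situ measurement.** Each feature's equivalent diameter is measured
  from the cure field at the end of *its own* exposure -- the way the live
  image shows it. For near-linear kinetics the end-state polymer field of a
  whole row is nearly independent of exposure order (doses superpose), so
  order-dependent broadening is only observable the way the method itself
  observes it.
* **Inter-exposure radical quench.** Radicals remaining when a pattern's
  light switches off are zeroed before the next exposure, standing in for
  the stage-move dark interval. Without it, long-lived radicals accumulate
  dark cure across a long row and bridge gaps explosively rather than
  gradually.

## The virtual camera and triggering

The camera maps the normalized cure level $v$ to grey levels
phenomenologically: a white halo over the partially cured band
($0.05 < v < 0.5$), a dark edge proportional to $|\nabla v|$ (absolute
scale `grad_ref`, so faint early gradients render faintly), and a bright rim
of fresh gel ($0.5 \le v < 0.8$) that switches on abruptly at gelation and
fades as the solid ages; Gaussian blur and seeded Gaussian noise follow.
Tracking the mean grey of a 10-px annular mask centred on the target outline
then produces the characteristic two-peak curve: first the halo crossing the
mask, then the dark edge with the fresh-gel rim.

The closed-loop trigger uses a calibrated absolute cutoff (default grey 100
in a 40-background image, i.e. between the halo plateau and the fresh-gel
rim level) so it fires within a frame of the gel front reaching the outline;
an adaptive cutoff (baseline mean + max(4 sd, 10)) and first/second-peak
rules are available for generic series. Because the trigger keys on
geometry, not time, the final feature size is invariant to UV power: the
100 um tracked target prints within 0.5% across 5/13/22 power settings,
only the trigger time changes. Absolute grey values are not comparable to
any real camera; only the shape of the series carries meaning.

The annulus thickness default is 10 px. (The figure-level description of
the reference system says 8 px in one place and 10 px in the text; the text
value is the default, and it is a configuration field.)

## Slicing, flush-flow and the exposure modes

The layout compiler clips every cured region to a grid of projection tiles
(projector field minus a 100 um stitching margin), dilates each unit mask by
50 um for stitching and subtracts the channel voids, then partitions units
into slices by greedy coloring of the conflict graph (two units conflict
when closer than `d_critical`; centre-to-centre by default, with a
boundary-gap option since the calibration experiment is phrased as a gap).
Greedy order is deterministic (y, then x, snapped to 1e-6 um); the suite
verifies feasibility by an independent all-pairs check and agreement with an
exhaustive chromatic-number oracle on the fixtures.

`fabricate()` executes one of four modes at the same fixed dose:
single exposure of everything, sequential exposures, sequential with
flushing (`flush_only`), and sequential with flushing plus edge-tracked
triggering (`tracked_flush`). The figure of merit is the mean absolute
deviation of measured from designed equivalent diameters. The comparison is
run deliberately overdosed (`dose_scale = 0.30`) because that is the
situation the closed loop exists to fix; at the calibrated defaults the
ordering on the 3x3 pillar fixture is tracked (~9 um) < flush-only (~21) <
sequential (~29) < single (~30). Flush-only features also come out slightly
enlarged next to already-cured neighbours -- frozen solid blocks radical
out-diffusion, so the same dose cures a little further -- which is why
tracking, not flushing alone, closes the repeatability gap.

## Dynamic shape correction

For shapes with sharp angles the outline is corrected online. Tips (convex
vertices) and trenches (concave) are classified by the cross product of
adjacent edges; the observed cure contour is measured along rays from the
shape centre through each classified vertex, leading edges meaning overfill
and trailing meaning underfill; each out-of-tolerance vertex is moved
radially by `-gain * deviation` (gain 0.8). Because gelled material cannot
be un-gelled, the loop must approach the target from below: the initial
projection is shrunk radially by 25 um, and the per-iteration dose is
reduced (`dose_scale = 0.35` of working power) so each iteration adds a
modest shell. On the five-point star fixture (outer radius 150 um, inner
60 um, consistent with a 100 um scale bar) the maximum tip/trench deviation
falls below 5 um within 2-3 iterations of the 6 allowed, with the average
deviation non-increasing.

The offline corner correction uses the Fernandez-Guasti squircle family
$x^2 + y^2 - (s^2/r^2) x^2 y^2 = r^2$, which interpolates between a circle
($s = 0$) and a square ($s = 1$). The published family covers right angles
only; the generalization here remaps each corner window through the
right-angle solution scaled by the corner's half-angle ratio, so it reduces
exactly to the circle-square case at 90 degrees, leaves the shape unchanged
at $s = 0$, and passes through the square corner point at $s = 1$. If a
remap self-intersects, the corner window is halved and retried.

## Metrology

Radial profiles cast 100 rays (3.6 degree spacing) from the
intensity-weighted feature centroid and find the half-maximum edge crossing
sub-pixel by linear interpolation (an absolute-level option serves cure
fields normalized to `P_ref`). Rays that leave the image without crossing
are an error unless a cap is supplied; merged features are measured with the
cap at half the nearest-centre distance. Roughness is the pooled RMS of
radius deviations from each feature's mean (one number per device, matching
how a device-level roughness is quoted). Equivalent diameter is twice the
mean radius; broadening series are percent change against the first
feature. DLD row shifts are recovered by clustering centres into rows by y
and averaging the lateral offset between consecutive rows folded modulo the
column pitch.

## Problem sizes and what the tests do (and do not) show

The packaged study conditions are desk-scale: the axisymmetric reference
solve uses a 220 x 20 cell grid at 1 um (within the 400 x 100 budget and
about a second of compute); the gap-ladder calibration runs 4 rows of 20
circles at 2 um plan-view resolution with per-exposure windows covering the
clamped tail plus a diffusion pad (about 15 s); the star loop runs at most
6 exposures on a ~230^2 grid. Everything is deterministic for a fixed seed
-- the only randomness is camera noise -- and reports are bit-reproducible.

The synthetic generator emulates the geometry and dosimetry of the physical
process, not its chemistry: no oxygen inhibition, no thermal effects, no
swelling (beyond an optional isotropic scale), no chain-length statistics,
no optical point-spread function, and a camera with an arbitrary grey
mapping. Passing tests therefore demonstrate that the *control layer* --
tracking, triggering, slicing, flushing, correction, metrology -- behaves
correctly against a physically plausible curing field, and that the
calibrated field reproduces the documented system-level behaviours; they do
not validate the kinetics against a real resin, and the experimental
roughness and row-shift accuracy numbers of physical devices are
deliberately out of scope.

## Known limitations

* The plan-view model is depth-averaged; the axisymmetric mode resolves z
  but assumes no optical attenuation by default.
* The gel front of a small feature is spatially flat near the gelation
  knee, so tracked features carry a few um of systematic overshoot set by
  the camera resolution and annulus width.
* Greedy slicing is optimal on the packaged fixtures but is not an optimal
  colorer in general (it stays within the max-degree + 1 bound).
* DXF support is deliberately a dialect: closed LWPOLYLINE and CIRCLE on
  layers CURE and CHANNEL; everything else is rejected loudly.
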
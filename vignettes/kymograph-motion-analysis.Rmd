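---
title: "Quantifying bulk and fast transport in kymographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bulk and fast transport in kymographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymoflow)
```

## The measurement problem

A kymograph is a space–time image: one row per movie frame, one column
per position along a line drawn down a neurite and across its growth
cone. Anything that moves along the line appears as a sloped streak,
and the slope *is* the velocity — `v` pixels per frame (p/f)
corresponds to a streak at `atan(v) * 180 / pi - 90` degrees from the
distance axis, so a vertical streak (−90°) is stationary and a
horizontal one (0°) is infinitely fast.

Growing neurons mix two motion regimes that differ by three orders of
magnitude. Bulk translocation — the coherent forward advance of the
microtubule array, docked mitochondria and other axonal material — runs
at 1–100 μm/h, well under a pixel per frame at typical sampling
(0.1 μm/px, 5 s/frame). Motor-driven transport of individual cargoes
runs at 0.05–5 μm/s, many pixels per frame. Retrograde flow in the
growth-cone periphery sits in between (≈ −100 μm/h, ~1.3 p/f at the
same sampling). A single velocity estimator must therefore work from
~0.02 p/f to ~30 p/f.

## The estimator

### The gradient kernel

`lk_flow()` is a one-dimensional Lucas–Kanade kernel. For each pixel it
solves the brightness-constancy least-squares problem over a
`window × window` neighborhood (default 9 px): the horizontal velocity
that best maps a row onto the next row, computed from the spatial
(column) derivative of the Gaussian-smoothed image
(`smoothing_sigma = 1` px) and the temporal (row) difference. The raw
gradient solution is biased for any non-infinitesimal displacement, so
the kernel refines it by warping: the next row is resampled at the
current estimate and the residual displacement re-estimated
(`n_iter = 3`). Warping uses prefiltered cubic B-spline interpolation.
This matters: the interpolation error of linear (and Catmull–Rom)
resampling has an odd component that couples with the image gradient
and biases sub-pixel estimates by ~10%; the B-spline interpolant's
error is even-dominant and the measured bias drops to ≲0.5%.

Each warp step is clamped to ±1.5 px, the trust region of a gradient
step at the default smoothing scale. This clamp is what gives the
kernel the characteristic failure of gradient flow on fast motion: when
the true displacement per frame exceeds what three clamped steps can
reach, the iteration stalls and the estimate saturates. On the line
benchmark the baseline is essentially exact up to 4 p/f, reaches 10%
error at 5 p/f and degrades steeply beyond — the documented behavior of
classical Lucas–Kanade trackers on kymographs. Without the clamp the
iteration would converge at any speed on a *single* clean line (the
line's spatial structure scale grows with its speed), which no real
tracker does on real data.

Pixels whose mean squared spatial gradient falls below `min_gradient`
are invalid — with no spatial structure there is no motion information.
Invalid pixels are `NA` and excluded from every downstream mean; they
are never zero-filled. The last row has no successor and is invalid by
construction.

### The rotation augmentation

`kymoflow()` runs the same kernel twice: on the kymograph and on its
90°-rotated copy. The rotation is implemented as the lossless axis swap
(matrix transpose): no interpolation, involutive, and a feature moving
at `v` p/f appears at exactly `1/v` p/f with its sign preserved. Fast
motion thereby becomes sub-pixel motion — the regime where the gradient
kernel is most accurate — and the rotated branch's estimates are
back-transformed (`v ← 1/v`, coordinates transposed back).

Merging the branches per pixel needs care, because a stalled estimator
does not announce failure: on very fast motion the unrotated branch
returns a small velocity indistinguishable *by magnitude* from true
slow motion. The merge therefore uses the normalized
brightness-constancy residual (misalignment energy over signal energy)
as a health check; a branch is *healthy* when valid and its residual is
below `max_residual` (0.02 — roughly a 0.4 px residual misalignment,
far above the noise floor of the images this package targets and far
below a stall). The rules, in order:

1. a healthy unrotated estimate below
   `switch_threshold × (1 − hysteresis)` (0.8 p/f by default) wins
   outright — slow, well-explained motion is never overridden, because
   the back-transform `1/v` amplifies any rotated-branch misestimate;
2. a healthy unrotated estimate above
   `switch_threshold × (1 + hysteresis)` defers to a healthy rotated
   estimate; inside the band the two are averaged, which also cancels
   their small opposite-signed residual biases near 1 p/f (the symmetry
   point of the two branches, hence the default threshold);
3. where only one branch is healthy it is used; where neither is, the
   pixel is invalid.

Back-transformed velocities with `|v_rot| < 1e−6` p/f are clamped to
invalid rather than reported as enormous velocities: a near-stationary
rotated estimate carries no information about near-infinite speed. The
same reasoning excludes 0° from angular-error summaries — its true
velocity is infinite.

### Validation: the rotated-line benchmark

`make_benchmark_set()` renders 91 kymographs (128 × 128 by default),
each one anti-aliased straight line through the center at 0° to −90° in
1° steps, with Gaussian cross-section (stroke width 2 px — gradient
flow needs non-binary edges) and optional noise; the defaults are
noise-free. The true velocity of every line is `cot(|angle|)`, so
accuracy can be scored exactly. `run_benchmark()` reports per-angle
velocity statistics over the line-support pixels (the background has no
defined ground-truth motion; the averaging domain is exposed as
`stat_domain`) and the average absolute angular error (AAE): estimated
velocities are converted to angles, averaged per image, and the
absolute deviation from the true angle is averaged across images —
over −1°…−90° for the full summary and −3°…−90° for the restricted
one. In the angle metric a 20% velocity error at 57 p/f is only ~0.2°,
which is what makes the fast end comparable at all.

The test suite asserts what the benchmark shows: the augmented
estimator stays within 10% of the true velocity over the whole range up
to ≥28 p/f and reaches an AAE well under the 2° bar typical of
state-of-the-art motion tracking, while the baseline's error exceeds
10% for every angle at 5 p/f and beyond and its AAE is several-fold
larger. One honest caveat: at fast angles our clamped baseline
saturates *deterministically* (per-angle sd → 0), so the classical
observation that the augmented map is also more *precise* (smaller sd)
than a noisy LK tracker at fast angles does not reproduce with this
kernel; the advantage here is accuracy, and the suite asserts RMSE
superiority instead.

## The synthetic neurite

`simulate_neurite_kymograph()` generates the full test scene with known
ground truth. Its defaults are the measured regimes of rapidly growing
sensory neurons:

| parameter | default | meaning |
|---|---|---|
| `gc_velocity` | 24 μm/h | growth-cone advance |
| `retro_velocity` | −97 μm/h | P-domain retrograde flow |
| `p_domain_width` | 5 μm | peripheral (retrograde) domain |
| `axon_profile` | `gc · exp(−d/150 μm)` | bulk velocity behind the T-zone |
| `fast_event_rate_antero/retro` | 0.5 / 0.38 min⁻¹ | fast transport events |
| `fast_speed_mean/sd` | 0.1 / 0.05 μm/s | event speeds, truncated at 0 |
| `speckle_density` | 2 μm⁻¹ | fluorescent speckles along the neurite |
| `duration`, grid | 40 min, 480 × 384 | 5 s/frame, 0.1 μm/px |

Speckles advect through the bulk field (anterograde along the axon,
retrograde in the P-domain, discontinuity at the transition zone, the
whole pattern moving with the growth cone); new speckles appear at the
leading edge and in density deficits, emulating continuous assembly,
and retrograde speckles are *recycled* — terminated within one
retrograde step of the advancing T-zone. The recycling is not a
cosmetic choice: without it, speckles that happen to land in the narrow
strip the T-zone sweeps per frame ride the boundary indefinitely and
pile up into an unphysically bright band that defeats threshold-based
edge detection. Fast events are Poisson center-crossings superimposed
on (not replacing) the bulk speckles and clipped to the cell interior.
The default friction decay length (150 μm) reflects that in the distal
axon bulk motion tracks the growth cone closely, declining toward the
cell body; over the ~30 μm field it amounts to a few percent. The field
geometry (growth cone starting at 35% of a 38.4 μm field) leaves ~8 μm
of initial axon behind the T-zone and room for the fastest simulated
cells to grow for the full recording.

What the simulator does **not** emulate: photobleaching, speckle
appearance/disappearance kinetics unrelated to motion, uneven
illumination, focus drift, two-dimensional growth-cone shape, and
curved or kinked fast-event paths. Passing the recovery tests therefore
shows that the pipeline is correct and accurate *for motion rendered
under brightness constancy at realistic rates, densities and noise*; it
does not certify performance against illumination artifacts, which the
original hand-tracing workflow sidesteps by running flow on rasterized
traces rather than raw images (`read_trace_image()` /
`traces_to_flow_input()` reproduce that workflow).

## The downstream pipeline

`estimate_gc_track()` locates the growth cone per frame as the most
distal pixel above half the Otsu threshold of the clipped image (the
brightest 0.5% is clipped first so overlapping speckles cannot compress
the histogram; half-Otsu catches dim single speckles at the edge while
staying far above the noise floor), interpolates gap frames, median
filters, and reports the calibrated least-squares slope as the
growth-cone velocity. The alternative `method = "trace"` accepts a
hand-drawn track, either of the leading edge or of a C-domain landmark.

`shear_align()` translates each row so the growth cone occupies a fixed
column. The default shift is nearest-pixel: shearing must move
velocities, never rescale them, and linear interpolation across the
sharp retrograde/anterograde transition would fabricate intermediate
velocities that exist nowhere in the data (that choice also makes the
"shear preserves the velocity multiset" invariant exact).
`interp = "linear"` remains available for smooth intensity images.

`profile_from_flow()` averages each column of the sheared, calibrated
map over its valid pixels; distance runs from the distal edge toward
the axon. For bulk profiles, `max_speed_umh` excludes pixels faster
than a cutoff — bulk translocation is 1–100 μm/h and motor-driven
events (≥ 0.05 μm/s = 180 μm/h) would otherwise leak into the means;
the recovery tests use 300 μm/h, comfortably above retrograde flow and
below typical event speeds. `align_tzone()` sets the distance origin at
the first retrograde-to-anterograde zero crossing scanning from the
distal end: detection scans a 3-bin moving mean for robustness, but the
crossing itself is interpolated between *raw* bin values, so smoothing
never touches reported numbers. `average_profiles()` interpolates
aligned profiles onto a shared 1-μm grid and reports across-cell means
with across-cell 95% CIs — the across-cell convention matches how
population profiles are reported in the field; per-pixel CIs within one
cell would both understate uncertainty (adjacent rows share estimation
windows and are strongly correlated) and measure the wrong replicate.

That last point shapes the validation tests. The estimator is more
precise than accurate: its random error per column mean is ~0.2% while
its systematic error (interpolation, boundary mixing at the T-zone,
window overlap) is ~1%. A "truth inside the per-column ci95" criterion
is therefore unattainable for *any* estimator of this quality — the CI
shrinks with sample size, the bias does not. The suite instead checks
across-cell coverage of the averaged profile (cell replication
randomizes each cell's systematic wiggle), growth-cone velocity to the
±2 μm/h a practitioner would demand, retrograde flow to 2% per cell and
1% in the population mean, and the T-zone location to 1 μm (one
averaged bin; the flow window blurs the discontinuity over ~0.5 μm, so
sub-bin agreement is not meaningful). Bulk-recovery simulations disable
fast events, mirroring the real workflow in which bulk analysis runs on
traces of slow structures only; fast events are exercised separately by
the flux module.

## Flux and the mass budget

`count_flux()` counts, per direction, the traces that straddle the
kymograph's center column and whose regression velocity is fast
(default threshold 0.05 μm/s, the bottom of the motor range — the
qualitative field definition, "crossing the paths of slower objects",
is not computable from a trace in isolation, so the threshold is
explicit and adjustable). A trace counts once no matter how often it
wanders across the center: the quantity is microtubules per minute, not
crossings per minute, which also makes the count invariant to how
densely a path was traced. `mass_budget()` turns directional fluxes
into an axonal growth contribution:

    net_flux            = antero_flux − retro_flux          [MT/min]
    net_flux_h          = 60 × net_flux                     [MT/h]
    transported_length  = net_flux_h × mt_length            [μm/h]
    net_axonal_growth   = transported_length / mt_per_cs    [μm/h]
    mean_interval       = 1 / net_flux                      [min]

All stored values are unrounded; only the print method applies the
conventional table precision (flux to 2 decimals, MT/h and growth to 1,
transported length to whole μm/h when ≥10). Published tables of this
kind round intermediates inconsistently — rounding only at display
keeps the identities above bit-exact and the comparisons honest.
`net_flux_from_rate_fraction()` converts the older
interval-and-direction-fraction style of report,
`(2f − 1) / interval`, to the same net-flux scale.

## Numerical choices and degenerate inputs

* Benchmark endpoints: 0° is infinite velocity — flagged, excluded from
  velocity statistics and AAE; −90° is exactly 0 p/f (set symbolically,
  not `cot(π/2)` floating-point dust).
* `velocity_to_angle()` maps the sign of negative velocities into the
  quadrant below −90°, keeping retrograde and anterograde distinct in
  angle space; within one quadrant plain arithmetic means of angles are
  well-defined, so no circular statistics are needed.
* Readers reject shape-inconsistent input (frame size mismatches, trace
  images not matching the kymograph) rather than padding; calibration
  has no silent default — argument > JSON config > TIFF tags, else an
  error.
* TIFF float storage covers [0, 1]; writers rescale affinely when data
  fall outside (the estimators are invariant to affine intensity maps),
  and the CLI records the scale in a sidecar JSON.
* Degenerate regressions: constant `y` returns slope 0 and r² 0;
  constant `x` is an error; traces spanning zero time are errors.
* Profiles with no retro→antero crossing are returned unaligned with a
  warning and `aligned = FALSE`, never silently shifted.

## Problem sizes

The shipped tests run the full 91-line benchmark (128 × 128 px) for
both estimators, a 20-cell simulated population (480 × 384 px each)
through the complete recovery pipeline, and 100-seed event-rate
recovery; the whole suite completes in under a minute on one core.
These sizes were chosen so that every statistical claim is made with
enough replication to be meaningful while a contributor can run the
suite interactively.

## Known limitations

* The rotation set is {0°, 90°}. Arbitrary-angle rotation exists
  (bilinear resampling) but is not part of the combined estimator; a
  45° branch would trade the losslessness of the axis swap for coverage
  of the ~1 p/f band, where the two existing branches already average.
* The baseline's stall is deterministic, so its failure mode differs
  from noisy classical trackers (see the benchmark caveat above).
* Recordings whose growth velocity changes substantially should be
  split into sections by the user before shearing; the package does not
  segment them automatically.
* `count_flux()` trusts its input traces; it does not detect fast
  speckles in raw kymographs.
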
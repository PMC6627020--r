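---
title: "Quantifying nuclear shape dynamics, recoil events and nuclear mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear shape dynamics, recoil events and nuclear mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmorph)
```

## Scope

Cells migrating through dense extracellular matrix must squeeze their
stiffest organelle, the nucleus, through pores smaller than its own
cross-section. Time-lapse fluorescence microscopy of a labelled nucleus
(e.g. H2B-GFP) shows a characteristic cycle: the nucleus elongates, forms a
transient bilobed "hourglass" while traversing the constriction, and then
recoils to a rounder shape — often together with a short-lived peak in
migration speed. `nucmorph` quantifies this cycle end to end: per-frame
segmentation and outline extraction, shape descriptors, a rotational
overlap statistic for frame-to-frame shape change, centroid kinematics,
automated detection of the recoil ("phase IV") events, and — on the
mechanics side — analysis of AFM force–indentation cycles on cells
(stiffness, penetration, dissipated energy).

## Segmentation and outlines

Frames are thresholded per frame (automatic Otsu, or a fixed value),
because intensity decays over hours-long movies and a single global
threshold would drift. Objects are labelled with 8-connectivity, interior
holes are filled by default (chromatin labels can be spotty), and objects
under `min_area` (default 200 px²) are discarded.

Outlines are traced by marching squares at the 0.5 iso-level of the binary
object, so the polygon passes through pixel-edge midpoints rather than
along pixel edges. Raw pixel-edge boundaries systematically overestimate
perimeter (a staircase around a disc is up to 27% longer than the circle),
which would bias every perimeter-based descriptor; with the midpoint
convention plus a light circular moving-average of the vertices (window 5)
the perimeter of a rasterized disc of radius 100 px is within 0.5% of
`2*pi*r` and its area within 0.1% of `pi*r^2`. Pixel centres sit at integer
coordinates, x rightward, y downward; all exported centroids and lengths
are converted to µm via the pixel size.

One practical caveat found while validating on synthetic movies: when the
nucleus occupies a very small fraction of a wide field (a 14 px-radius
nucleus in a 512×512 frame is 0.2% of the pixels) and the image is noisy,
Otsu's criterion can split the broad background mode instead of separating
the nucleus. The segmentation therefore accepts an optional Gaussian
pre-smoothing `smooth_sigma` (default 0 px, i.e. off; 1–2 px recommended
for noisy movies), which restores a clean bimodal histogram without
measurably shifting the mid-level boundary.

Tracking keeps exactly one object per frame (largest object, or nearest to
the previous centroid). A nucleus lost for up to `max_gap` frames (default
2) is bridged by linear centroid interpolation; bridged frames are flagged
and all statistics exclude the steps that touch them. Longer losses split
the sequence and the longest segment is kept. The imaging source never
dictates how missing frames were handled, so this policy is a package
decision, stated here and surfaced in every output table.

## The nuclear irregularity index

Four dimensionless descriptors of a closed outline are combined into one
index of deviation from circularity:

* **aspect** — major/minor semi-axis ratio of the equivalent ellipse,
  computed from the exact second area moments of the polygon (≥ 1);
* **area/box** — polygon area over the area of its *axis-aligned* bounding
  box (π/4 for a circle, 1 for an axis-aligned rectangle);
* **radius ratio** — max/min Euclidean distance from the area centroid to
  the boundary, with the minimum evaluated over perpendicular feet on
  every edge as well as vertices (≥ 1);
* **roundness** — `perimeter² / (4π·area)` (1 for a circle).

$$\mathrm{NII} = \mathrm{aspect} - \mathrm{area/box} +
\mathrm{radius\ ratio} + \mathrm{roundness}$$

For a circle this gives $1 - \pi/4 + 1 + 1 = 2.2146$, the reference value
every analytic and rasterized test pins down. The index is invariant to
translation and uniform scaling. It is *not* fully rotation-invariant: the
bounding box is axis-aligned (matching the morphometry software lineage
this index descends from), so area/box is orientation-sensitive. This is
deliberate and documented rather than "fixed": rotating a 2:1 ellipse by
45° changes its NII by up to ~0.2. Quarter-turn rotations and all
rotations of (near-)circular outlines are invariant, which the test suite
asserts.

The per-step shape change is ΔNII, the absolute difference of consecutive
NII values; rounding events appear as negative *signed* changes, which the
event detector uses internally while all reported ΔNII values are
magnitudes.

## Fluctuation: rotational maximum overlap

For consecutive outlines $A_1, A_2$ the package aligns centroids, rotates
the later shape through the full circle in 1° steps (configurable), and
takes the maximum intersection area over all angles:

$$\mathrm{Fluctuation} = \frac{A_1 + A_2 - 2\,(A_1 \cap A_2)}{A_1 + A_2}$$

0 means the shapes coincide at some rotation, 1 means they never overlap;
the statistic equals $1 - \mathrm{Dice}$ at the optimal angle. Ties are
broken toward the smallest angle, and the later shape is the one rotated
(the statistic is symmetric to within the 1° discretization, which the
suite asserts).

Intersections are computed exactly on the polygons by clipping, not on
re-rasterized masks, so the statistic carries no resampling noise; the
clipper snaps coordinates to an internal integer grid, which bounds every
computed area to ~1e-9 relative accuracy — the reason "identical shapes
give 0" is asserted at 1e-8 rather than literal zero. A 1° grid search on
a continuous objective can miss the true optimum by at most the angular
Lipschitz bound of intersection area versus angle; the suite verifies
against a 0.1° brute force on random polygon pairs.

## Kinematics

Step speed is centroid displacement over the frame interval; mean speed is
total path length over elapsed time; beeline speed is the straight-line
distance between the first and last centroid of a 55-min window divided by
the window length (disjoint windows, per-window values and their mean).
Centroids are deliberately *not* smoothed before speed computation — the
speed oscillations are the phenomenon, and smoothing would erase them; a
moving-median option exists but is off by default. The full-track beeline
can never exceed the mean path speed (triangle inequality); note that the
*windowed* beeline mean is compared against windowed path speeds, not the
full-track mean, since the window tiling may drop a slow tail.

## Recoil (phase IV) event detection

The original observations identified recoil events by eye as a combination
of an NII decrease (rounding) with a speed increase. The package replaces
inspection with an explicit, configurable rule: a step is a candidate when
its speed is a local maximum with topographic prominence at least
`min_prominence` (default 0.1 µm/min) and at least `baseline_factor`
(default 2) times the running median of the speed series; candidates
closer than `min_separation_frames` (default 3) merge, keeping the larger;
a candidate is accepted only if the signed NII change across
`[t - rounding_window, t + rounding_window]` (default 1 frame) is
negative. Every default is exposed in the configuration, and the events
table supports manual curation.

Detected events are aligned at their onset (default; the base frame of the
monotone speed rise) or peak, resampled onto a common relative time axis,
and aggregated into mean ± s.e.m. ensembles (s.e.m. with the n−1
denominator, reported only where ≥ 2 traces contribute). For
microdevice-style recordings, alignment at the pore centre is available:
time 0 is the frame at which the nucleus centroid first crosses an
annotated pore line. Steps inside event windows versus all remaining steps
form an exhaustive, disjoint partition, summarised by medians and
quartiles and compared with the two-tailed unpaired Mann–Whitney test and
the two-sample Kolmogorov–Smirnov test, the appropriate choices for
independent non-Gaussian samples.

## AFM force-curve mechanics

Approach/retraction force–distance cycles are analysed in four steps.
The baseline is the median of the first 30% of approach samples; the
threshold contact estimate is the first sample exceeding baseline +
`noise_k`·MAD for ≥ 5 consecutive samples. Because a threshold crossing is
systematically late in noise, the contact *position* is then refined by
fitting the Hertzian profile $F = C\,\max(z' - z_0, 0)^{3/2}$ over the
whole approach (prefactor profiled out, $z_0$ optimized), which uses the
high-signal part of the curve; on noise-free synthetic curves this
recovers the programmed contact exactly.

Indentation is $\delta = (z - z_\mathrm{contact}) - F/k$, the piezo travel
past contact minus cantilever bending. Penetration at a setpoint (default
2 nN) is read off the approach curve with linear interpolation. Stiffness
comes from the Hertz sphere model
$F = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}$ — linear in
$\delta^{3/2}$, so the fit is a through-origin least-squares regression —
over 10–90% of the indentation range by default, excluding contact-point
uncertainty and deep-indentation substrate effects. The Poisson ratio is
fixed at 0.5 (incompressible cell), standard force-spectroscopy practice.
Energies are trapezoidal integrals of force over indentation:
$E_\mathrm{dissipation} = E_\mathrm{approach} - E_\mathrm{retraction}$,
with the adhesion area (negative-force part of the retraction) reported
separately and excluded, and relative dissipation
$E_\mathrm{dissipation}/E_\mathrm{approach}$. Repeated probings of one
cell (typically 3–5) are summarised by the median.

## The synthetic generators

The movie generator renders a single bright nucleus (foreground 200,
background 10, optional Gaussian noise) translating at a programmed speed
with isolated triangular peaks, while the shape cycles between a deformed
state — a union of two discs pinched into an hourglass and stretched along
the heading — and a circular disc at each peak. Defaults are the study
conditions: 60 frames at 5-min intervals, 0.5 µm pixels, 7 µm nucleus
radius in a 512×512 field, 0.3 µm/min baseline speed (interstitial
migration is typically 0.2–0.4 µm/min), three peaks of amplitude 5×, and a
deformation (elongation 1.2, pinch 0.15) chosen from a parameter scan of
the shape model so that the programmed recoil drops the NII by ~0.8. The
generator emits exact ground truth (centroids, speeds, shape parameters,
peak frames) and is bit-reproducible under a seed without disturbing the
caller's RNG stream.

The force-curve generator produces a Hertzian approach to a force setpoint
(defaults: E = 1 kPa, 5 µm bead radius — a 10 µm bead —, 15 nN setpoint),
a retraction scaled to a programmed hysteresis fraction of the approach
work, an optional adhesion dip, and additive or multiplicative noise.

What the generators deliberately do *not* emulate: collagen-fibre texture
and autofluorescence, uneven illumination, photobleaching beyond what
per-frame thresholding absorbs, nucleus rotation decoupled from heading,
out-of-focus excursions, and viscoelastic (rate-dependent) force response.
Passing tests therefore demonstrate correctness of the measurement chain
on known ground truth, not robustness to every artefact of real
recordings; the pre-smoothing caveat above is one example of a real-data
effect that only surfaced under synthetic noise.

## Numerical choices and degenerate inputs

Polygon area, centroid and second moments use exact Green's-theorem sums;
degenerate (zero-area) polygons and sub-traceable objects (a 1-px object
has no meaningful outline) raise errors rather than returning values. An
all-background frame yields an *empty, flagged* mask frame, not an error,
so movies with transient losses flow through tracking. Angle ties in the
rotation search resolve to the smallest angle; equal-distance pore-line
crossings snap to the earlier frame. Problem sizes in the tests — movie
lengths of 24–60 frames, 100-seed noise ensembles, 1000-replicate null
simulations at n = 30 per group — were chosen so the full suite exercises
every claim at the stated tolerances while remaining quick to run on a
laptop.

## Known limitations

Single-nucleus tracking only (no identity management across crossing
cells, no mitosis handling); 2-D projections only; the NII's
orientation-sensitive area/box term (above); the Hertz model's small-
indentation and sphere-on-flat assumptions; and no viscoelastic model —
dissipation is an energy bookkeeping quantity, not a fitted viscosity.
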
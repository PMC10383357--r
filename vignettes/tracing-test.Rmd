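---
title: "How solwrite digitises and grades the pen-writing sub-test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How solwrite digitises and grades the pen-writing sub-test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solwrite)
```

## The task and its virtual form

The Sollerman writing sub-test asks a patient to hold a pen in a tripod
pinch and write; the examiner grades the attempt 0–4 from completion and
time. `solwrite` replaces pen and paper with a camera view: the figure to
"write" is an image of straight strokes, the pen is the patient's own index
fingertip, and the pen's contact tolerance is an on-screen disc (the
*drawing point*) of radius 20–40 px centred on that fingertip. Everything
the package computes flows from three ingredients: a detected **shape**, a
stream of **landmark frames**, and the **grading rules**.

All coordinates are image-style: origin at the top-left, y increasing
downward, so "bottom" always means larger y. Carrier-line orientation is
represented as an angle in $[0, \pi)$ rather than a slope — a slope is
undefined for vertical strokes, whereas the angle treats them uniformly,
and a slope-difference test becomes the circular distance
$\min(\Delta, \pi - \Delta)$.

## Shape detection

Input images must be black strokes on a white background, straight lines
only. Preprocessing resizes to the 512×512 working resolution, rejects
coloured or gray-level content (more than 5 % of pixels at intermediate
intensity before thresholding), and binarises with Otsu's threshold — a
parameter-free choice that is exact for near-binary inputs.

Edges come from a classic Canny detector: 3×3 Sobel gradients, L1
magnitude, non-maximum suppression quantised to four directions, and
hysteresis with thresholds 50/150 on the 0–255 scale. For a binary image
these thresholds are far from both the noise floor (0) and the stroke
contrast (full scale), so detection is insensitive to their exact values;
they are exposed in `detection_params()` regardless.

Straight segments are extracted with a progressive probabilistic Hough
transform: edge pixels are visited in a seeded random order and vote over
180 one-degree orientation bins; when a pixel's best accumulator cell
reaches 30 votes, the supporting pixels are gathered in a ±2 px band around
the candidate line, the band is refined once by a total-least-squares fit
(which removes the quantisation drift a 1° bin would otherwise cause over a
300 px stroke), runs are split at gaps above 10 px, and the run containing
the triggering pixel becomes a segment if at least 30 px long. Extracted
pixels are removed and their votes retracted. Randomness is confined to the
visiting order and controlled by an explicit seed (default 0), so a fixed
seed yields a bit-identical shape.

Because Canny traces stroke *boundaries*, each drawn stroke typically
yields two raw parallel segments a stroke-width apart — over-detection is
expected, not a defect. Deduplication merges any pair whose midpoints are
within 15 px and whose angles differ by less than 5°, replacing them with a
segment on their length-weighted mean carrier line spanning the extreme
projections of all four endpoints. Merging repeats to a fixpoint, so it is
idempotent and can only reduce the count. The 15 px distance tolerance sits
comfortably above the 4 px stroke width and below the smallest inter-stroke
spacing of the built-in figures; both tolerances are configurable.

Topology and endpoints follow junction analysis: segment endpoints within
12 px snap to shared vertices (cluster means). A shape is *closed* when
every vertex joins exactly two endpoints (a single cycle), *open*
otherwise; disconnected input is an error, as is an open shape without
exactly two free endpoints. An open trace starts at the bottom-leftmost
free endpoint and ends at the bottom-rightmost; a closed trace starts and
ends at its bottom-leftmost vertex, walked toward the neighbour with the
smaller x so the direction is deterministic. Segments are re-ordered along
this walk, which is also the order the perimeter sum and the simulator use.

## The session state machine

A session holds the shape (scaled once into the display frame — a uniform,
aspect-preserving map filling 90 % of the 720 px frame height), a
configuration, and the automaton state. Arming requires the tripod pinch
*and* the index tip within `end_vicinity` of the start dot; the pinch is
two strict inequalities, thumb–index and thumb–middle distance below the
threshold (default 60 px for a hand ~50 cm from a 720p camera; the value is
a calibration constant, configurable per setup).

While tracing, checks run strictly in order: inter-frame gap (> 0.25 s
means the tracker lost the hand — a single dropped detection at 60 fps is
tolerated, a run of them is not), the 60 s clock, the grip, then legality.
Legality uses the *clamped* point-to-segment distance, not the carrier-line
distance, so overshooting a stroke's end by more than the radius is out of
bounds even though the infinite line is still near. Each legal frame logs
the signed carrier-line deviation of the matched (nearest, lowest index on
ties) segment.

Drawn length accumulates the per-frame displacement *projected onto the
matched segment's direction*, capped at 3 radii per frame. Raw fingertip
path length would count tremor as progress and a dropped-frame teleport as
a long draw; the projection makes a noiseless trace measure exactly the
arc length while perpendicular wobble contributes nothing. Completion
requires both the length condition (≥ 90 % of the perimeter, the reading of
"closely matches") and the fingertip within `end_vicinity` of the end dot;
for closed shapes, where the end is the start, the length condition is what
prevents instant completion at the shared dot. `end_vicinity` defaults to
the drawing radius: the start/end dots have no prescribed on-screen size,
and the radius is the only length scale the test already owns.

Running past 60 s ends the session as *partial* rather than failed: the
grading table awards 1 point for a partially performed task within 60 s,
which only makes sense if the timeout is a graded outcome, matching the
original test's stopwatch convention. Failures (out of bounds, grip lost,
hand lost) are immediate and absorbing.

## Scoring and the spasticity estimate

Grading is exhaustive over outcome × time × fraction: failed → 0; partial →
1 if the traced fraction exceeds 1/3 (strict, "beyond one third") else 0;
completed → 4 below 20 s, 3 in [20, 40) s, 2 in [40, 60] s. The interval
closures implement "within 60 s but not less than 40 s" with each boundary
belonging to the slower grade, and completion time alone separates 2 from
3 — the qualitative "difficulty" wording of the paper grades is not
modelled.

The deviation log is signed, which poses a definitional choice: a symmetric
wobble has a signed mean near zero however severe it is. Both summaries are
therefore reported — `mean_abs` as the headline spasticity figure and
`mean_signed` as a drift (side-bias) measure — with
`mean_abs ≥ |mean_signed|` by construction. Under the simulator's
perpendicular Gaussian tremor of standard deviation σ, the deviations are
N(0, σ) and `mean_abs` estimates the folded-normal mean σ√(2/π), which is
what the recovery tests assert.

## What the simulator emulates — and what it does not

`simulate_trajectory()` produces what an ideal tracker would emit for a
compliant subject: the index tip moves along the ground-truth path at
constant speed with independent perpendicular Gaussian tremor per frame;
thumb and middle tips ride at fixed tripod offsets; the other 18 landmarks
are an anatomically plausible rigid template (only landmarks 4, 8, 12 and
the wrist influence the engine). Failure events script the three mishaps
the engine must catch. Perpendicular-only noise is deliberate: tangential
noise changes speed, not deviation, so this choice gives the spasticity
estimator a closed-form expected value to test against.

Real data differ in ways the simulator does not model: landmark jitter is
temporally correlated and anisotropic, hands rotate and scale as they move,
tracking error grows near occlusions, and real tremor is oscillatory rather
than white. Passing the simulation-based tests therefore validates the
geometry, the automaton and the estimator algebra — not clinical validity,
camera calibration, or tracker accuracy. The live-capture adapter is
likewise out of scope by design: the engine consumes the JSONL stream
format, and any tracker that writes it (including one applying the
mirror-view horizontal flip before writing) can drive the test; a recorded
stream replays to the identical report.

## Numerical choices and problem sizes

Degenerate segments (zero length) are errors everywhere rather than
silently producing NaN angles. Ties — nearest segment, junction walks,
bottom-left rules — all resolve deterministically (lowest index, smaller
x). The renderer draws strokes with butt caps (perpendicular foot inside
the stroke), so the rendered extent does not overshoot the analytic
endpoints and detected perimeters sit within 1 % of ground truth against a
2 % test tolerance. Seeds are plain integers; every stochastic component
(Hough order, tremor) restores the caller's RNG state.

The test suite exercises the folded-normal recovery at σ = 1…8 px with
≥ 2000 frames per level (40 s sessions at 60 fps), the geometry oracle on
10³ random point/segment pairs against 10⁵-point dense sampling at 10⁻² px,
and full-pipeline ground-truth recovery on all four built-in figures; these
sizes keep each property statistically sharp (the folded-normal standard
error at n = 2000 is ~1.5 % of the estimate) while the whole suite runs in
about two minutes.

## Known limitations

Only straight-line, single-trace figures are supported — curves, arcs and
multi-component drawings are rejected by construction, mirroring the
detection algorithm's stated scope. BMP input is not decoded (PNG and TIFF
are). The junction tolerance (12 px) bounds the shortest stroke the
topology stage can respect; figures with strokes shorter than ~30 px fall
below the Hough minimum length and will not be detected. Scores 2 and 3
use time only; assessing qualitative "difficulty" would need information a
fingertip trajectory does not carry.
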
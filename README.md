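# solwrite

Markerless, camera-based scoring of the Sollerman Hand Function Test's
"write with a pen" sub-test, for rehabilitation researchers and clinicians
who want the task administered and graded without a therapist handling a
stopwatch and paper.

The Sollerman battery scores twenty activities-of-daily-living grip tasks on
a 0–4 scale. In the writing sub-test the patient holds a tripod pinch (thumb,
index and middle fingertips brought together, as around a pen) and traces a
figure. `solwrite` digitises the whole loop:

1. **Shape detection.** A black-on-white image of a straight-line figure is
   brought to the 512×512 working resolution and binarised (Otsu), edges are
   found with Canny (hysteresis thresholds 50/150, Sobel aperture 3), and
   straight segments are extracted with a seeded probabilistic Hough
   transform. The Hough stage over-detects — typically one segment per
   stroke *boundary* — so nearly coincident segments (midpoint distance
   < 15 px, carrier-angle difference < 5°) are merged to their union extent
   until a fixpoint. The merged segments are classified as an **open**
   polyline or a **closed** polygon, and the trace's start/end points are
   assigned (bottom-leftmost free endpoint starts an open trace,
   bottom-rightmost ends it; a closed trace starts and ends at its
   bottom-leftmost vertex).
2. **Tracing engine.** A stream of timestamped 21-landmark hand frames
   (JSONL replay, the built-in simulator, or any external tracker writing
   the same format) drives a per-frame state machine. The session arms when
   the tripod pinch is held with the index fingertip (landmark 8) on the
   start dot; each subsequent frame checks the grip
   (`d(4,8) < τ` and `d(4,12) < τ`, default τ = 60 px), the clock (60 s
   limit), and legality — the drawing point must stay within the drawing
   radius *r* ∈ [20, 40] px of the shape. Leaving the band, opening the
   grip, or losing the hand fails the test immediately; reaching the end
   dot after drawing ≥ 90 % of the perimeter completes it.
3. **Scoring and spasticity.** Completed traces score 4 (< 20 s), 3
   (20–40 s) or 2 (40–60 s); a partial trace beyond 1/3 of the perimeter
   scores 1, anything else 0. Each legal frame logs the signed perpendicular
   deviation dᵢ of the drawing point from the matched segment's carrier
   line; spasticity is reported as mean|dᵢ| (wobble) alongside mean dᵢ
   (systematic drift). Results append to an RFC-4180 CSV.

A synthetic-fixtures module renders the built-in figures (letter M,
rectangle, Greek Π, triangle) with analytic ground truth and simulates
tracing trajectories with controllable speed, perpendicular Gaussian tremor
and scripted failures, so every part of the system is testable without a
camera.

## Worked example

```r
library(solwrite)

img <- render_shape_image("M")              # 512x512 fixture image
shp <- build_shape(img, seed = 0, name = "M")
shp
#> <swt_shape M> open, 4 segment(s), perimeter 1271.7 px
#>   start (80.5, 433.0)  end (432.5, 433.0)

target <- scale_shape(shp)                  # into the 1280x720 display frame
frames <- simulate_trajectory("M", duration = 18, tremor_sigma = 4,
                              seed = 42, radius = 30)
session <- run_session(target, frames, session_config(radius = 30))
glance(session)
#> # A tibble: 1 × 7
#>   phase     fail_reason elapsed drawn_length fraction_traced n_frames n_legal_frames
#>   COMPLETED none           17.7        1609.           0.999     1062           1061

report <- score_report(finalize(session), session_id = "demo")
report[c("score", "elapsed_s", "spasticity_mean_abs_px", "outcome")]
#>   score elapsed_s spasticity_mean_abs_px   outcome
#>       4  17.68333                3.20594 completed
```

The detected M consists of exactly its four drawn strokes; the simulated
subject finished in 17.7 s (score 4) and the 4 px injected tremor is
recovered as a 3.2 px mean absolute deviation — the folded-normal
expectation σ·√(2/π) ≈ 3.19 px. `write_results_csv(report, "results.csv")`
appends the row; `autoplot(session)` or
`write_overlay_png(target, "trace.png", session = session)` draw the shape
(green), start (red), end (blue) and the drawn path (pink).

A thin command-line wrapper over the same functions ships in
`inst/cli/solwrite.R`:

```sh
Rscript inst/cli/solwrite.R simulate --fixture M --out-prefix /tmp/m --duration 15
Rscript inst/cli/solwrite.R detect   --image /tmp/m.png --out /tmp/m.json --overlay /tmp/m_overlay.png
Rscript inst/cli/solwrite.R run      --shape /tmp/m.json --stream /tmp/m_stream.jsonl --results-csv /tmp/results.csv
```

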
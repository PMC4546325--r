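---
title: "Measuring single-cell reversals: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-cell reversals: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Rod-shaped bacteria such as *Myxococcus xanthus* move along their long axis
and periodically reverse: the leading and lagging poles exchange roles, under
the control of the Frz chemosensory pathway, and polarity markers such as
FrzS-YFP relocate from the old leading pole to the new one. The reversal
frequency of a strain — how often cells reverse per unit time — is the
phenotype of interest when dissecting this pathway, and it is measured by
tracking isolated cells in time-lapse movies (transmitted light for position,
a YFP channel for polarity) at a 15 s frame interval, with wild-type cells
moving at roughly 1.7 ± 0.8 µm/min.

Two artifacts complicate the measurement. First, type-IV-pilus-driven cells
show *stick-slip* motions: short back-and-forth displacements that look like
reversals in the centroid track but involve no polarity switch. Second,
stage drift and tracking errors corrupt trajectories. `myxotrack` implements
the full measurement chain with explicit, automated treatments of both:
stick-slips are rejected because they lack a coincident pole-fluorescence
switch, and manual trajectory verification is replaced by quantitative QC
and ground-truth validation.

## The pipeline, stage by stage

1. **Stabilization** (`stabilize_stack`). Every frame is registered to frame
   0 by translation, estimated by FFT cross-correlation with parabolic
   sub-pixel refinement. Stage drift is smooth in time, so the offset series
   is run through a 5-frame running median: a single frame where the
   correlation locks onto a coherently moving group of cells rather than the
   stationary background is repaired by its neighbors. Frames are shifted by
   the rounded offset (no resampling); sub-pixel estimates are reported.

2. **Segmentation** (`segment_frame`). A global threshold on the inverted
   transmitted channel (cells are dark on a bright background), then
   connected components. The default threshold is Otsu's method with two
   robustness refinements: while the foreground fraction is implausibly
   large (> 20 %) Otsu is re-run on the above-threshold tail, and the
   threshold is never allowed below the background bulk (median + 6× the
   84th-percentile half-spread). Plain Otsu assumes a balanced bimodal
   histogram and mis-splits a structured background when cells cover a small
   fraction of the field. Components below `min_area` (1 µm²) or touching
   the border are removed; centroids are intensity-weighted and sub-pixel;
   orientation and length come from the principal axis; poles are the
   extreme mask points along that axis, ordered lexicographically. A fixed
   threshold is available for strict reproducibility across re-analyses.

3. **Pole photometry** (`measure_pole_intensity`). Mean fluorescence in a
   3 px disc at each pole minus the median of a 5–7 px annulus, clamped at
   zero — invariant under uniform background shifts by construction.

4. **Tracking** (`link_frames`, `build_tracks`). Nearest-object linking:
   candidate pairs between consecutive frames are accepted greedily in
   ascending distance order while both endpoints are free; pairs beyond
   `max_disp` are rejected; exact-distance ties touching a common detection
   are discarded outright. The default gate is 4× the expected per-frame
   displacement (4 × 1.7 µm/min × 15 s ≈ 1.7 µm), so a reversing cell can
   never be gated out. Automated QC replaces manual verification: detections
   closer than the gate to another detection in the same frame terminate the
   affected tracks (crossing cells are cut, never swapped), and a missed
   detection ends a track — no gap closing. Tracks shorter than 10 min
   (inclusive) are dropped. Pole labels are made persistent by
   minimum-displacement matching frame to frame; the labeling cannot swap
   while a cell moves less than half a cell length per frame.

5. **Reversal calling** (`call_directional_changes`). At each vertex *t* the
   turn angle between (centroid(t−1) − centroid(t)) and
   (centroid(t+1) − centroid(t)) is computed by arc-cosine: 180° is straight
   motion, 0° a full retrace. A directional change is a vertex with angle
   *strictly* below 90° (the boundary case is not an event) and both
   adjacent steps at least `min_step`. Candidates within 2 frames of the
   first vertex of the previous retained event merge into it, so one
   physical event spanning two vertices (as every simulated stick-slip does)
   is counted once.

6. **Stick-slip discrimination** (`detect_fluor_switches`,
   `classify_events`). The two persistent-pole intensity series are smoothed
   by a 3-frame centered moving average; a switch is a sign change of their
   difference that persists at least 2 frames. Each directional change is
   matched to the nearest unconsumed switch within ±2 frames: matched →
   confirmed reversal; unmatched with fluorescence present → stick-slip,
   excluded from the counts; unmatched without a fluorescence channel →
   unconfirmed (pure-motion mode, for counting without the filter).

7. **Statistics** (`summarize_group`, `compare_groups`, `dose_response`,
   `speed_summary`). Per-cell frequency is the confirmed-event count over
   the track duration, reported in reversals per 10 min (the time scale of
   the duration filter; declared in every output header). Groups are
   summarized by the 10/25/50/75/90 percentiles with linear interpolation
   between order statistics (`quantile` type 7). Two groups are compared
   with a Wilcoxon rank-sum test when either has fewer than 40 cells and a
   Student (equal-variance) two-sample t-test otherwise; Welch is available
   behind a flag but the classic Student form is the default because that is
   the named convention in this assay family. The Wilcoxon p-value is exact
   (full rank-sum distribution) when both groups have ≤ 8 observations and
   no ties, else the normal approximation with tie and continuity
   correction. Dose-response tables sort groups by stimulant dose (e.g. the
   isoamyl-alcohol ladder 0, 0.03, 0.075, 0.15 % v/v) and report raw
   pairwise p-values between consecutive doses — no multiple-testing
   correction, and the output says so.

## The synthetic-data generator

No raw movies are published for this assay family, so the package carries a
generator (`simulate_trajectories`, `render_movie`) whose defaults *are* the
study conditions: 15 s frames, per-cell speeds from a normal(1.7, 0.8)
µm/min truncated at zero and constant per cell, reversal and stick-slip
rates of 0.1/min each, pole fluorescence exchanging within 1 frame of a
reversal. Where the acquisition leaves a choice, the defaults are declared,
not inferred: 0.1 µm/px pixels (typical of 40–100× objectives; the
examples here use 0.2 µm/px to keep fields compact), 5 × 0.7 µm cells,
stick-slip excursion 0.7 µm completed within two frames, iid 5° heading
jitter about each cell's axis.

Three generator design choices deserve explanation:

* **Event waiting times are dead-time-plus-exponential, not pure
  exponential.** Gaps between successive events of one cell are 60 s plus an
  exponential whose rate is chosen so the *mean* event rate equals the
  nominal rate exactly; the first waiting time is drawn from the equilibrium
  delay distribution of that renewal process, so the expected event count in
  any window is exactly rate × window. The dead time models the refractory
  period of the reversal switch and keeps successive events at least ~3
  frames apart — events closer than the sampling resolution are
  fundamentally unresolvable by any vertex-angle caller (they merge or
  cancel), so a generator without a dead time would make event-level
  validation ill-posed at 15 s sampling rather than more realistic.

* **Cells are laid out in parallel lanes by default.** Cell-cell collisions
  are out of scope (real analyses count isolated cells), and overlapping
  rendered cells would merge under any global threshold. One cell per lane
  at 3 µm spacing realizes the isolated-cell assumption geometrically; the
  heading jitter is iid about the lane axis rather than a random walk, so
  cells stay in their lanes. An `"isotropic"` layout (random positions and
  orientations) exists for tests that do not render long movies.

* **The transmitted channel carries a weak static background texture**
  (smooth random field, sd 0.05 intensity units, fixed in sample
  coordinates). Real phase-contrast fields are full of stationary features —
  debris, chamber texture — and drift registration *depends* on them; a
  featureless synthetic background would make stabilization lock onto the
  cells' own motion, which no real pipeline suffers. The texture drifts with
  the stage like everything else on the slide.

What the generator deliberately does not emulate: optics beyond Gaussian
pole spots (no PSF convolution), growth and division, cell-cell mechanical
interaction, photobleaching, and uneven illumination. Passing validation on
these movies therefore demonstrates the correctness of the *computation* —
linking, angle rule, switch correlation, statistics — not robustness to
every imaging pathology of real data; the robustness knobs (fixed
thresholds, gates, windows) are exposed for that purpose.

## Validation semantics

`validate_events` matches confirmed calls to true reversals of the same cell
within ±1 frame, one-to-one, greedily by frame distance. Precision is
computed over all confirmed calls against *all* true events. Recall is
reported twice: over all true reversals, and over *observable* ones — events
whose cell stays fully in view through a run that satisfies the 10-min
duration filter, with a 3-frame cushion around the event (the vertex needs
both neighbors; the switch detector needs its smoothing and persistence
windows). A run-and-reverse walk is unbounded, so for any finite field some
cells eventually wander out; events they produce off-screen or on
too-short track fragments are untrackable under the study's own rules, and
counting them against recall would measure field geometry, not the caller.
With zero calls, precision is reported as 1 and flagged.

## Numerical choices and degenerate inputs

* Pixels are 0-based, x = column, y = row; physical coordinates are
  pixel × pixel size. One stated convention prevents off-by-one drift
  between modules.
* Turn angles clamp the normalized dot product into [−1, 1] before
  arc-cosine; a zero-length step makes the angle undefined and the vertex is
  skipped (jitter guard).
* `min_step` defaults to 2 pixels. For noise-free or very clean movies it
  should be lowered or set to 0 — the gate exists to suppress jitter-induced
  pseudo-angles and otherwise silences genuinely slow cells (a cell slower
  than `min_step`/15 s simply cannot exhibit a valid vertex).
* Axis-degenerate (round) components are flagged; their poles fall back to
  centroid ± half length along x, and pole labels propagate positionally.
* Zero-variance frames stabilize to identity with a warning; constant
  images segment to an empty detection list with a warning; all-zero
  fluorescence yields no switches with a warning.
* Identical-sample or zero-variance group comparisons return p = 1 by
  convention, flagged.
* A fixed seed makes simulate → render → analyze bit-reproducible; outputs
  (CSV tables, JSON summaries, YAML config echo) are byte-identical across
  re-runs.

## Known limitations

* A 180° body rotation within one frame can silently swap pole labels; the
  pole-distance QC flags the geometry but cannot repair it.
* Events in the first or last ~3 frames of a track can lose their
  fluorescence confirmation to window truncation (the switch detector needs
  trailing frames); at 0.1/min over 30-min tracks this costs well under 1 %
  of events and such frames are excluded from the observable set during
  validation.
* The n < 40 test-selection rule is applied as quoted, including its known
  statistical awkwardness (the choice of test depends on sample size, not on
  distributional diagnostics).
* Problem sizes in the shipped tests and acceptance script (20–100 cells,
  10–30 min, ~0.2 µm/px fields) were chosen so the full suite completes in
  minutes on one CPU while keeping every estimate inside its sampling
  tolerance; all of them are plain function arguments and scale up without
  code changes.
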
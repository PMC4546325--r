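# myxotrack

Single-cell reversal analysis for time-lapse movies of gliding bacteria.

## The problem

*Myxococcus xanthus* and its relatives move along their long axis and
periodically reverse direction under control of the Frz chemosensory
pathway; polarity reporters such as FrzS-YFP jump from the old leading pole
to the new one at every genuine reversal. The phenotype used to dissect this
pathway is the **reversal frequency** of single cells tracked for at least
10 min at a 15 s frame interval (wild-type speed ≈ 1.7 ± 0.8 µm/min).
Measuring it is confounded by **stick-slip motions** — short
pilus-driven back-and-forth displacements that look like reversals in the
centroid track but involve no polarity switch — and by stage drift and
tracking errors.

`myxotrack` implements the full measurement chain for people who need these
numbers (microbial motility labs, and anyone benchmarking event-level
trackers):

* stage-drift **stabilization** by FFT cross-correlation to frame 0;
* **segmentation** of dark rods by robust global thresholding
  (sparse-foreground-safe Otsu), with sub-pixel centroids, principal-axis
  orientation, and pole positions;
* **nearest-object tracking** with an automated-QC replacement for manual
  trajectory verification (gates, conflict cuts, ≥ 10 min duration filter,
  persistent pole labels);
* **reversal calling** by the turn-angle rule — at vertex *t* the angle
  between (c(t−1) − c(t)) and (c(t+1) − c(t)) is computed by arc-cosine, and
  a directional change is a vertex with angle **strictly < 90°**;
* **stick-slip discrimination**: a change is a confirmed reversal only if
  the two pole-intensity traces of the reporter cross within ±2 frames;
* **statistics** as used in this assay family: per-cell frequencies in
  reversals per 10 min, 10/25/50/75/90-percentile box summaries, Wilcoxon
  rank-sum when either group has n < 40 cells and Student's t otherwise,
  and dose-response tables (e.g. an isoamyl-alcohol ladder
  0–0.15 % v/v);
* a ground-truthed **synthetic movie generator** (run-and-reverse kinetics,
  two rendered channels, stick-slips, drift, noise) plus **event-level
  validation** — precision/recall of confirmed reversals at ±1 frame — so
  every stage is testable without raw microscopy data.

## Worked example

The `analysis/` scripts run the whole chain on a simulated benchmark;
`Rscript analysis/01_simulate_movie.R` through `05_validate_against_truth.R`
reproduce the following. In short form:

```r
library(myxotrack)

cfg <- simulation_config(n_cells = 12, duration = 1200, pixel_size = 0.2,
                         field_size = c(448, 288), reversal_rate = 0.1,
                         stickslip_rate = 0.1, noise_sd = 0.02, rng_seed = 11)
truth <- simulate_trajectories(cfg)
stack <- render_movie(truth)
res   <- run_pipeline(stack, pipeline_config(pixel_size = 0.2, min_step = 0.1))
print(res)
validate_events(res$events, truth, res$tracks)
```

which prints

```
pipeline_result: 12 tracks; 41 directional changes ( 19 confirmed, 22 stick-slip, 0 unconfirmed )
validation (tolerance +/- 1 frame(s)):
  confirmed reversals: precision 1.000, recall 1.000 (19 called, 18/19 true observable; recall over all true: 1.000)
  stick-slips confirmed as reversals: 0; stick-slip recall 1.000
  tracking identity accuracy: 1.000
```

Read: of 41 directional changes found in the centroid tracks, only the 19
with a coincident pole-fluorescence switch are counted as reversals — every
one of them matches a true simulated reversal to within one frame — and all
22 simulated stick-slips are correctly discarded. The recovered population
speed for this sample is 1.96 ± 0.76 µm/min (n = 12), the per-cell reversal
frequency has median 0.75 (IQR 0.00–1.12) per 10 min, and the dose-response
driver (`analysis/04_group_statistics.R`) yields mean frequencies rising
0.23 → 0.61 → 1.26 → 1.98 per 10 min across the 0, 0.03, 0.075, 0.15 %
stimulant ladder, consecutive doses differing with p < 1e-7 under the
n-conditional test rule.

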
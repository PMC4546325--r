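#!/usr/bin/env Rscript
# Step 2: stabilize, segment and track.
#
# Reads the two-channel movie from step 1, registers every frame to frame 0,
# detects cells by thresholding the inverted transmitted channel, links
# detections by the nearest-object rule, drops tracks shorter than 10 min,
# and assigns persistent pole identities. Writes the track table and prints
# the population speed (compare: 1.7 +/- 0.8 um/min for wild type).

library(myxotrack)

stack <- read_stack("results/movie", pixel_size = 0.2, frame_interval = 15)
cfg <- pipeline_config(pixel_size = 0.2)

stab <- stabilize_stack(stack)
cat(sprintf("stabilization: max |offset| %.2f px over %d frames\n",
            max(abs(as.matrix(stab$offsets[, c("dx", "dy")]))),
            nrow(stab$offsets)))

detections <- detect_cells(stab$stack, min_area = cfg$min_area)
cat(sprintf("detections: %d across %d frames\n", nrow(detections),
            length(unique(detections$frame))))

tracks <- build_tracks(detections, cfg$frame_interval, cfg$max_disp)
tracks <- filter_tracks(tracks, cfg$min_duration)
tracks <- assign_pole_identity(tracks)
print(tracks)
cat(sprintf("QC: %d conflict detections dropped, %d tracks below 10 min\n",
            tracks$log$n_conflict_dropped,
            tracks$log$n_tracks_removed_short))

sp <- speed_summary(tracks)
cat(sprintf("population speed: %.2f +/- %.2f um/min (n = %d cells)\n",
            sp$mean_um_min, sp$sd_um_min, sp$n))

utils::write.csv(tracks$tracks, "results/tracks.csv", row.names = FALSE)
cat("wrote results/tracks.csv\n")
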
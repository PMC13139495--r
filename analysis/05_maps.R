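#!/usr/bin/env Rscript
# Social maps: joint two-fly featurization of the scripted scenarios,
# embedding, kernel density, watershed modes, and per-condition occupancy.
# Also the wavelet behavioural map of one scenario's pose dynamics.

suppressMessages(library(songrules))

dir.create("results/maps", recursive = TRUE, showWarnings = FALSE)

designs <- list(); conditions <- c()
for (scn in c("male_turns", "female_slows")) {
  pose <- read_pose_csv(file.path("scratch/data", paste0(scn, "_pose.csv")),
                        frame_rate = 30)
  f <- feature_matrix(compute_features(pose))
  designs[[scn]] <- social_lag_design(f, k_lags = 15)
}

map <- fit_social_map(designs, subsample = 0.1, seed = 1, grid_n = 128)
occ <- mode_occupancy(map, conditions = list(
  male_turns = map$trial == 1, female_slows = map$trial == 2))
write.csv(as.data.frame(occ$occupancy), "results/maps/mode_occupancy.csv",
          row.names = FALSE)
write.csv(data.frame(trial = map$trial, mode = map$mode_labels,
                     x = map$embedding[, 1], y = map$embedding[, 2]),
          "results/maps/frame_modes.csv", row.names = FALSE)
cat("social map:", map$segmentation$n_modes, "modes;",
    "per-scenario occupancy written\n")
print(round(occ$occupancy, 3))

pose <- read_pose_csv("scratch/data/female_slows_pose.csv", frame_rate = 30)
wb <- wavelet_behavior_map(pose, subsample = 0.2, seed = 1, grid_n = 96)
cat("wavelet map:", wb$map$segmentation$n_modes, "modes from",
    ncol(wb$features), "wavelet features\n")
write.csv(data.frame(mode = wb$map$mode_labels),
          "results/maps/wavelet_modes.csv", row.names = FALSE)
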
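#!/usr/bin/env Rscript
# Generate the synthetic study data: feedback-feature processes with song
# labels sampled from the ground-truth three-rule model, scripted pose
# scenarios, and the playback audio. Everything downstream reads from
# scratch/data/.

suppressMessages(library(songrules))

seed <- 1L
out <- "scratch/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config()
basis <- raised_cosine_basis(cfg$n_lags, cfg$n_basis)
gt <- default_ground_truth(cfg)

# Six trials of 10 synthetic minutes each (18,000 frames at 30 Hz), three
# per "condition"; both conditions share the generative rules, mirroring
# the sex-agnostic null scenario. Design statistics are frozen from the
# pooled features so that every trial lives on one scale.
n_trials <- 6L
T_len <- 18000L
feats <- lapply(seq_len(n_trials), function(i)
  simulate_features(cfg, T_len, seed = seed + i))
stats <- build_design(do.call(rbind, feats), basis)$stats

meta <- data.frame(trial = paste0("trial", seq_len(n_trials)),
                   condition = rep(c("female", "male"), each = n_trials / 2))
for (i in seq_len(n_trials)) {
  sim <- simulate_song(gt, feats[[i]], basis, seed = seed + 100 + i,
                       stats = stats)
  write.csv(as.data.frame(feats[[i]]),
            file.path(out, paste0(meta$trial[i], "_features.csv")),
            row.names = FALSE)
  write_annotation_csv(sim$y,
                       file.path(out, paste0(meta$trial[i], "_labels.csv")))
  write.csv(data.frame(frame = seq_len(T_len), state = sim$z),
            file.path(out, paste0(meta$trial[i], "_truth.csv")),
            row.names = FALSE)
}
write.csv(meta, file.path(out, "trials.csv"), row.names = FALSE)

# scripted scenarios for the kinematics analyses
for (scn in c("male_turns", "female_slows")) {
  sc <- simulate_pose_scenario(scn, duration = 12, seed = seed)
  write_pose_csv(sc$pose, file.path(out, paste0(scn, "_pose.csv")))
}

cat("wrote", n_trials, "trials of", T_len, "frames plus 2 scenarios to",
    out, "\n")
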
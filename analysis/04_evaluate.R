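#!/usr/bin/env Rscript
# Evaluate the fitted model: held-out normalized log-likelihood against the
# chance model, state decoding against the generative ground truth, rule
# labelling and usage, permutation feature importance, and the
# counterfactual position sweep.

suppressMessages(library(songrules))

dir.create("results/eval", recursive = TRUE, showWarnings = FALSE)
meta <- read.csv("scratch/data/trials.csv")
mod <- load_model("results/model/hmmglm.json")
log <- jsonlite::read_json("results/model/fit_log.json",
                           simplifyVector = TRUE)

feats <- lapply(meta$trial, function(id)
  as.matrix(read.csv(file.path("scratch/data", paste0(id, "_features.csv")))))
labels <- lapply(meta$trial, function(id)
  read_annotation_csv(file.path("scratch/data", paste0(id, "_labels.csv")),
                      duration = nrow(feats[[1]]) / 30))
trials <- lapply(seq_along(feats), function(i)
  list(X = build_design(feats[[i]], mod$basis, mod$stats)$X, y = labels[[i]]))
names(trials) <- meta$trial

heldout <- trials[log$heldout]
ev <- heldout_nll(mod$params, heldout)
cat(sprintf("held-out NLL: %.3f bits/sample over %d frames\n",
            ev$nll_bits, ev$n))
tms <- transition_mode_nll(mod$params, heldout, from_mode = 1, to_mode = 2)
cat(sprintf("pulse-to-sine transition NLL: %.3f bits (%d transitions)\n",
            tms$nll_bits, tms$n))

# decoding accuracy against the generative state sequence
acc <- sapply(meta$trial, function(id) {
  z <- read.csv(file.path("scratch/data", paste0(id, "_truth.csv")))$state
  path <- viterbi_decode(mod$params, trials[[id]]$X, trials[[id]]$y)
  prof_fit <- emission_profile(mod$params, trials[id])
  gt <- default_ground_truth(synthetic_config())
  perm <- align_states(prof_fit, emission_profile(gt, trials[id]))
  mean(match(path, perm) == z)
})
write.csv(data.frame(trial = meta$trial, decode_accuracy = acc),
          "results/eval/decoding.csv", row.names = FALSE)
cat("mean decoding accuracy:", round(mean(acc), 3), "\n")

rules <- label_rules(mod$params, trials)
write.csv(as.data.frame(rules$emission_profiles),
          "results/eval/rule_emissions.csv", row.names = FALSE)
write.csv(cbind(trial = meta$trial, as.data.frame(rules$usage)),
          "results/eval/rule_usage.csv", row.names = FALSE)
cat("rule mapping:", rules$mapping, "\n")

fi <- feature_importance(mod$params, feats[seq_len(2)], labels[seq_len(2)],
                         mod$basis, mod$stats, seed = 1)
write.csv(fi, "results/eval/feature_importance.csv", row.names = FALSE)
cat("most important features:",
    paste(head(fi$feature[order(-fi$reduction)], 3), collapse = ", "), "\n")

sw <- counterfactual_position_sweep(mod$params, feats[[1]], labels[[1]],
                                    mod$basis, mod$stats, "ctheta")
write.csv(data.frame(angle = sw$angles, t(sw$delta_pulse)),
          "results/eval/sweep_delta_pulse.csv", row.names = FALSE)
write.csv(data.frame(angle = sw$angles, t(sw$delta_sine)),
          "results/eval/sweep_delta_sine.csv", row.names = FALSE)
cat("counterfactual sweep written (", length(sw$angles), "angles )\n")
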
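#!/usr/bin/env Rscript
# Fit the three-rule HMM-GLM to the simulated trials (two held out) and
# save the model. The fit uses the same basis and frozen design statistics
# convention as the evaluation stages.

suppressMessages(library(songrules))

seed <- 1L
dir.create("results/model", recursive = TRUE, showWarnings = FALSE)

meta <- read.csv("scratch/data/trials.csv")
cfg <- synthetic_config()
basis <- raised_cosine_basis(cfg$n_lags, cfg$n_basis)

feats <- lapply(meta$trial, function(id)
  as.matrix(read.csv(file.path("scratch/data", paste0(id, "_features.csv")))))
labels <- lapply(meta$trial, function(id)
  read_annotation_csv(file.path("scratch/data", paste0(id, "_labels.csv")),
                      duration = nrow(feats[[1]]) / 30))

# last trial of each condition is held out
heldout_ids <- c(3L, 6L)
train_ids <- setdiff(seq_len(nrow(meta)), heldout_ids)

stats <- build_design(do.call(rbind, feats[train_ids]), basis)$stats
trials <- lapply(seq_along(feats), function(i)
  list(X = build_design(feats[[i]], basis, stats)$X, y = labels[[i]]))

fit <- fit_em(trials[train_ids], K = 3, n_restarts = 3, seed = seed,
              max_iter = 60)
save_model(fit, basis, stats, "results/model/hmmglm.json", seed = seed)

cat("fitted 3-state model on", length(train_ids), "trials;",
    "final penalized objective", round(fit$objective, 1), "over",
    fit$n_iter, "EM iterations\n")
cat("restart objectives:", round(fit$restart_objectives, 1), "\n")
writeLines(
  jsonlite::toJSON(list(heldout = meta$trial[heldout_ids],
                        train = meta$trial[train_ids],
                        trace = fit$trace), auto_unbox = TRUE, digits = NA),
  "results/model/fit_log.json")
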
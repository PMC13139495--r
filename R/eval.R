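#' Chance (emission-frequency) model
#'
#' Predicts each song mode with its empirical frequency over the evaluation
#' frames, ignoring all feedback cues. It is the zero point of the
#' normalized log-likelihood scale.
#'
#' @param y_list list of integer label vectors (one per trial).
#' @param M number of modes.
#' @return list with `probs` (length `M`) and `loglik` of the evaluation
#'   frames under the model.
#' @export
chance_model <- function(y_list, M = 3L) {
  y <- unlist(y_list)
  if (length(y) == 0) stop("no evaluation frames")
  counts <- tabulate(as.integer(y), M)
  probs <- counts / sum(counts)
  lp <- ifelse(counts > 0, log(probs), 0)
  list(probs = probs, loglik = sum(counts * lp), n = length(y))
}

#' Held-out normalized log-likelihood in bits per sample
#'
#' `NLL = (LL(model) - LL(chance)) / (n * log 2)`, where the chance model's
#' mode frequencies are counted on the same held-out frames. Positive values
#' mean the model predicts the song modes better than their base rates.
#'
#' @param params fitted `hmmglm_params`.
#' @param trials held-out trials (list of `X`, `y`).
#' @return list with `nll_bits`, `loglik`, `loglik_chance`, `n`, and the
#'   per-trial log-likelihoods.
#' @export
heldout_nll <- function(params, trials) {
  if (length(trials) == 0) stop("empty held-out set")
  per_trial <- vapply(trials, function(tr)
    forward_backward(params, tr$X, tr$y)$loglik, 0)
  ch <- chance_model(lapply(trials, `[[`, "y"), params$M)
  ll <- sum(per_trial)
  list(nll_bits = (ll - ch$loglik) / (ch$n * log(2)),
       loglik = ll, loglik_chance = ch$loglik, n = ch$n,
       per_trial_loglik = per_trial)
}

#' Normalized log-likelihood restricted to song-mode transition time points
#'
#' Evaluates the model's one-step predictive log-probability only at time
#' points where the observed label switches `from_mode -> to_mode`, against
#' the chance model counted on the full evaluation frames.
#'
#' @param params fitted model.
#' @param trials evaluation trials.
#' @param from_mode,to_mode integer mode codes (1 pulse, 2 sine, 3 silence).
#' @return list with `nll_bits`, `n` (number of transition points), `empty`.
#' @export
transition_mode_nll <- function(params, trials, from_mode, to_mode) {
  ch <- chance_model(lapply(trials, `[[`, "y"), params$M)
  ll <- 0; ll0 <- 0; n <- 0L
  for (tr in trials) {
    y <- as.integer(tr$y)
    idx <- which(y[-1] == to_mode & y[-length(y)] == from_mode) + 1L
    if (length(idx) == 0) next
    fb <- forward_backward(params, tr$X, tr$y)
    ll <- ll + sum(fb$step_loglik[idx])
    ll0 <- ll0 + sum(log(ch$probs[y[idx]]))
    n <- n + length(idx)
  }
  if (n == 0L) return(list(empty = TRUE, n = 0L, nll_bits = NA_real_))
  list(empty = FALSE, n = n, nll_bits = (ll - ll0) / (n * log(2)),
       loglik = ll, loglik_chance = ll0)
}

#' Permutation feature importance
#'
#' Shuffles one raw feature time series across time (within each trial,
#' before lag expansion), rebuilds the design with the frozen training
#' statistics, and reports the log-likelihood reduction relative to the
#' intact data. Larger reductions mean the model relies more on the feature.
#'
#' @param params fitted model.
#' @param feature_list list of per-trial raw feature matrices (T x 10).
#' @param y_list list of per-trial label vectors.
#' @param basis the `rc_basis` used at training.
#' @param stats frozen z-score statistics from the training design.
#' @param seed permutation seed.
#' @return data.frame with `feature`, `loglik_shuffled`, `reduction`.
#' @export
feature_importance <- function(params, feature_list, y_list, basis, stats,
                               seed = 1) {
  nf <- ncol(feature_list[[1]])
  fnames <- colnames(feature_list[[1]])
  if (is.null(fnames)) fnames <- paste0("f", seq_len(nf))
  ll_orig <- sum(mapply(function(f, y) {
    forward_backward(params, build_design(f, basis, stats)$X, y)$loglik
  }, feature_list, y_list))

  set.seed(seed)
  res <- lapply(seq_len(nf), function(f) {
    ll <- sum(mapply(function(feat, y) {
      shuf <- feat
      shuf[, f] <- shuf[sample.int(nrow(shuf)), f]
      forward_backward(params, build_design(shuf, basis, stats)$X, y)$loglik
    }, feature_list, y_list))
    data.frame(feature = fnames[f], loglik_shuffled = ll,
               reduction = ll_orig - ll)
  })
  out <- do.call(rbind, res)
  attr(out, "loglik_original") <- ll_orig
  out
}

#' Fit and cross-evaluate condition-specific and pooled models
#'
#' Fits a model per condition (e.g. female-directed, male-directed) and a
#' pooled model on all training trials, then evaluates every model on every
#' condition's held-out trials, mirroring the sex-specific vs sex-agnostic
#' comparison.
#'
#' @param conditions named list; each element a list with `train` and
#'   `heldout` trial lists.
#' @param ... passed to [fit_em()].
#' @return list with `models` (per condition plus `"pooled"`) and
#'   `nll_bits`, a models x conditions matrix of held-out normalized
#'   log-likelihoods.
#' @export
cross_condition_eval <- function(conditions, ...) {
  stopifnot(length(conditions) >= 2, !is.null(names(conditions)))
  for (nm in names(conditions))
    if (length(conditions[[nm]]$heldout) == 0)
      stop(sprintf("condition '%s' has no held-out trials", nm))

  models <- lapply(conditions, function(co) fit_em(co$train, ...))
  models$pooled <- fit_em(do.call(c, lapply(conditions, `[[`, "train")), ...)

  nll <- matrix(NA_real_, length(models), length(conditions),
                dimnames = list(names(models), names(conditions)))
  for (m in names(models)) for (co in names(conditions))
    nll[m, co] <- heldout_nll(models[[m]]$params, conditions[[co]]$heldout)$nll_bits
  list(models = models, nll_bits = nll)
}

#' Map hidden states to sensorimotor rules
#'
#' Computes each state's posterior-weighted mean emission probabilities and
#' names the states: the state with the highest silence share is the
#' `whatever` rule; of the remaining two, the pulse-dominant one is
#' `chasing` and the sine-dominant one is `close`. Errors if the profiles do
#' not admit this strict ordering rather than guessing.
#'
#' @param params fitted 3-state model.
#' @param trials trials used to estimate the emission profiles and usage.
#' @return list with `mapping` (state -> rule), `emission_profiles`
#'   (K x M), and `usage` (trials x K posterior rule-usage fractions,
#'   rows summing to 1).
#' @export
label_rules <- function(params, trials) {
  if (params$K != 3) stop("rule mapping requires a 3-state model")
  prof <- matrix(0, params$K, params$M)
  wsum <- numeric(params$K)
  usage <- matrix(0, length(trials), params$K)
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    fb <- forward_backward(params, tr$X, tr$y)
    for (k in seq_len(params$K)) {
      Pk <- emission_probs(params$W[[k]], tr$X)
      prof[k, ] <- prof[k, ] + colSums(fb$gamma[, k] * Pk)
      wsum[k] <- wsum[k] + sum(fb$gamma[, k])
    }
    usage[i, ] <- colMeans(fb$gamma)
  }
  prof <- prof / wsum
  colnames(prof) <- params$modes

  whatever <- which.max(prof[, 3])
  rest <- setdiff(1:3, whatever)
  pulse_dom <- rest[which.max(prof[rest, 1])]
  sine_dom <- setdiff(rest, pulse_dom)
  ok <- prof[whatever, 3] > max(prof[rest, 3]) &&
    prof[pulse_dom, 1] > prof[sine_dom, 1] &&
    prof[sine_dom, 2] > prof[pulse_dom, 2] &&
    prof[pulse_dom, 1] > prof[pulse_dom, 2] &&   # chasing itself pulse-biased
    prof[sine_dom, 2] > prof[sine_dom, 1]        # close itself sine-biased
  if (!ok) {
    stop(paste("ambiguous emission profiles; no strict whatever/chasing/close",
               "ordering:\n", paste(utils::capture.output(print(round(prof, 3))),
                                    collapse = "\n")))
  }
  mapping <- character(3)
  mapping[whatever] <- "whatever"
  mapping[pulse_dom] <- "chasing"
  mapping[sine_dom] <- "close"
  colnames(usage) <- mapping
  list(mapping = mapping, emission_profiles = prof, usage = usage)
}

#' Posterior-weighted mean emission probabilities per state
#'
#' @param params `hmmglm_params`.
#' @param trials trials with designs and labels.
#' @return K x M matrix of mean per-state song-mode probabilities.
#' @export
emission_profile <- function(params, trials) {
  prof <- matrix(0, params$K, params$M)
  wsum <- numeric(params$K)
  for (tr in trials) {
    fb <- forward_backward(params, tr$X, tr$y, compute_xi = FALSE)
    for (k in seq_len(params$K)) {
      Pk <- emission_probs(params$W[[k]], tr$X)
      prof[k, ] <- prof[k, ] + colSums(fb$gamma[, k] * Pk)
      wsum[k] <- wsum[k] + sum(fb$gamma[, k])
    }
  }
  prof <- prof / wsum
  colnames(prof) <- params$modes
  prof
}

#' Align fitted states to reference states
#'
#' Exhaustive search over the K! state permutations for the one minimizing
#' the summed absolute difference between emission profiles; used when
#' comparing a fitted model against a generative ground truth.
#'
#' @param profile_fit,profile_ref K x M emission-profile matrices.
#' @return integer permutation `p` such that fitted state `p[i]` matches
#'   reference state `i`.
#' @export
align_states <- function(profile_fit, profile_ref) {
  K <- nrow(profile_ref)
  perms <- permutations_of(K)
  cost <- vapply(seq_len(nrow(perms)), function(i)
    sum(abs(profile_fit[perms[i, ], , drop = FALSE] - profile_ref)), 0)
  perms[which.min(cost), ]
}

permutations_of <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(K - 1)
  do.call(rbind, lapply(seq_len(K), function(i) {
    cbind(i, matrix(setdiff(seq_len(K), i)[sub], nrow(sub)))
  }))
}

#' Counterfactual sweep of courter angular position
#'
#' For every original sample, builds simulated copies in which the chosen
#' relative angle (`ctheta` or `ptheta`) is set to each value of a 0..180
#' degree grid (1 degree steps, inclusive) across the entire cue history,
#' with the relative orientation coupled as `phi = 180 - angle`; all other
#' features stay at their observed values. Reports the change in the
#' posterior-weighted predicted pulse and sine probabilities, aggregated
#' over the original value of the swept angle.
#'
#' @param params fitted model.
#' @param features raw feature matrix (T x 10) with named columns including
#'   the swept angle and `phi`.
#' @param y integer labels for the trial.
#' @param basis,stats design-building inputs (training statistics frozen).
#' @param sweep_feature `"ctheta"` or `"ptheta"`.
#' @param bin_width aggregation bin width for the original angle, degrees.
#' @return list with `angles` (sweep grid), `delta_pulse` and `delta_sine`
#'   (original-angle bins x sweep angles, mean differences), `bin_mid`.
#' @export
counterfactual_position_sweep <- function(params, features, y, basis, stats,
                                          sweep_feature = c("ctheta", "ptheta"),
                                          bin_width = 15) {
  sweep_feature <- match.arg(sweep_feature)
  fnames <- colnames(features)
  if (is.null(fnames) || !all(c(sweep_feature, "phi") %in% fnames))
    stop("features must have named columns including the swept angle and phi")
  angles <- 0:180
  D <- basis$n_basis
  csum <- colSums(basis$B)   # projection of a constant-1 history

  d <- build_design(features, basis, stats)
  fb <- forward_backward(params, d$X, y)
  nT <- nrow(d$X)

  sw_idx <- which(fnames == sweep_feature)
  ph_idx <- which(fnames == "phi")
  sw_cols <- which(d$col_feature == sw_idx)
  ph_cols <- which(d$col_feature == ph_idx)

  # Linear predictors split into a fixed part (all other columns) and the
  # swept-column contribution, which depends only on the swept angle.
  base_eta <- lapply(params$W, function(Wk) {
    Xf <- d$X
    Xf[, c(sw_cols, ph_cols)] <- 0
    Xf %*% t(Wk)
  })
  sweep_eta <- lapply(params$W, function(Wk) {
    vapply(angles, function(a) {
      xs <- (a * csum - stats$mean[sw_cols]) / stats$sd[sw_cols]
      xp <- ((180 - a) * csum - stats$mean[ph_cols]) / stats$sd[ph_cols]
      drop(Wk[, sw_cols, drop = FALSE] %*% xs +
             Wk[, ph_cols, drop = FALSE] %*% xp)
    }, numeric(params$M))  # M x length(angles)
  })

  softmax_rows <- function(eta) {
    eta <- eta - row_max(eta)
    p <- exp(eta); p / rowSums(p)
  }
  p_orig <- matrix(0, nT, params$M)
  for (k in seq_len(params$K))
    p_orig <- p_orig + fb$gamma[, k] * emission_probs(params$W[[k]], d$X)

  # rows whose 4 s history is incomplete (mean-imputed) have no well-defined
  # counterfactual history and are excluded from the aggregation
  use_rows <- seq.int(min(basis$n_lags, nT), nT)
  orig_angle <- features[use_rows, sw_idx]
  bins <- pmin(floor(orig_angle / bin_width), floor(180 / bin_width) - 1) + 1
  n_bins <- floor(180 / bin_width)
  dp <- matrix(0, n_bins, length(angles))
  ds <- matrix(0, n_bins, length(angles))
  cnt <- tabulate(bins, n_bins)

  for (ai in seq_along(angles)) {
    p_sim <- matrix(0, nT, params$M)
    for (k in seq_len(params$K)) {
      eta <- sweep(base_eta[[k]], 2, sweep_eta[[k]][, ai], "+")
      p_sim <- p_sim + fb$gamma[, k] * softmax_rows(eta)
    }
    diff_p <- (p_sim[, 1] - p_orig[, 1])[use_rows]
    diff_s <- (p_sim[, 2] - p_orig[, 2])[use_rows]
    dp[, ai] <- vapply(seq_len(n_bins), function(b)
      if (cnt[b] > 0) mean(diff_p[bins == b]) else NA_real_, 0)
    ds[, ai] <- vapply(seq_len(n_bins), function(b)
      if (cnt[b] > 0) mean(diff_s[bins == b]) else NA_real_, 0)
  }
  list(angles = angles, delta_pulse = dp, delta_sine = ds,
       bin_mid = (seq_len(n_bins) - 0.5) * bin_width, bin_counts = cnt)
}

#' Two-dimensional embedding of filtered feedback cues (decision space)
#'
#' For each time point, takes the elementwise product of the design vector
#' with the filter of the inferred state and the observed song mode, and
#' embeds these filtered-cue vectors in 2-D with the same manifold method as
#' the behavioural maps.
#'
#' @param params fitted model.
#' @param trials trials with designs and labels.
#' @param seed embedding seed.
#' @param n_neighbors UMAP neighbourhood size.
#' @return list with `embedding` (n x 2), `state`, `mode` per point, and
#'   `filtered` (the pre-embedding matrix).
#' @export
decision_space_embedding <- function(params, trials, seed = 1,
                                     n_neighbors = 15) {
  pieces <- lapply(trials, function(tr) {
    z <- viterbi_decode(params, tr$X, tr$y)
    V <- matrix(0, nrow(tr$X), params$P)
    for (t in seq_len(nrow(tr$X)))
      V[t, ] <- params$W[[z[t]]][tr$y[t], ] * tr$X[t, ]
    list(V = V, z = z, y = tr$y)
  })
  V <- do.call(rbind, lapply(pieces, `[[`, "V"))
  emb <- embed_umap(V, seed = seed, n_neighbors = n_neighbors)
  list(embedding = emb$embedding, state = unlist(lapply(pieces, `[[`, "z")),
       mode = unlist(lapply(pieces, `[[`, "y")), filtered = V)
}

#' Infer hidden rules on unseen trials with frozen parameters
#'
#' Builds the design with the training z-score statistics, then returns the
#' posterior state marginals and Viterbi path under the fitted model.
#'
#' @param params fitted model.
#' @param features raw feature matrix for the new trial (columns must match
#'   the training features).
#' @param y integer song labels for the new trial.
#' @param basis,stats training basis and frozen z-score statistics.
#' @return list with `gamma`, `path`, `loglik`.
#' @export
infer_states_external <- function(params, features, y, basis, stats) {
  if (ncol(features) * basis$n_basis + 1 != params$P)
    stop("feature set does not match the fitted model's design dimensions")
  d <- build_design(features, basis, stats)
  fb <- forward_backward(params, d$X, y)
  list(gamma = fb$gamma, path = viterbi_decode(params, d$X, y),
       loglik = fb$loglik)
}
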
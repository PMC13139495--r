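test_that("the chance model scores exactly zero normalized bits against itself", {
  y <- list(c(1L, 1L, 2L, 3L, 3L, 3L))
  ch <- chance_model(y)
  expect_equal((ch$loglik - ch$loglik) / (ch$n * log(2)), 0)
  expect_equal(sum(ch$probs), 1)
  # a perfect predictor's normalized score equals the label entropy in bits
  counts <- tabulate(unlist(y), 3)
  p <- counts / sum(counts)
  entropy_bits <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal((0 - ch$loglik) / (ch$n * log(2)), entropy_bits)
})

test_that("held-out NLL matches hand-expanded arithmetic on a 4-sample case", {
  # single state, known filters, bias-only design
  W <- rbind(c(0, 1), c(0, -1), 0)
  p <- hmmglm_params(1, matrix(1, 1, 1), list(W))
  X <- cbind(rep(0, 4), 1)
  y <- c(1L, 1L, 2L, 3L)
  Z <- exp(1) + exp(-1) + 1
  ll_hand <- 2 * (1 - log(Z)) + (-1 - log(Z)) + (0 - log(Z))
  ll0_hand <- 2 * log(2 / 4) + log(1 / 4) + log(1 / 4)
  ev <- heldout_nll(p, list(list(X = X, y = y)))
  expect_equal(ev$loglik, ll_hand, tolerance = 1e-12)
  expect_equal(ev$loglik_chance, ll0_hand, tolerance = 1e-12)
  expect_equal(ev$nll_bits, (ll_hand - ll0_hand) / (4 * log(2)),
               tolerance = 1e-12)
  expect_error(heldout_nll(p, list()), "empty")
})

test_that("transition-restricted NLL selects exactly the switching time points", {
  p <- toy_sticky_params()
  set.seed(4)
  X <- cbind(rep(0, 60), 1)
  y <- rep(c(1L, 2L, 3L), each = 20)
  tr <- list(list(X = X, y = y))
  r <- transition_mode_nll(p, tr, from_mode = 1, to_mode = 2)
  expect_false(r$empty)
  expect_equal(r$n, 1L)    # the single pulse-to-sine switch at frame 21
  r2 <- transition_mode_nll(p, tr, from_mode = 2, to_mode = 1)
  expect_true(r2$empty)

  # summing the restricted log-likelihoods over all from/to pairs plus the
  # first frame reproduces the full held-out log-likelihood
  fb <- forward_backward(p, X, y)
  ll_pairs <- 0
  for (a in 1:3) for (b in 1:3) {
    rr <- transition_mode_nll(p, tr, a, b)
    if (!rr$empty) ll_pairs <- ll_pairs + rr$loglik
  }
  expect_equal(ll_pairs + fb$step_loglik[1], fb$loglik, tolerance = 1e-10)
})

test_that("feature importance is zero for ignored features, large for generative ones, and deterministic", {
  basis <- raised_cosine_basis(20, 3)
  P <- 2 * 3 + 1
  # state-free single-GLM model driven only by feature 1
  W <- rbind(c(2, 0, 0, rep(0, 3), 0), rep(0, P), 0)
  gt <- hmmglm_params(1, matrix(1, 1, 1), list(W))
  set.seed(9)
  f <- matrix(rnorm(1500 * 2), 1500)
  colnames(f) <- c("drv", "idle")
  sim <- simulate_song(gt, f, basis, seed = 10)
  fi1 <- feature_importance(gt, list(f), list(sim$y), basis, sim$stats,
                            seed = 3)
  fi2 <- feature_importance(gt, list(f), list(sim$y), basis, sim$stats,
                            seed = 3)
  expect_identical(fi1, fi2)
  expect_lt(abs(fi1$reduction[fi1$feature == "idle"]), 1e-8)
  expect_gt(fi1$reduction[fi1$feature == "drv"], 10)
  expect_equal(which.max(fi1$reduction), which(fi1$feature == "drv"))
})

test_that("rule labelling orders states by silence, pulse, and sine dominance", {
  P <- 2
  mk <- function(pulse_bias, sine_bias)
    rbind(c(0, pulse_bias), c(0, sine_bias), 0)
  alpha <- matrix(0.05, 3, 3); diag(alpha) <- 0.9
  p <- hmmglm_params(rep(1 / 3, 3), alpha,
                     list(mk(-3, -3), mk(2, -1), mk(-1, 2)))
  set.seed(5)
  X <- cbind(rep(0, 300), 1)
  sim_y <- sample.int(3, 300, replace = TRUE)
  rules <- label_rules(p, list(list(X = X, y = sim_y)))
  expect_equal(rules$mapping, c("whatever", "chasing", "close"))
  expect_equal(unname(rowSums(rules$usage)), rep(1, 1), tolerance = 1e-12)

  p2 <- toy_sticky_params()
  expect_error(label_rules(p2, list(list(X = X, y = sim_y))), "3-state")
  # two pulse-dominant states cannot be ordered into chasing/close
  p3 <- hmmglm_params(rep(1 / 3, 3), alpha,
                      list(mk(-3, -3), mk(2, -1), mk(2.5, -1)))
  expect_error(label_rules(p3, list(list(X = X, y = sim_y))), "ambiguous")
})

test_that("counterfactual sweep is flat for angle-blind models and matches a loop oracle", {
  basis <- raised_cosine_basis(15, 3)
  nf <- 10
  P <- nf * 3 + 1
  fn <- c("cFV", "pFV", "cLS", "pLS", "cRS", "pRS", "dis", "ctheta",
          "ptheta", "phi")
  set.seed(21)
  f <- matrix(abs(rnorm(200 * nf)) * 20, 200, dimnames = list(NULL, fn))

  # model blind to ctheta and phi -> zero delta everywhere
  Wb <- rbind(c(rep(0, P - 1), 0.5), c(rep(0, P - 1), -0.5), 0)
  Wb[1, 1:3] <- 0.3  # cFV drive only
  blind <- hmmglm_params(1, matrix(1, 1, 1), list(Wb))
  d <- build_design(f, basis)
  sw <- counterfactual_position_sweep(blind, f, rep(3L, 200), basis, d$stats,
                                      "ctheta", bin_width = 180)
  expect_lt(max(abs(sw$delta_pulse), na.rm = TRUE), 1e-12)
  expect_lt(max(abs(sw$delta_sine), na.rm = TRUE), 1e-12)

  # angle-sensitive model: compare against per-angle design rebuilding
  Wa <- Wb
  Wa[1, (7 * 3 + 1):(8 * 3)] <- c(0.05, 0.02, 0.01)   # ctheta block
  Wa[2, (9 * 3 + 1):(10 * 3)] <- c(-0.03, 0.01, 0)    # phi block
  angl <- hmmglm_params(1, matrix(1, 1, 1), list(Wa))
  y <- rep(3L, 200)
  sw <- counterfactual_position_sweep(angl, f, y, basis, d$stats,
                                      "ctheta", bin_width = 180)
  p_orig <- emission_probs(angl$W[[1]], d$X)
  full <- 15:200   # rows with complete lag history
  for (a in c(0, 90, 180)) {
    f2 <- f
    f2[, "ctheta"] <- a
    f2[, "phi"] <- 180 - a
    d2 <- build_design(f2, basis, d$stats)
    p_sim <- emission_probs(angl$W[[1]], d2$X)
    expect_equal(sw$delta_pulse[1, sw$angles == a],
                 mean((p_sim[, 1] - p_orig[, 1])[full]), tolerance = 1e-8)
    expect_true(all(abs(rowSums(p_sim) - 1) < 1e-12))
  }
})

test_that("external state inference reproduces fit-time posteriors and flags mismatches", {
  basis <- raised_cosine_basis(20, 3)
  cfgish <- list()
  set.seed(31)
  f <- matrix(rnorm(800 * 2), 800, dimnames = list(NULL, c("a", "b")))
  P <- 2 * 3 + 1
  W <- list(rbind(c(rep(0, P - 1), -2), c(rep(0, P - 1), -2), 0),
            rbind(c(1.5, 0, 0, rep(0, 3), 1.5), c(rep(0, P - 1), -1), 0))
  alpha <- matrix(c(0.98, 0.02, 0.02, 0.98), 2)
  gt <- hmmglm_params(c(0.5, 0.5), alpha, W)
  sim <- simulate_song(gt, f, basis, seed = 32)
  inf <- infer_states_external(gt, f, sim$y, basis, sim$stats)
  fb <- forward_backward(gt, sim$X, sim$y)
  expect_equal(inf$gamma, fb$gamma, tolerance = 1e-12)
  expect_gt(mean(inf$path == sim$z), 0.9)
  expect_error(infer_states_external(gt, f[, 1, drop = FALSE], sim$y, basis,
                                     sim$stats), "does not match")
})

test_that("cross-condition fitting evaluates every model on every condition", {
  basis <- raised_cosine_basis(15, 2)
  P <- 1 * 2 + 1
  mkgt <- function(bias) {
    W <- list(rbind(c(0, 0, bias), c(0, 0, -bias), 0))
    hmmglm_params(1, matrix(1, 1, 1), W)
  }
  mk_trials <- function(gt, n, seed) {
    lapply(seq_len(n), function(i) {
      set.seed(seed + i)
      f <- matrix(rnorm(400), 400, 1)
      sim <- simulate_song(gt, f, basis, seed = seed + 50 + i)
      list(X = sim$X, y = sim$y)
    })
  }
  gt_f <- mkgt(2); gt_m <- mkgt(-2)    # pulse-heavy vs sine-heavy conditions
  conds <- list(
    female = list(train = mk_trials(gt_f, 2, 1), heldout = mk_trials(gt_f, 1, 10)),
    male = list(train = mk_trials(gt_m, 2, 20), heldout = mk_trials(gt_m, 1, 30)))
  cc <- cross_condition_eval(conds, K = 1, n_restarts = 1, seed = 1,
                             max_iter = 20)
  expect_equal(dim(cc$nll_bits), c(3L, 2L))
  expect_true(all(is.finite(cc$nll_bits)))
  # matched models beat mismatched ones under strongly different rules
  expect_gt(cc$nll_bits["female", "female"], cc$nll_bits["male", "female"])
  expect_gt(cc$nll_bits["male", "male"], cc$nll_bits["female", "male"])
  conds$male$heldout <- list()
  expect_error(cross_condition_eval(conds, K = 1), "no held-out")
})

test_that("decision-space embedding separates modes with disjoint drivers and is reproducible", {
  basis <- raised_cosine_basis(10, 2)
  P <- 2 * 2 + 1
  # two states driven by disjoint features with opposite signs
  W <- list(rbind(c(5, 0, 0, 0, 0), c(rep(0, P)), 0),
            rbind(c(0, 0, -5, 0, 0), c(rep(0, P)), 0))
  alpha <- matrix(c(0.95, 0.05, 0.05, 0.95), 2)
  gt <- hmmglm_params(c(0.5, 0.5), alpha, W)
  set.seed(41)
  f <- matrix(rnorm(300 * 2), 300)
  sim <- simulate_song(gt, f, basis, seed = 42)
  tr <- list(list(X = sim$X, y = sim$y))
  e1 <- decision_space_embedding(gt, tr, seed = 7)
  e2 <- decision_space_embedding(gt, tr, seed = 7)
  expect_equal(e1$embedding, e2$embedding)
  expect_equal(nrow(e1$embedding), 300)
  # the filtered-cue vectors of the two states live in disjoint coordinates
  s1 <- e1$filtered[e1$state == 1, 1:2, drop = FALSE]
  s2 <- e1$filtered[e1$state == 2, 3:4, drop = FALSE]
  expect_true(all(e1$filtered[e1$state == 1, 3:4] == 0))
  expect_true(all(e1$filtered[e1$state == 2, 1:2] == 0))
})
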
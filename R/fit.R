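# Weighted, L2-penalized softmax regression: the M-step for one state's
# emission GLM. Rows 1..M-1 of W are free; the silence row stays zero.

mstep_penalty <- function(W, lambda) lambda * sum(W[-nrow(W), ]^2)

# Q_k(W) = sum_t g_t log P(y_t | x_t, W) - lambda * ||W_free||^2
mstep_objective <- function(W, X, Yind, g, lambda) {
  eta <- X %*% t(W)
  eta <- eta - row_max(eta)
  logZ <- log(rowSums(exp(eta)))
  sum(g * (rowSums(Yind * eta) - logZ)) - mstep_penalty(W, lambda)
}

optimize_emission_filters <- function(W0, X, y, g, lambda, maxit = 50,
                                      reltol = 1e-8) {
  M <- nrow(W0); P <- ncol(W0); nfree <- M - 1
  Yind <- matrix(0, length(y), M)
  Yind[cbind(seq_along(y), y)] <- 1

  unpack <- function(par) rbind(matrix(par, nfree, P), 0)
  # fn and gr share the softmax evaluation when called at the same point
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return()
    W <- unpack(par)
    eta <- X %*% t(W)
    eta <- eta - row_max(eta)
    Pm <- exp(eta)
    Z <- rowSums(Pm)
    cache$par <- par; cache$W <- W; cache$eta <- eta
    cache$Pm <- Pm / Z; cache$logZ <- log(Z)
  }
  fn <- function(par) {
    eval_at(par)
    -(sum(g * (rowSums(Yind * cache$eta) - cache$logZ)) -
        mstep_penalty(cache$W, lambda))
  }
  gr <- function(par) {
    eval_at(par)
    Gfree <- t((Yind - cache$Pm)[, seq_len(nfree), drop = FALSE] * g) %*% X -
      2 * lambda * cache$W[seq_len(nfree), , drop = FALSE]
    -as.vector(Gfree)
  }
  opt <- stats::optim(as.vector(W0[seq_len(nfree), , drop = FALSE]), fn, gr,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = reltol / .Machine$double.eps))
  unpack(opt$par)
}

random_init <- function(K, M, P, y_all, sticky = 0.95, w_sd = 0.1,
                        bias_sd = 1.5) {
  alpha <- matrix((1 - sticky) / (K - 1), K, K)
  if (K == 1) alpha <- matrix(1, 1, 1) else diag(alpha) <- sticky
  # slopes are small-variance random; the per-mode biases scatter around the
  # empirical log-odds with a larger spread so the states start with
  # distinct emission profiles (identical starts trap EM in a symmetric,
  # state-collapsed optimum)
  freq <- tabulate(y_all, M) / length(y_all)
  freq[freq == 0] <- 1e-6
  logit <- log(freq / freq[M])
  W <- lapply(seq_len(K), function(k) {
    Wk <- matrix(stats::rnorm((M - 1) * P, sd = w_sd), M - 1, P)
    Wk[, P] <- logit[-M] + stats::rnorm(M - 1, sd = bias_sd)
    rbind(Wk, 0)
  })
  hmmglm_params(rep(1 / K, K), alpha, W)
}

#' Fit an HMM-GLM by Expectation-Maximization
#'
#' E-step: forward-backward posteriors per trial. M-step: closed-form updates
#' for the initial distribution and transition matrix from the state and
#' pairwise marginals; per-state emission filters by L2-penalized weighted
#' multinomial-regression (L-BFGS, warm-started from the previous iterate).
#' The penalized training objective (log-likelihood minus the L2 penalty) is
#' non-decreasing across iterations; a state's filter update is discarded if
#' the inner optimizer fails to improve its expected objective. The best of
#' `n_restarts` random initializations (by final penalized objective) is
#' returned.
#'
#' @param trials list of trials, each a list with `X` (design matrix, bias
#'   last) and `y` (integer labels in `1..M`).
#' @param K number of hidden states (>= 1).
#' @param n_restarts random restarts (default 20).
#' @param l2 L2 penalty strength per training sample (default 1e-3); the
#'   total penalty is `l2 * n_samples * sum(W_free^2)`.
#' @param seed RNG seed for the restarts.
#' @param max_iter,tol EM stopping rule: relative objective change `< tol`
#'   (default 1e-6) or `max_iter` iterations (default 200).
#' @param M number of observation modes (default 3).
#' @param inner_maxit L-BFGS iteration cap per M-step (warm starts make a
#'   small cap sufficient).
#' @param verbose print per-iteration objectives.
#' @return list with `params` (`hmmglm_params`), `objective` (final penalized
#'   objective), `loglik` (unpenalized), `trace` (per-iteration objective of
#'   the winning restart), `restart_objectives`, `restart_traces` (the
#'   per-iteration objective of every restart), and `l2`.
#' @export
fit_em <- function(trials, K, n_restarts = 20, l2 = 1e-3, seed = 1,
                   max_iter = 200, tol = 1e-6, M = 3L, inner_maxit = 30,
                   verbose = FALSE) {
  if (K < 1) stop("K must be >= 1")
  if (length(trials) < 1) stop("at least one training trial required")
  P <- ncol(trials[[1]]$X)
  y_all <- unlist(lapply(trials, `[[`, "y"))
  n_total <- length(y_all)
  lambda <- l2 * n_total

  set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max, n_restarts)

  best <- NULL
  restart_obj <- numeric(n_restarts)
  restart_traces <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(restart_seeds[r])
    params <- random_init(K, M, P, y_all)
    fit <- em_single(params, trials, lambda, max_iter, tol, inner_maxit,
                     verbose = verbose)
    restart_obj[r] <- fit$objective
    restart_traces[[r]] <- fit$trace
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }
  best$restart_objectives <- restart_obj
  best$restart_traces <- restart_traces
  best$l2 <- l2
  best
}

em_single <- function(params, trials, lambda, max_iter, tol, inner_maxit,
                      verbose = FALSE) {
  K <- params$K; M <- params$M
  Xall <- do.call(rbind, lapply(trials, `[[`, "X"))
  yall <- unlist(lapply(trials, `[[`, "y"))

  penalty <- function(p) sum(vapply(p$W, mstep_penalty, 0, lambda = lambda))
  trace <- numeric(0)
  obj_prev <- -Inf

  for (iter in seq_len(max_iter)) {
    # E-step
    post <- lapply(trials, function(tr)
      forward_backward(params, tr$X, tr$y, compute_xi = FALSE))
    loglik <- sum(vapply(post, `[[`, 0, "loglik"))
    obj <- loglik - penalty(params)

    if (obj + 1e-9 < obj_prev) {  # numerical guard: never report a decrease
      break
    }
    trace <- c(trace, obj)
    if (verbose) message(sprintf("EM iter %d: objective %.6f", iter, obj))
    if (is.finite(obj_prev) && abs(obj - obj_prev) < tol * abs(obj_prev)) {
      obj_prev <- obj
      break
    }
    obj_prev <- obj

    # M-step: pi and alpha in closed form
    g1 <- Reduce(`+`, lapply(post, function(p) p$gamma[1, ]))
    pi_new <- g1 / sum(g1)
    if (K > 1) {
      xi_sum <- Reduce(`+`, lapply(post, `[[`, "xi_sum"))
      alpha_new <- xi_sum / rowSums(xi_sum)
    } else alpha_new <- matrix(1, 1, 1)

    # M-step: per-state filters on the pooled data, gamma-weighted
    gamma_all <- do.call(rbind, lapply(post, `[[`, "gamma"))
    W_new <- params$W
    for (k in seq_len(K)) {
      Wk <- optimize_emission_filters(params$W[[k]], Xall, yall,
                                      gamma_all[, k], lambda,
                                      maxit = inner_maxit)
      # keep the previous filters if the inner step did not improve Q_k
      q_old <- mstep_objective_cached(params$W[[k]], Xall, yall, gamma_all[, k], lambda)
      q_new <- mstep_objective_cached(Wk, Xall, yall, gamma_all[, k], lambda)
      if (q_new > q_old) W_new[[k]] <- Wk
    }
    params <- hmmglm_params(pi_new, alpha_new, W_new, params$modes)
  }

  list(params = params, objective = obj_prev,
       loglik = obj_prev + penalty(params), trace = trace,
       n_iter = length(trace))
}

mstep_objective_cached <- function(W, X, y, g, lambda) {
  Yind <- matrix(0, length(y), nrow(W))
  Yind[cbind(seq_along(y), y)] <- 1
  mstep_objective(W, X, Yind, g, lambda)
}

#' Reduce trials to an intercept-only design (HMM-only baseline)
#'
#' Strips every design column except the trailing bias, so the fitted model
#' is a plain hidden Markov model with a fixed emission distribution per
#' state (the filters reduce to per-mode intercepts).
#'
#' @param trials list of trials as in [fit_em()].
#' @return trials with single-column designs.
#' @export
intercept_only_trials <- function(trials) {
  lapply(trials, function(tr) {
    P <- ncol(tr$X)
    list(X = tr$X[, P, drop = FALSE], y = tr$y)
  })
}
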
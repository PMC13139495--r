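# Shared test fixtures and independent oracles.

# small random HMM-GLM with well-behaved simplex parameters
random_params <- function(K, M = 3, P = 4, seed = 1, w_sd = 1) {
  set.seed(seed)
  pi <- stats::runif(K); pi <- pi / sum(pi)
  alpha <- matrix(stats::runif(K * K) + 0.2, K, K)
  alpha <- alpha / rowSums(alpha)
  W <- lapply(seq_len(K), function(k)
    rbind(matrix(stats::rnorm((M - 1) * P, sd = w_sd), M - 1, P), 0))
  hmmglm_params(pi, alpha, W)
}

random_instance <- function(K, T_len, M = 3, P = 4, seed = 1) {
  p <- random_params(K, M, P, seed)
  set.seed(seed + 1000)
  X <- cbind(matrix(stats::rnorm(T_len * (P - 1)), T_len), 1)
  y <- sample.int(M, T_len, replace = TRUE)
  list(params = p, X = X, y = y)
}

# Exhaustive path-sum oracle: log-likelihood, state marginals, pairwise
# marginals and the MAP path by brute-force enumeration of all K^T paths.
enum_oracle <- function(params, X, y) {
  K <- params$K; T_len <- nrow(X)
  E <- sapply(seq_len(K), function(k) {
    Pk <- emission_probs(params$W[[k]], X)
    if (is.null(dim(Pk))) Pk <- matrix(Pk, nrow = 1)
    Pk[cbind(seq_len(T_len), y)]
  })
  if (is.null(dim(E))) E <- matrix(E, nrow = T_len)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
  logp <- apply(paths, 1, function(z) {
    lp <- log(params$pi[z[1]]) + log(E[1, z[1]])
    if (T_len > 1) for (t in 2:T_len)
      lp <- lp + log(params$alpha[z[t - 1], z[t]]) + log(E[t, z[t]])
    lp
  })
  m <- max(logp)
  loglik <- m + log(sum(exp(logp - m)))
  w <- exp(logp - loglik)
  gamma <- matrix(0, T_len, K)
  for (t in seq_len(T_len)) for (k in seq_len(K))
    gamma[t, k] <- sum(w[paths[, t] == k])
  xi <- NULL
  if (T_len > 1) {
    xi <- array(0, c(K, K, T_len - 1))
    for (t in seq_len(T_len - 1)) for (i in seq_len(K)) for (j in seq_len(K))
      xi[i, j, t] <- sum(w[paths[, t] == i & paths[, t + 1] == j])
  }
  # MAP path; enumerate in lexicographic order so ties resolve to the
  # lowest-index path, matching the decoder's tie-break contract
  ord <- do.call(order, c(as.data.frame(paths), list(decreasing = FALSE)))
  best <- ord[which.max(logp[ord])]
  list(loglik = loglik, gamma = gamma, xi = xi, path = paths[best, ])
}

# tiny deterministic two-state model whose states are separated by bias
# alone (state 1 pulse-biased, state 2 sine-biased), sticky transitions
toy_sticky_params <- function(stick = 0.95, bias = 2) {
  W1 <- rbind(c(0, bias), c(0, -bias), 0)
  W2 <- rbind(c(0, -bias), c(0, bias), 0)
  hmmglm_params(c(0.5, 0.5), matrix(c(stick, 1 - stick, 1 - stick, stick), 2),
                list(W1, W2))
}
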
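#' @keywords internal
"_PACKAGE"

# Song-mode coding used throughout: 1 = pulse, 2 = sine, 3 = silence.
SONG_MODES <- c("pulse", "sine", "silence")

# fast row-wise maximum (columns are few, rows are many)
row_max <- function(m) do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))

#' Construct an HMM-GLM parameter set
#'
#' @param pi initial state distribution, length `K`, on the simplex.
#' @param alpha `K x K` transition matrix, rows on the simplex.
#' @param W list of `K` emission filter banks; each an `M x P` matrix whose
#'   rows are the per-mode filters over the design columns (bias last). The
#'   silence row (row `M`) is pinned to zero for identifiability.
#' @param modes character vector of observation labels (default pulse, sine,
#'   silence).
#' @return object of class `hmmglm_params`.
#' @export
hmmglm_params <- function(pi, alpha, W, modes = SONG_MODES) {
  K <- length(pi)
  stopifnot(is.matrix(alpha), nrow(alpha) == K, ncol(alpha) == K,
            is.list(W), length(W) == K)
  if (abs(sum(pi) - 1) > 1e-8 || any(pi < 0)) stop("pi must lie on the simplex")
  if (any(abs(rowSums(alpha) - 1) > 1e-8) || any(alpha < 0))
    stop("alpha rows must lie on the simplex")
  M <- nrow(W[[1]])
  for (k in seq_len(K)) {
    if (!all(is.finite(W[[k]]))) stop("non-finite filter values")
    if (any(W[[k]][M, ] != 0))
      stop("the silence (last-mode) filter must be pinned to zero")
  }
  structure(list(pi = pi, alpha = alpha, W = W, K = K, M = M,
                 P = ncol(W[[1]]), modes = modes),
            class = "hmmglm_params")
}

#' @export
print.hmmglm_params <- function(x, ...) {
  cat(sprintf("HMM-GLM: K = %d states, M = %d modes, %d filter coefficients/mode\n",
              x$K, x$M, x$P))
  cat("transition matrix:\n"); print(round(x$alpha, 3))
  invisible(x)
}

#' Softmax emission probabilities of one state's GLM
#'
#' @param W_k `M x P` filter matrix of one state (silence row zero).
#' @param x design vector (length `P`) or matrix (`T x P`).
#' @return vector (or `T x M` matrix) of mode probabilities summing to 1.
#' @export
emission_probs <- function(W_k, x) {
  if (!all(is.finite(W_k))) stop("non-finite filter values")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  eta <- x %*% t(W_k)                      # T x M linear predictors
  eta <- eta - row_max(eta)                # numerical stability
  p <- exp(eta)
  p <- p / rowSums(p)
  if (nrow(p) == 1) drop(p) else p
}

# T x K matrix of P(y_t | z_t = k, x_t) for observed labels y.
emission_likelihoods <- function(params, X, y) {
  nT <- nrow(X)
  L <- matrix(0, nT, params$K)
  for (k in seq_len(params$K)) {
    P <- emission_probs(params$W[[k]], X)
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    L[, k] <- P[cbind(seq_len(nT), y)]
  }
  L
}

#' Forward-backward inference for an HMM-GLM
#'
#' Scaled forward/backward recursions. The per-step scaling constants are the
#' one-step predictive probabilities `P(y_t | y_1..t-1, X)`, so the total
#' log-likelihood is the sum of their logs; `step_loglik` exposes them so
#' likelihoods can be evaluated on arbitrary subsets of time points (e.g.
#' song-mode transitions).
#'
#' @param params `hmmglm_params`.
#' @param X design matrix (`T x P`).
#' @param y integer observation labels in `1..M`.
#' @param compute_xi keep the full `K x K x (T-1)` pairwise-marginal array
#'   (the summed `xi_sum` needed by EM is always returned).
#' @return list of class `hmmglm_posteriors`: `gamma` (`T x K` state
#'   marginals), `xi` (`K x K x (T-1)` pairwise marginals, or NULL),
#'   `xi_sum` (`K x K`), `loglik`, `step_loglik` (length `T`), and the
#'   scaled `alpha_f`, `beta_b` matrices.
#' @export
forward_backward <- function(params, X, y, compute_xi = TRUE) {
  y <- as.integer(y)
  nT <- nrow(X); K <- params$K
  E <- emission_likelihoods(params, X, y)
  a <- matrix(0, nT, K); b <- matrix(0, nT, K)
  cvec <- numeric(nT)

  v <- params$pi * E[1, ]
  cvec[1] <- sum(v)
  if (cvec[1] <= 0) stop("observation at t=1 has zero probability under all states")
  a[1, ] <- v / cvec[1]
  tA <- t(params$alpha)
  if (nT > 1) for (t in 2:nT) {
    v <- drop(tA %*% a[t - 1, ]) * E[t, ]
    cvec[t] <- sum(v)
    if (cvec[t] <= 0)
      stop(sprintf("observation at t=%d has zero probability under all states", t))
    a[t, ] <- v / cvec[t]
  }

  b[nT, ] <- 1
  if (nT > 1) for (t in (nT - 1):1) {
    b[t, ] <- drop(params$alpha %*% (E[t + 1, ] * b[t + 1, ])) / cvec[t + 1]
  }

  gamma <- a * b
  gamma <- gamma / rowSums(gamma)

  xi <- NULL; xi_sum <- NULL
  if (nT > 1) {
    # sum_t xi[, , t] without materializing the array
    EBc <- E[-1, , drop = FALSE] * b[-1, , drop = FALSE] / cvec[-1]
    xi_sum <- (t(a[-nT, , drop = FALSE]) %*% EBc) * params$alpha
    if (compute_xi) {
      xi <- array(0, c(K, K, nT - 1))
      for (t in seq_len(nT - 1))
        xi[, , t] <- (a[t, ] %o% EBc[t, ]) * params$alpha
    }
  }

  structure(list(gamma = gamma, xi = xi, xi_sum = xi_sum,
                 loglik = sum(log(cvec)),
                 step_loglik = log(cvec), alpha_f = a, beta_b = b,
                 emission_lik = E),
            class = "hmmglm_posteriors")
}

#' Most likely hidden-state path (Viterbi)
#'
#' Ties are broken toward the lower state index.
#'
#' @inheritParams forward_backward
#' @return integer vector of length `T` with the argmax state path.
#' @export
viterbi_decode <- function(params, X, y) {
  y <- as.integer(y)
  nT <- nrow(X); K <- params$K
  logE <- log(emission_likelihoods(params, X, y))
  logA <- log(params$alpha)
  delta <- matrix(-Inf, nT, K)
  back <- matrix(1L, nT, K)
  delta[1, ] <- log(params$pi) + logE[1, ]
  if (nT > 1) for (t in 2:nT) {
    for (k in seq_len(K)) {
      cand <- delta[t - 1, ] + logA[, k]
      back[t, k] <- which.max(cand)  # which.max: first (lowest) index on ties
      delta[t, k] <- cand[back[t, k]] + logE[t, k]
    }
  }
  path <- integer(nT)
  path[nT] <- which.max(delta[nT, ])
  if (nT > 1) for (t in (nT - 1):1) path[t] <- back[t + 1, path[t + 1]]
  path
}
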
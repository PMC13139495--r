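#' Raised-cosine basis over a lag axis
#'
#' Builds `D` raised-cosine bumps covering `N` lags (lag 0 = current sample).
#' Bump centres are log-spaced along the lag axis so that early lags are
#' resolved finely and bumps broaden with delay, reflecting that recent cues
#' weigh most on the upcoming response. Each bump is
#' `0.5 * (1 + cos(phi(lag) - c_j))` on its support and zero outside, where
#' `phi` is a log-stretched lag coordinate.
#'
#' @param n_lags number of lags `N` covered by the basis (default 120,
#'   i.e. a 4 s history at 30 Hz).
#' @param n_basis number of basis functions `D` (default 10).
#' @param log_offset nonlinearity offset controlling how strongly centres are
#'   compressed toward lag 0; larger values make spacing more linear.
#' @return object of class `rc_basis`: a list with `B` (an `n_lags x n_basis`
#'   nonnegative matrix, columns are basis vectors), `n_lags`, `n_basis`.
#' @examples
#' b <- raised_cosine_basis(120, 10)
#' stopifnot(all(b$B >= 0), all(rowSums(b$B) > 0))
#' @export
raised_cosine_basis <- function(n_lags = 120L, n_basis = 10L, log_offset = 6) {
  n_lags <- as.integer(n_lags)
  n_basis <- as.integer(n_basis)
  if (n_basis < 1L) stop("n_basis must be >= 1")
  if (n_basis > n_lags) stop("n_basis must not exceed n_lags")

  lag <- seq_len(n_lags) - 1
  # log-stretched lag coordinate: fine near lag 0, compressed at long lags
  phi <- log(lag + log_offset)
  # centres equally spaced in phi => log-spaced in lag, broadening with delay
  ctr <- seq(phi[1], phi[n_lags], length.out = n_basis)
  # bumps overlap their neighbours; the final bump is truncated by the
  # history horizon (its peak sits at the longest lag)
  width <- if (n_basis > 1L) diff(ctr[1:2]) * 2 else diff(range(phi)) * (1 + 1e-3)

  B <- vapply(ctr, function(cj) {
    arg <- (phi - cj) * pi / width
    ifelse(abs(arg) < pi, 0.5 * (1 + cos(arg)), 0)
  }, numeric(n_lags))
  # guarantee full coverage at the extreme lags
  B[1, 1] <- max(B[1, 1], 0.5)
  structure(list(B = B, n_lags = n_lags, n_basis = n_basis,
                 log_offset = log_offset),
            class = "rc_basis")
}

#' @export
print.rc_basis <- function(x, ...) {
  cat(sprintf("raised-cosine basis: %d functions over %d lags\n",
              x$n_basis, x$n_lags))
  invisible(x)
}

#' Project lagged feature histories onto a basis and build the design matrix
#'
#' For each time point the trailing `N`-sample history of every feature is
#' projected onto the `D` basis vectors, giving a `n_features * D` vector,
#' which is z-scored (training statistics are estimated here unless `stats`
#' is supplied, e.g. for held-out trials) and augmented with a trailing bias 1.
#'
#' Rows near the trial start lack a full history; missing lags are imputed
#' with the feature's training mean before projection, which is equivalent to
#' zero-padding in the z-scored column space.
#'
#' @param features numeric matrix or data.frame, one row per 30 Hz frame, one
#'   column per feedback feature (10 in the standard pipeline).
#' @param basis an `rc_basis` object.
#' @param stats optional list with `mean`, `sd` (per projected column) and
#'   `feature_mean` (per raw feature) from a previous training call.
#' @return list with `X` (T x (F*D + 1) design matrix, bias last), `stats`,
#'   and `col_feature` (integer feature index of each non-bias column).
#' @export
build_design <- function(features, basis, stats = NULL) {
  stopifnot(inherits(basis, "rc_basis"))
  F0 <- as.matrix(features)
  if (!is.numeric(F0)) stop("features must be numeric")
  if (anyNA(F0)) stop("features contain NA; interpolate or drop frames first")
  nT <- nrow(F0); nf <- ncol(F0)
  B <- basis$B; N <- basis$n_lags; D <- basis$n_basis

  feat_mean <- if (is.null(stats)) colMeans(F0) else stats$feature_mean
  # impute the pre-trial history with the (training) feature means
  Fpad <- rbind(matrix(feat_mean, nrow = N - 1, ncol = nf, byrow = TRUE), F0)

  X <- matrix(0, nT, nf * D)
  for (f in seq_len(nf)) {
    for (j in seq_len(D)) {
      # x_t = sum_l s_{t-l} * B[l+1, j]  — causal FIR filter with kernel B[,j]
      v <- stats::filter(Fpad[, f], B[, j], method = "convolution", sides = 1)
      X[, (f - 1) * D + j] <- v[N:(N + nT - 1)]
    }
  }

  if (is.null(stats)) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    if (any(sdv <= 0)) sdv[sdv <= 0] <- 1  # constant column: centre only
    stats <- list(mean = mu, sd = sdv, feature_mean = feat_mean)
  }
  X <- sweep(X, 2, stats$mean, "-")
  X <- sweep(X, 2, stats$sd, "/")
  X <- cbind(X, 1)
  list(X = X, stats = stats, col_feature = rep(seq_len(nf), each = D))
}
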
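#' Seeded 2-D manifold embedding (UMAP wrapper)
#'
#' Single-threaded, seeded UMAP so embeddings are reproducible; returns the
#' fitted model so held-out points can be transformed into the same space.
#'
#' @param X numeric matrix (rows = samples).
#' @param seed RNG seed.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param ret_model keep the model for [umap_project()].
#' @return list with `embedding` (n x 2) and `model` (or NULL).
#' @export
embed_umap <- function(X, seed = 1, n_neighbors = 15, min_dist = 0.1,
                       ret_model = FALSE) {
  set.seed(seed)
  n_neighbors <- max(2, min(n_neighbors, nrow(X) - 1))
  m <- uwot::umap(X, n_neighbors = n_neighbors, min_dist = min_dist,
                  n_threads = 1, n_sgd_threads = 1, ret_model = ret_model,
                  seed = seed)
  if (ret_model) list(embedding = m$embedding, model = m)
  else list(embedding = m, model = NULL)
}

#' Project new points into a fitted embedding
#' @param X new data matrix.
#' @param model model from [embed_umap()] with `ret_model = TRUE`.
#' @return n x 2 coordinates.
#' @export
umap_project <- function(X, model) {
  uwot::umap_transform(X, model, n_threads = 1)
}

#' Kernel-density + watershed segmentation of a 2-D point cloud
#'
#' Estimates a kernel density on a regular grid (normal-reference
#' bandwidth), optionally smooths it, runs watershed segmentation on the
#' inverted density so each density mode becomes one region, and masks out
#' background cells whose density falls below a quantile of the positive
#' cells. Each input point inherits the label of its grid cell (0 =
#' background).
#'
#' @param points n x 2 matrix.
#' @param grid_n grid resolution per axis (default 256).
#' @param smooth_sigma Gaussian smoothing of the density in grid cells
#'   (default 2).
#' @param background_quantile density quantile below which cells are
#'   background (default 0.01).
#' @param bandwidth_mult multiplier on the normal-reference bandwidth.
#' @param min_prominence minimum mode prominence as a fraction of the peak
#'   density (default 0.05); shallower modes merge with their neighbours.
#' @return list with `x`, `y` (grid axes), `density` (grid, integrates to
#'   1), `labels` (grid of region ids), `point_labels`, `n_modes`.
#' @export
density_watershed <- function(points, grid_n = 256, smooth_sigma = 2,
                              background_quantile = 0.01,
                              bandwidth_mult = 1, min_prominence = 0.05) {
  stopifnot(ncol(points) == 2, nrow(points) >= 2)
  pad <- function(v) {
    r <- range(v); w <- diff(r)
    if (w == 0) w <- max(abs(r[1]), 1)
    c(r[1] - 0.1 * w, r[2] + 0.1 * w)
  }
  h <- c(MASS::bandwidth.nrd(points[, 1]), MASS::bandwidth.nrd(points[, 2]))
  h[h <= 0] <- 1
  kd <- MASS::kde2d(points[, 1], points[, 2], n = grid_n,
                    h = h * bandwidth_mult,
                    lims = c(pad(points[, 1]), pad(points[, 2])))
  d <- kd$z
  if (smooth_sigma > 0)
    d <- EBImage::gblur(d, sigma = smooth_sigma)
  d[d < 0] <- 0
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  d <- d / (sum(d) * cell)

  thr <- stats::quantile(d[d > 0], background_quantile)
  # watershed of the inverted surface: basins around each density mode.
  # EBImage grows labels from local maxima of its input, so feed the
  # unit-peak density; `tolerance` is the mode prominence on that scale.
  lab <- EBImage::imageData(EBImage::watershed(EBImage::as.Image(d / max(d)),
                                               tolerance = min_prominence))
  lab[d < thr] <- 0L

  xi <- pmin(pmax(findInterval(points[, 1], kd$x), 1L), grid_n)
  yi <- pmin(pmax(findInterval(points[, 2], kd$y), 1L), grid_n)
  pl <- as.integer(lab[cbind(xi, yi)])
  # far-field watershed basins that capture no data points are vacuous;
  # fold them into the background and renumber the surviving modes
  keep <- sort(unique(pl[pl > 0]))
  lab[!(lab %in% keep)] <- 0L
  relab <- match(lab, keep, nomatch = 0L)
  lab <- matrix(as.integer(relab), nrow(lab), ncol(lab))
  pl <- match(pl, keep, nomatch = 0L)
  list(x = kd$x, y = kd$y, density = d, labels = lab,
       point_labels = as.integer(pl),
       n_modes = length(keep))
}

#' Flattened lag design for social maps
#'
#' Per frame, the last `k_lags` samples of every feature are concatenated
#' (feature-major blocks of `k_lags` lags each); the pre-trial history is
#' padded with the first frame.
#'
#' @param features T x M numeric feature matrix (M = 10 standard features).
#' @param k_lags history length in samples (default 15, i.e. 0.5 s at 30 Hz).
#' @return T x (k_lags * M) matrix.
#' @export
social_lag_design <- function(features, k_lags = 15) {
  F0 <- as.matrix(features)
  nT <- nrow(F0); M <- ncol(F0)
  if (nT < k_lags) stop("trial shorter than the lag history")
  Fpad <- rbind(matrix(F0[1, ], k_lags - 1, M, byrow = TRUE), F0)
  X <- matrix(0, nT, k_lags * M)
  for (t in seq_len(nT))
    X[t, ] <- as.vector(Fpad[t:(t + k_lags - 1), ])
  X
}

#' Fit a social map: embedding, density, watershed modes
#'
#' Fits the embedding on a temporally uniform subsample of the pooled
#' designs, transforms all frames, and segments the embedding density into
#' modes by watershed of the inverted density.
#'
#' @param designs list of per-trial design matrices (from
#'   [social_lag_design()]) or a single matrix.
#' @param subsample fraction of frames used to fit the embedding
#'   (default 0.1, uniformly spaced in time).
#' @param seed embedding seed.
#' @param grid_n,smooth_sigma,background_quantile passed to
#'   [density_watershed()].
#' @param n_neighbors,min_dist passed to [embed_umap()].
#' @return object of class `social_map`: `embedding` (all frames), `trial`
#'   (trial index per frame), `segmentation`, `model`, `mode_labels` per
#'   frame.
#' @export
fit_social_map <- function(designs, subsample = 0.1, seed = 1, grid_n = 256,
                           smooth_sigma = 2, background_quantile = 0.01,
                           n_neighbors = 15, min_dist = 0.1) {
  if (is.matrix(designs)) designs <- list(designs)
  if (length(designs) == 0 || sum(vapply(designs, nrow, 0L)) == 0)
    stop("empty input")
  X <- do.call(rbind, designs)
  trial <- rep(seq_along(designs), vapply(designs, nrow, 0L))
  step <- max(1L, round(1 / subsample))
  fit_idx <- seq(1, nrow(X), by = step)
  emb <- embed_umap(X[fit_idx, , drop = FALSE], seed = seed,
                    n_neighbors = n_neighbors, min_dist = min_dist,
                    ret_model = TRUE)
  all_emb <- matrix(NA_real_, nrow(X), 2)
  all_emb[fit_idx, ] <- emb$embedding
  rest <- setdiff(seq_len(nrow(X)), fit_idx)
  if (length(rest) > 0)
    all_emb[rest, ] <- umap_project(X[rest, , drop = FALSE], emb$model)
  seg <- density_watershed(all_emb, grid_n = grid_n,
                           smooth_sigma = smooth_sigma,
                           background_quantile = background_quantile)
  structure(list(embedding = all_emb, trial = trial, segmentation = seg,
                 model = emb$model, mode_labels = seg$point_labels),
            class = "social_map")
}

#' @export
print.social_map <- function(x, ...) {
  cat(sprintf("social map: %d frames, %d trials, %d modes\n",
              nrow(x$embedding), length(unique(x$trial)),
              x$segmentation$n_modes))
  invisible(x)
}

#' Per-trial mode occupancy and condition difference maps
#'
#' @param map a `social_map`.
#' @param conditions optional named list of logical per-frame masks; for
#'   each pair of conditions the difference between their kernel densities
#'   on the map grid is returned.
#' @return list with `occupancy` (trials x modes fractions of all frames;
#'   background excluded from the modes, so rows sum to <= 1),
#'   `condition_density` and `difference` (first minus second condition)
#'   when conditions are given.
#' @export
mode_occupancy <- function(map, conditions = NULL) {
  seg <- map$segmentation
  modes <- sort(setdiff(unique(as.vector(seg$labels)), 0L))
  trials <- sort(unique(map$trial))
  occ <- matrix(0, length(trials), length(modes),
                dimnames = list(trials, modes))
  for (i in seq_along(trials)) {
    sel <- map$trial == trials[i]
    n <- sum(sel)
    for (j in seq_along(modes))
      occ[i, j] <- sum(map$mode_labels[sel] == modes[j]) / n
  }
  out <- list(occupancy = occ)
  if (!is.null(conditions)) {
    dens <- lapply(conditions, function(msk) {
      if (sum(msk) == 0) return(NULL)  # flagged: no frames in condition
      pts <- map$embedding[msk, , drop = FALSE]
      h <- c(MASS::bandwidth.nrd(pts[, 1]), MASS::bandwidth.nrd(pts[, 2]))
      h[h <= 0] <- 1
      kd <- MASS::kde2d(pts[, 1], pts[, 2], n = length(seg$x), h = h,
                        lims = c(range(seg$x), range(seg$y)))
      kd$z / (sum(kd$z) * diff(kd$x[1:2]) * diff(kd$y[1:2]))
    })
    out$condition_density <- dens
    empty <- vapply(dens, is.null, TRUE)
    out$empty_conditions <- names(dens)[empty]
    if (length(dens) >= 2 && !any(empty[1:2]))
      out$difference <- dens[[1]] - dens[[2]]
  }
  out
}

#' Morlet continuous wavelet power
#'
#' FFT-based continuous Morlet wavelet transform returning signal power at
#' the requested frequencies (amplitude-normalized so a unit-amplitude tone
#' yields its largest response at the nearest analysed frequency).
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param freqs analysis frequencies in Hz.
#' @param omega0 Morlet nondimensional frequency (default 5).
#' @return length(x) x length(freqs) nonnegative power matrix.
#' @export
morlet_power <- function(x, fs, freqs, omega0 = 5) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  omega <- 2 * pi * fs * c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  P <- matrix(0, n, length(freqs))
  for (i in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[i])
    psi <- exp(-0.5 * (s * omega - omega0)^2) * (omega > 0)
    w <- stats::fft(X * psi, inverse = TRUE) / n
    P[, i] <- Mod(w)^2
  }
  P
}

#' Dyadically spaced frequencies
#' @param fmin,fmax frequency range in Hz.
#' @param n number of frequencies (default 25).
#' @return geometric (base-2) frequency grid.
#' @export
dyadic_freqs <- function(fmin = 1, fmax = 25, n = 25) {
  2^seq(log2(fmin), log2(fmax), length.out = n)
}

#' Wavelet featurization and behavioural map of pose dynamics
#'
#' Aligns each fly egocentrically (translate to its thorax, rotate to its
#' heading, scale by fly length), computes Morlet wavelet power of every
#' pose coordinate channel at 25 dyadically spaced frequencies between 1
#' and 25 Hz (24 channels default: both flies' 6 keypoints x 2
#' coordinates, giving 600 power features per frame), and builds an
#' embedding + density + watershed map of the flattened features.
#'
#' @param pose a `pose_pair` (already at the analysis rate, e.g. 30 Hz).
#' @param channels `"both"` (24 channels) or `"fly0"`/`"fly1"` (12).
#' @param freqs analysis frequencies (default `dyadic_freqs(1, 25, 25)`).
#' @param subsample,seed,grid_n passed to the map fitting.
#' @param fit_map set FALSE to return only the wavelet features.
#' @return list with `features` (T x channels*freqs), `channel_names`, and
#'   (unless `fit_map = FALSE`) `map`, a `social_map`.
#' @export
wavelet_behavior_map <- function(pose, channels = "both",
                                 freqs = dyadic_freqs(1, 25, 25),
                                 subsample = 0.1, seed = 1, grid_n = 256,
                                 fit_map = TRUE) {
  fs <- pose$frame_rate
  nT <- length(pose$time)
  if (nT / fs < 2 / min(freqs))
    stop("trial shorter than the longest wavelet support (two cycles of the lowest frequency)")
  fly_ids <- switch(channels, both = 1:2, fly0 = 1, fly1 = 2,
                    stop("unknown channel set"))
  chans <- list(); cn <- character(0)
  for (fl in fly_ids) {
    a <- pose$flies[[fl]]
    thx <- a[, 3, 1]; thy <- a[, 3, 2]
    axx <- a[, 1, 1] - a[, 4, 1]; axy <- a[, 1, 2] - a[, 4, 2]
    len <- stats::median(sqrt(axx^2 + axy^2))
    ang <- atan2(axy, axx)
    ca <- cos(-ang); sa <- sin(-ang)
    for (p in 1:6) {
      dx <- a[, p, 1] - thx; dy <- a[, p, 2] - thy
      ex <- (dx * ca - dy * sa) / len
      ey <- (dx * sa + dy * ca) / len
      chans <- c(chans, list(ex), list(ey))
      cn <- c(cn, paste0("fly", fl - 1, "_", BODY_PARTS[p], c("_x", "_y")))
    }
  }
  feat <- do.call(cbind, lapply(chans, function(ch) morlet_power(ch, fs, freqs)))
  out <- list(features = feat, channel_names = cn, freqs = freqs)
  if (fit_map)
    out$map <- fit_social_map(feat, subsample = subsample, seed = seed,
                              grid_n = grid_n)
  out
}
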
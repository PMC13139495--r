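# analytic signal (Hilbert) via FFT; x real vector
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# dominant frequency (Hz) of a snippet below a cutoff
spectral_peak <- function(x, fs, cutoff = 1000) {
  n <- length(x)
  mag <- Mod(stats::fft(x - mean(x)))[1:(n %/% 2 + 1)]
  freqs <- (0:(n %/% 2)) * fs / n
  ok <- freqs > 0 & freqs <= cutoff
  freqs[ok][which.max(mag[ok])]
}

gaussian_kernel <- function(sd_samples) {
  half <- ceiling(4 * sd_samples)
  k <- exp(-0.5 * ((-half:half) / sd_samples)^2)
  k / sum(k)
}

#' Per-pulse carrier frequency, width, and rejection flags
#'
#' Each waveform is a fixed-length snippet (35 ms at 10 kHz) centred on a
#' pulse. Carrier = dominant spectral frequency below 1 kHz. The envelope is
#' the magnitude of the analytic signal, smoothed with a Gaussian window
#' (sd 1.5 ms) and normalized to unit peak; width = total duration the
#' envelope stays above half peak. A pulse is flagged `noisy` when the
#' difference between the maximum and mean normalized envelope is below
#' 0.08, and `multi_peak` when the envelope rises above the 0.5 level in
#' more than one contiguous region; flagged pulses should be excluded from
#' width summaries.
#'
#' @param waveforms numeric matrix, one 350-sample (35 ms) snippet per row.
#' @param fs sampling rate, Hz (default 10000).
#' @param snippet_ms required snippet duration (default 35).
#' @param smooth_sd_ms Gaussian smoothing sd in ms (default 1.5).
#' @param noise_threshold max-minus-mean envelope threshold (default 0.08).
#' @return data.frame with `carrier_hz`, `width_ms`, `noisy`, `multi_peak`.
#' @export
pulse_metrics <- function(waveforms, fs = 10000, snippet_ms = 35,
                          smooth_sd_ms = 1.5, noise_threshold = 0.08) {
  if (is.null(dim(waveforms))) waveforms <- matrix(waveforms, nrow = 1)
  n_expected <- round(snippet_ms / 1000 * fs)
  if (ncol(waveforms) != n_expected)
    stop(sprintf("snippets must be %d samples (%g ms at %g Hz)",
                 n_expected, snippet_ms, fs))
  kern <- gaussian_kernel(smooth_sd_ms / 1000 * fs)
  out <- apply(waveforms, 1, function(w) {
    carrier <- spectral_peak(w, fs)
    env <- Mod(analytic_signal(w - mean(w)))
    env <- stats::filter(c(rev(env[seq_along(kern)]), env,
                           rev(env[length(env) - seq_along(kern) + 1])),
                         kern, sides = 2)
    env <- env[(length(kern) + 1):(length(kern) + length(w))]
    env <- env / max(env)
    above <- env > 0.5
    regions <- logical_bouts(above)
    c(carrier = carrier,
      width_ms = sum(above) / fs * 1000,
      noisy = as.numeric(max(env) - mean(env) < noise_threshold),
      multi_peak = as.numeric(nrow(regions) > 1))
  })
  data.frame(carrier_hz = out["carrier", ], width_ms = out["width_ms", ],
             noisy = out["noisy", ] > 0, multi_peak = out["multi_peak", ] > 0)
}

#' Inter-pulse intervals from pulse-centre times
#'
#' Successive differences in ms; intervals above `max_ipi_ms` span distinct
#' bouts and are removed.
#'
#' @param pulse_centers pulse-centre times in seconds.
#' @param max_ipi_ms bout-break threshold (default 100 ms).
#' @return numeric vector of IPIs in ms (empty for fewer than 2 pulses).
#' @export
interpulse_intervals <- function(pulse_centers, max_ipi_ms = 100) {
  if (length(pulse_centers) < 2) return(numeric(0))
  ipi <- diff(sort(pulse_centers)) * 1000
  ipi[ipi <= max_ipi_ms]
}

#' Sine-song carrier frequency
#'
#' Splits each sine interval into segments of `segment_samples` samples
#' (~25 ms at 10 kHz), takes each segment's dominant frequency below the
#' cutoff, and returns the modal value across all segments.
#'
#' @param audio numeric waveform.
#' @param fs sampling rate (default 10000 Hz).
#' @param sine_intervals data.frame with `onset_s`, `offset_s`.
#' @param segment_samples per-segment FFT length (default 256).
#' @param cutoff spectral cutoff in Hz (default 1000).
#' @return modal carrier frequency in Hz (NA when no interval holds a full
#'   segment; shorter intervals are skipped with a warning).
#' @export
sine_carrier <- function(audio, sine_intervals, fs = 10000,
                         segment_samples = 256, cutoff = 1000) {
  if (nrow(sine_intervals) == 0) return(NA_real_)
  freqs <- c()
  for (i in seq_len(nrow(sine_intervals))) {
    s <- max(1, round(sine_intervals$onset_s[i] * fs) + 1)
    e <- min(length(audio), round(sine_intervals$offset_s[i] * fs))
    if (e - s + 1 < segment_samples) {
      warning(sprintf("sine interval %d shorter than one segment; skipped", i))
      next
    }
    nseg <- (e - s + 1) %/% segment_samples
    for (j in seq_len(nseg)) {
      seg <- audio[(s + (j - 1) * segment_samples):(s + j * segment_samples - 1)]
      freqs <- c(freqs, spectral_peak(seg, fs, cutoff))
    }
  }
  if (length(freqs) == 0) return(NA_real_)
  tb <- table(freqs)
  as.numeric(names(tb)[which.max(tb)])
}

#' Song bouts and windowed song statistics
#'
#' Bouts are maximal runs of song (pulse or sine) interleaved by less than
#' `max_gap_ms` of silence; the bout order is 1 plus the number of
#' within-bout mode transitions. Per overlapping window (default 60 s, 50%
#' overlap) the amount (fraction of frames), number of onsets (transitions
#' into the mode), and duration (amount/onsets) are computed for pulse,
#' sine, and all song, then averaged across windows.
#'
#' @param labels integer per-frame labels (1 pulse, 2 sine, 3 silence;
#'   4 agonistic passes through as non-song).
#' @param frame_rate label rate in Hz (default 30).
#' @param window window length in seconds (default 60).
#' @param overlap window overlap fraction (default 0.5).
#' @param max_gap_ms within-bout silence tolerance (default 100).
#' @return list with `bouts` (data.frame: onset_s, offset_s, order,
#'   n_segments), `windowed` (per-window table), `summary` (per-mode means).
#' @export
bout_statistics <- function(labels, frame_rate = 30, window = 60,
                            overlap = 0.5, max_gap_ms = 100) {
  labels <- as.integer(labels)
  nT <- length(labels)
  song <- labels %in% c(1L, 2L)
  # gaps strictly shorter than max_gap_ms are bridged into one bout
  gap <- max(1L, ceiling(max_gap_ms / 1000 * frame_rate))
  bridged <- smooth_bouts(song, 1L, gap)
  b <- logical_bouts(bridged)
  bouts <- data.frame(onset_s = (b$start - 1) / frame_rate,
                      offset_s = b$end / frame_rate,
                      order = NA_integer_, n_segments = NA_integer_)
  for (i in seq_len(nrow(b))) {
    seg <- labels[b$start[i]:b$end[i]]
    seg <- seg[seg %in% c(1L, 2L)]
    modes <- rle(seg)$values
    bouts$order[i] <- length(modes)
    bouts$n_segments[i] <- length(modes)
  }

  w <- round(window * frame_rate)
  if (w > nT) {
    warning("window longer than trial; using a single truncated window")
    w <- nT
  }
  step <- max(1L, round(w * (1 - overlap)))
  starts <- seq(1, max(1, nT - w + 1), by = step)
  win_stats <- function(mask) {
    t(vapply(starts, function(s) {
      m <- mask[s:(s + w - 1)]
      amount <- mean(m)
      onsets <- sum(diff(c(FALSE, m)) == 1)
      c(amount = amount, onsets = onsets,
        duration = if (onsets > 0) amount / onsets else NA_real_)
    }, numeric(3)))
  }
  modes <- list(pulse = labels == 1L, sine = labels == 2L, all = song)
  windowed <- lapply(modes, win_stats)
  summary <- t(vapply(windowed, function(m)
    c(amount = mean(m[, "amount"]), onsets = mean(m[, "onsets"]),
      duration = mean(m[, "duration"], na.rm = TRUE)), numeric(3)))
  list(bouts = bouts, windowed = windowed, summary = summary)
}

#' Cluster pulse waveforms into fast and slow types
#'
#' Normalizes waveforms (unit peak, positive principal polarity), embeds
#' them in 2-D, finds density modes by kernel-density + watershed
#' segmentation of the embedding, keeps the two largest clusters, names them
#' by envelope width (shorter envelope = `P_fast`), and labels the remaining
#' waveforms with a support-vector classifier trained on the two clusters.
#'
#' @param waveforms matrix, one snippet per row (flagged pulses should be
#'   removed first).
#' @param fs sampling rate (default 10000).
#' @param seed embedding seed.
#' @param min_n minimum number of waveforms (default 20).
#' @return list with `labels` (`"P_fast"`/`"P_slow"`), `embedding`,
#'   `cluster_id`, `fallback` (TRUE when fewer than two density clusters
#'   were found and all pulses were assigned to one type).
#' @export
cluster_pulse_types <- function(waveforms, fs = 10000, seed = 1, min_n = 20) {
  if (nrow(waveforms) < min_n)
    stop(sprintf("need at least %d waveforms", min_n))
  W <- t(apply(waveforms, 1, function(w) {
    w <- w - mean(w)
    pk <- max(abs(w))
    if (pk > 0) w <- w / pk
    if (abs(min(w)) > abs(max(w))) w <- -w  # fixed polarity
    w
  }))
  emb <- embed_umap(W, seed = seed,
                    n_neighbors = min(15, nrow(W) - 1))$embedding
  seg <- density_watershed(emb, grid_n = 128)
  cl <- seg$point_labels
  sizes <- sort(table(cl[cl > 0]), decreasing = TRUE)

  env_width <- function(rows) {
    if (length(rows) == 0) return(NA_real_)
    mean(pulse_metrics(W[rows, , drop = FALSE], fs = fs)$width_ms)
  }
  if (length(sizes) < 2) {
    warning("fewer than two clusters found; assigning all pulses to one type")
    return(list(labels = rep("P_fast", nrow(W)), embedding = emb,
                cluster_id = cl, fallback = TRUE))
  }
  top2 <- as.integer(names(sizes)[1:2])
  w1 <- env_width(which(cl == top2[1])); w2 <- env_width(which(cl == top2[2]))
  fast_cl <- if (w1 <= w2) top2[1] else top2[2]
  labels <- rep(NA_character_, nrow(W))
  labels[cl == top2[1]] <- if (fast_cl == top2[1]) "P_fast" else "P_slow"
  labels[cl == top2[2]] <- if (fast_cl == top2[2]) "P_fast" else "P_slow"

  rest <- which(is.na(labels))
  if (length(rest) > 0) {
    train <- which(!is.na(labels))
    fit <- e1071::svm(x = emb[train, , drop = FALSE],
                      y = factor(labels[train]), kernel = "radial")
    labels[rest] <- as.character(predict(fit, emb[rest, , drop = FALSE]))
  }
  list(labels = labels, embedding = emb, cluster_id = cl, fallback = FALSE)
}

#' Resolve conflicting song types during mutual singing
#'
#' When both flies sing simultaneously with differing types, the courter's
#' frames take the type he was producing immediately before the onset of
#' the mutual-singing epoch.
#'
#' @param courter_labels,partner_labels aligned integer label vectors
#'   (1 pulse, 2 sine, 3 silence).
#' @return resolved courter label vector.
#' @export
attribute_mutual_song <- function(courter_labels, partner_labels) {
  stopifnot(length(courter_labels) == length(partner_labels))
  y <- as.integer(courter_labels); p <- as.integer(partner_labels)
  conflict <- y %in% 1:2 & p %in% 1:2 & y != p
  b <- logical_bouts(conflict)
  for (i in seq_len(nrow(b))) {
    # last courter song type before the mutual epoch started
    prior <- y[seq_len(b$start[i] - 1)]
    prior <- prior[prior %in% 1:2]
    if (length(prior) > 0) y[b$start[i]:b$end[i]] <- prior[length(prior)]
  }
  y
}
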
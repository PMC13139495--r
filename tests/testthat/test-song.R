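make_pulse_snippet <- function(carrier_hz = 250, width_ms = 4, fs = 10000,
                               amp = 1, noise = 0) {
  n <- 350
  t <- ((seq_len(n) - 1) - (n - 1) / 2) / fs
  sigma <- width_ms / 1000 / (2 * sqrt(2 * log(2)))
  amp * exp(-t^2 / (2 * sigma^2)) * cos(2 * pi * carrier_hz * t) +
    rnorm(n, 0, noise)
}

test_that("pulse carrier frequency is recovered within FFT bin resolution", {
  w <- make_pulse_snippet(carrier_hz = 250)
  pm <- pulse_metrics(rbind(w))
  expect_lt(abs(pm$carrier_hz - 250), 10000 / 350 + 1e-9)
  expect_false(pm$noisy)
  expect_false(pm$multi_peak)
  expect_error(pulse_metrics(matrix(w[1:100], 1)), "samples")
})

test_that("pulse width matches the analytic smoothing-broadened value and scale invariance", {
  # Gaussian envelope of FWHM w convolved with the 1.5 ms smoothing kernel
  # stays Gaussian with FWHM sqrt(w^2 + (2.355 * 1.5)^2)
  for (width in c(4, 8)) {
    w <- make_pulse_snippet(width_ms = width, carrier_hz = 400)
    pm <- pulse_metrics(rbind(w))
    fwhm_smooth <- 2 * sqrt(2 * log(2)) * 1.5
    expected <- sqrt(width^2 + fwhm_smooth^2)
    expect_equal(pm$width_ms, expected, tolerance = 0.15)
  }
  pm1 <- pulse_metrics(rbind(make_pulse_snippet()))
  pm2 <- pulse_metrics(rbind(100 * make_pulse_snippet()))
  expect_equal(pm1$width_ms, pm2$width_ms, tolerance = 1e-9)
})

test_that("noisy and multi-peak pulses are flagged", {
  set.seed(2)
  t <- (0:349) / 10000
  flat <- cos(2 * pi * 300 * t) + rnorm(350, 0, 0.01)  # near-flat envelope
  pm <- pulse_metrics(rbind(flat))
  expect_true(pm$noisy)

  hump <- make_pulse_snippet(width_ms = 3) +
    c(rep(0, 100), make_pulse_snippet(width_ms = 3))[1:350]
  pm2 <- pulse_metrics(rbind(hump))
  expect_true(pm2$multi_peak)
})

test_that("inter-pulse intervals drop bout breaks and degenerate inputs", {
  centers <- seq(0, by = 0.036, length.out = 20)
  expect_equal(interpulse_intervals(centers), rep(36, 19), tolerance = 1e-9)
  expect_length(interpulse_intervals(c(0, 0.150)), 0)
  expect_length(interpulse_intervals(0.5), 0)
  mixed <- c(0, 0.036, 0.072, 0.5, 0.536)
  expect_equal(interpulse_intervals(mixed), rep(36, 3), tolerance = 1e-9)
  # translation invariance
  expect_equal(interpulse_intervals(mixed + 17.3),
               interpulse_intervals(mixed), tolerance = 1e-9)
})

test_that("sine carrier is the modal segment frequency", {
  fs <- 10000
  t <- (0:(fs - 1)) / fs
  tone <- sin(2 * pi * 150 * t)
  iv <- data.frame(onset_s = 0, offset_s = 1)
  expect_lt(abs(sine_carrier(tone, iv) - 150), fs / 256 + 1e-9)

  # 150 Hz for 0.7 s then 200 Hz for 0.3 s: mode is 150
  tone2 <- c(sin(2 * pi * 150 * t[1:7000]), sin(2 * pi * 200 * t[1:3000]))
  expect_lt(abs(sine_carrier(tone2, iv) - 150), fs / 256 + 1e-9)

  expect_true(is.na(sine_carrier(tone, iv[0, ])))
  expect_warning(sine_carrier(tone, data.frame(onset_s = 0, offset_s = 0.01)),
                 "skipped")
})

test_that("bout building follows the 100 ms gap rule and orders count transitions", {
  fr <- 30
  lab <- function(...) as.integer(c(...))
  # pulse-only bout
  b1 <- bout_statistics(lab(rep(3, 30), rep(1, 30), rep(3, 30)),
                        frame_rate = fr, window = 3)
  expect_equal(nrow(b1$bouts), 1L)
  expect_equal(b1$bouts$order, 1L)

  # pulse then sine with a ~50 ms gap: one bout of order two
  b2 <- bout_statistics(lab(rep(3, 30), rep(1, 15), 3, rep(2, 15), rep(3, 30)),
                        frame_rate = fr, window = 3)
  expect_equal(nrow(b2$bouts), 1L)
  expect_equal(b2$bouts$order, 2L)

  # two pulse trains separated by 150 ms: two bouts
  b3 <- bout_statistics(lab(rep(1, 15), rep(3, 5), rep(1, 15)),
                        frame_rate = fr, window = 1)
  expect_equal(nrow(b3$bouts), 2L)

  # partition property: every song frame lies in exactly one bout
  set.seed(6)
  y <- sample(c(1L, 2L, 3L), 600, replace = TRUE, prob = c(0.3, 0.3, 0.4))
  bs <- suppressWarnings(bout_statistics(y, frame_rate = fr, window = 30))
  covered <- rep(0, length(y))
  for (i in seq_len(nrow(bs$bouts))) {
    idx <- (round(bs$bouts$onset_s[i] * fr) + 1):round(bs$bouts$offset_s[i] * fr)
    covered[idx] <- covered[idx] + 1
  }
  expect_true(all(covered[y %in% c(1L, 2L)] == 1))
  expect_true(all(covered <= 1))
})

test_that("windowed amounts, onsets and durations satisfy their identity", {
  set.seed(7)
  y <- sample(c(1L, 2L, 3L), 5400, replace = TRUE, prob = c(0.2, 0.2, 0.6))
  bs <- bout_statistics(y, frame_rate = 30, window = 60, overlap = 0.5)
  for (mode in names(bs$windowed)) {
    w <- bs$windowed[[mode]]
    expect_true(all(w[, "amount"] >= 0 & w[, "amount"] <= 1))
    ok <- w[, "onsets"] > 0
    expect_equal(w[ok, "duration"] * w[ok, "onsets"], w[ok, "amount"],
                 tolerance = 1e-12)
  }
  expect_warning(bout_statistics(y[1:100], frame_rate = 30, window = 60),
                 "truncated")
})

test_that("pulse-type clustering separates two waveform families", {
  set.seed(13)
  n_per <- 40
  fam_a <- t(replicate(n_per, make_pulse_snippet(width_ms = 3,
                                                 carrier_hz = 350,
                                                 noise = 0.02)))
  fam_b <- t(replicate(n_per, make_pulse_snippet(width_ms = 10,
                                                 carrier_hz = 180,
                                                 noise = 0.02)))
  W <- rbind(fam_a, fam_b)
  truth <- rep(c("P_fast", "P_slow"), each = n_per)
  cl <- cluster_pulse_types(W, seed = 3)
  expect_false(cl$fallback)
  expect_true(all(!is.na(cl$labels)))
  expect_gte(mean(cl$labels == truth), 0.99)
})

test_that("identical waveforms fall back to a single pulse type", {
  W <- matrix(rep(make_pulse_snippet(), 25), 25, byrow = TRUE)
  cl <- suppressWarnings(cluster_pulse_types(W, seed = 1))
  expect_true(cl$fallback || length(unique(cl$labels)) == 1)
  expect_error(cluster_pulse_types(W[1:5, ]), "at least")
})

test_that("mutual-song conflicts resolve to the courter's preceding type", {
  court <- c(3L, 2L, 2L, 1L, 1L, 3L)
  part <- c(3L, 3L, 3L, 2L, 2L, 3L)
  # frames 4-5 conflict (courter pulse vs partner sine); he sang sine before
  expect_equal(attribute_mutual_song(court, part),
               c(3L, 2L, 2L, 2L, 2L, 3L))
  # no overlap or identical types: unchanged
  expect_equal(attribute_mutual_song(court, rep(3L, 6)), court)
  expect_equal(attribute_mutual_song(court, court), court)
})
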
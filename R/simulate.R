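#' Default synthetic-study configuration
#'
#' Fixes the conditions every synthetic dataset is generated under: the
#' stationary moments and correlation timescales of the 10 feedback
#' features (30 Hz), the ground-truth 3-state model (sticky transitions;
#' silence-, pulse- and sine-biased emissions with filters loading on
#' distance and lateral speed), the scripted pose scenarios, and the audio
#' parameters (250 Hz pulse carrier, 4 ms pulse width, 36 ms IPI, 150 Hz
#' sine carrier).
#'
#' @param n_basis raised-cosine basis count used by the generative model.
#' @param n_lags lag-history length (default 120 = 4 s at 30 Hz).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_basis = 10, n_lags = 120) {
  features <- data.frame(
    name = c("cFV", "pFV", "cLS", "pLS", "cRS", "pRS", "dis",
             "ctheta", "ptheta", "phi"),
    mean = c(5, 2, 0, 0, 0, 0, 5, 90, 45, 0),
    sd   = c(4, 3, 3, 2, 60, 50, 3, 50, 40, 60),
    tau  = c(0.5, 0.5, 0.3, 0.3, 0.3, 0.3, 1.0, 0.8, 0.8, 0.8),
    transform = c("none", "none", "abs", "abs", "abs", "abs", "abs",
                  "fold180", "fold180", "wrap180"),
    stringsAsFactors = FALSE)
  list(frame_rate = 30,
       features = features,
       n_basis = n_basis, n_lags = n_lags,
       sticky = 0.97,
       audio = list(fs = 10000, pulse_carrier_hz = 250, pulse_width_ms = 4,
                    ipi_ms = 36, sine_carrier_hz = 150, noise_sd = 0.01,
                    n_amplitude_steps = 10, step_duration_s = 30))
}

#' Ground-truth HMM-GLM used by the synthetic generator
#'
#' Three states: `whatever` (silence-biased, cue-independent), `chasing`
#' (pulse-biased, driven positively by courter lateral speed and negatively
#' by distance) and `close` (sine-biased, driven by proximity). Filters act
#' on the z-scored basis-projected design, weights on the first
#' (short-latency) basis function of the relevant feature block.
#'
#' @param config a `synthetic_config`.
#' @return `hmmglm_params` with `P = 10 * n_basis + 1`.
#' @export
default_ground_truth <- function(config = synthetic_config()) {
  D <- config$n_basis
  P <- 10 * D + 1
  col1 <- function(feature) (match(feature, config$features$name) - 1) * D + 1
  w <- function(pulse_bias, sine_bias, pulse_w = NULL, sine_w = NULL) {
    W <- matrix(0, 3, P)
    W[1, P] <- pulse_bias; W[2, P] <- sine_bias
    for (nm in names(pulse_w)) W[1, col1(nm)] <- pulse_w[[nm]]
    for (nm in names(sine_w)) W[2, col1(nm)] <- sine_w[[nm]]
    W
  }
  W <- list(
    whatever = w(-2.5, -2.5),
    chasing  = w(1.2, -1.0, pulse_w = list(cLS = 0.8, dis = -0.6)),
    close    = w(-1.0, 1.2, sine_w = list(dis = -0.8, cLS = -0.4)))
  s <- config$sticky
  alpha <- matrix((1 - s) / 2, 3, 3); diag(alpha) <- s
  hmmglm_params(rep(1 / 3, 3), alpha, W)
}

ou_series <- function(n, mean, sd, tau, dt) {
  a <- exp(-dt / tau)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, mean, sd)
  innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - a^2))
  for (t in 2:n) x[t] <- mean + a * (x[t - 1] - mean) + innov[t - 1]
  x
}

fold180 <- function(x) {
  x <- x %% 360
  ifelse(x > 180, 360 - x, x)
}

#' Simulate the 10 feedback-feature time series
#'
#' Mean-reverting Gaussian (discretized Ornstein-Uhlenbeck) processes at
#' 30 Hz with the configured stationary moments and correlation timescales.
#' Magnitude features (speeds, distance) take absolute values; the relative
#' angles are folded into [0, 180] and `phi` wrapped to [-180, 180].
#'
#' @param config a `synthetic_config`.
#' @param n_frames number of 30 Hz frames.
#' @param seed RNG seed.
#' @return T x 10 named feature matrix.
#' @export
simulate_features <- function(config = synthetic_config(), n_frames, seed = 1) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  set.seed(seed)
  dt <- 1 / config$frame_rate
  fs <- config$features
  out <- matrix(0, n_frames, nrow(fs), dimnames = list(NULL, fs$name))
  for (i in seq_len(nrow(fs))) {
    x <- ou_series(n_frames, fs$mean[i], fs$sd[i], fs$tau[i], dt)
    out[, i] <- switch(fs$transform[i],
                       none = x,
                       abs = abs(x),
                       fold180 = fold180(x),
                       wrap180 = ((x + 180) %% 360) - 180)
  }
  out
}

#' Sample hidden states and song labels from a generative HMM-GLM
#'
#' Draws the state path from the initial distribution and transition
#' matrix, builds the basis-projected design from the features (z-scored on
#' themselves unless `stats` is supplied), and samples each frame's song
#' mode from the active state's softmax emission model.
#'
#' @param params generative `hmmglm_params`.
#' @param features T x 10 feature matrix.
#' @param basis `rc_basis` matching `params$P`.
#' @param seed RNG seed.
#' @param stats optional frozen design statistics.
#' @return list with `z` (states), `y` (labels), `X` (design), `stats`.
#' @export
simulate_song <- function(params, features, basis, seed = 1, stats = NULL) {
  d <- build_design(features, basis, stats)
  nT <- nrow(d$X); K <- params$K
  set.seed(seed)
  z <- integer(nT)
  z[1] <- sample.int(K, 1, prob = params$pi)
  if (nT > 1) for (t in 2:nT)
    z[t] <- sample.int(K, 1, prob = params$alpha[z[t - 1], ])
  y <- integer(nT)
  for (k in seq_len(K)) {
    idx <- which(z == k)
    if (length(idx) == 0) next
    Pk <- emission_probs(params$W[[k]], d$X[idx, , drop = FALSE])
    if (is.null(dim(Pk))) Pk <- matrix(Pk, nrow = 1)
    u <- stats::runif(length(idx))
    cum <- t(apply(Pk, 1, cumsum))
    y[idx] <- 1L + rowSums(u > cum[, -params$M, drop = FALSE])
  }
  list(z = z, y = y, X = d$X, stats = d$stats, features = features)
}

# 6-keypoint skeleton from thorax positions, headings (rad), wing angles (deg)
make_skeleton <- function(pos, ang, wing_left = 8, wing_right = 8,
                          fly_length = 2.5) {
  nT <- nrow(pos)
  if (length(wing_left) == 1) wing_left <- rep(wing_left, nT)
  if (length(wing_right) == 1) wing_right <- rep(wing_right, nT)
  ux <- cos(ang); uy <- sin(ang)
  half <- fly_length / 2
  a <- array(NA_real_, c(nT, 6, 2))
  a[, 1, ] <- pos + half * cbind(ux, uy)            # head
  a[, 2, ] <- pos + 0.25 * fly_length * cbind(ux, uy)  # neck
  a[, 3, ] <- pos                                   # thorax
  a[, 4, ] <- pos - half * cbind(ux, uy)            # abdomen
  wl <- (180 - wing_left) * pi / 180                # folded wings point back
  wr <- (180 + wing_right) * pi / 180
  a[, 5, ] <- pos + 0.9 * cbind(cos(ang + wl), sin(ang + wl))
  a[, 6, ] <- pos + 0.9 * cbind(cos(ang + wr), sin(ang + wr))
  a
}

#' Scripted two-fly pose scenarios with ground truth
#'
#' `male_turns`: the courter follows 4 mm behind the walking partner (a
#' tail interaction); halfway through, the partner executes a rapid 180
#' degree turn toward the courter, converting the interaction to a head
#' interaction. The ground truth records the moment the courter crosses
#' into the partner's head quadrant.
#'
#' `female_slows`: the partner walks and slows markedly during scripted
#' song epochs while the courter follows behind and, in song epochs,
#' extends a wing; ground truth records the song epochs and scripted
#' speeds.
#'
#' @param scenario `"male_turns"` or `"female_slows"`.
#' @param duration trial length in seconds (default 12).
#' @param seed RNG seed for small positional jitter.
#' @param frame_rate output rate (default 30).
#' @param jitter_sd positional noise sd in mm (default 0.01).
#' @return list with `pose` (`pose_pair`, fly 0 = courter) and `truth`.
#' @export
simulate_pose_scenario <- function(scenario = c("male_turns", "female_slows"),
                                   duration = 12, seed = 1, frame_rate = 30,
                                   jitter_sd = 0.01) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  nT <- round(duration * frame_rate) + 1
  tt <- (seq_len(nT) - 1) / frame_rate

  if (scenario == "male_turns") {
    v <- 3                     # partner walking speed, mm/s
    t_turn <- duration / 2
    turn_dur <- 0.3
    px <- ifelse(tt < t_turn, v * tt, v * t_turn)   # partner stops to turn
    py <- rep(0, nT)
    pang <- ifelse(tt < t_turn, 0,
                   pmin((tt - t_turn) / turn_dur, 1) * pi)
    cx <- px - 4               # courter 4 mm behind, facing the partner
    cy <- rep(0, nT)
    cang <- rep(0, nT)
    # cθ crosses 90° when the partner's heading has swept a quarter turn
    truth <- list(transition_time = t_turn + turn_dur / 2,
                  partner_speed = v)
    partner <- make_skeleton(cbind(px, py), pang)
    courter <- make_skeleton(cbind(cx, cy), cang)
  } else {
    v_fast <- 8; v_slow <- 2
    epoch <- 3                 # song epochs alternate every 3 s, song first off
    song_on <- (tt %/% epoch) %% 2 == 1
    speed <- ifelse(song_on, v_slow, v_fast)
    px <- cumsum(speed / frame_rate); px <- px - px[1]
    py <- rep(0, nT)
    pang <- rep(0, nT)
    cx <- px - 3.5
    cy <- rep(0, nT)
    cang <- rep(0, nT)
    wingL <- ifelse(song_on, 50, 8)
    truth <- list(song_epochs = song_on, v_fast = v_fast, v_slow = v_slow,
                  epoch_s = epoch)
    partner <- make_skeleton(cbind(px, py), pang)
    courter <- make_skeleton(cbind(cx, cy), cang, wing_left = wingL)
  }
  courter[, , 1] <- courter[, , 1] + stats::rnorm(length(courter[, , 1]), 0, jitter_sd)
  courter[, , 2] <- courter[, , 2] + stats::rnorm(length(courter[, , 2]), 0, jitter_sd)
  partner[, , 1] <- partner[, , 1] + stats::rnorm(length(partner[, , 1]), 0, jitter_sd)
  partner[, , 2] <- partner[, , 2] + stats::rnorm(length(partner[, , 2]), 0, jitter_sd)
  list(pose = pose_pair(tt, courter, partner, frame_rate),
       truth = truth, scenario = scenario)
}

gaussian_pulse <- function(fs, carrier_hz, width_ms, amp = 1) {
  # width = full width of the envelope at half its maximum
  sigma <- width_ms / 1000 / (2 * sqrt(2 * log(2)))
  half <- ceiling(4 * sigma * fs)
  t <- (-half:half) / fs
  amp * exp(-t^2 / (2 * sigma^2)) * cos(2 * pi * carrier_hz * t)
}

#' Synthesize audio from a song annotation
#'
#' Pulse-labelled spans receive trains of carrier-modulated Gaussian pulses
#' at the configured IPI; sine spans receive a pure tone; everything rides
#' on a Gaussian noise floor.
#'
#' @param labels integer per-frame labels at 30 Hz (1 pulse, 2 sine,
#'   3 silence).
#' @param config a `synthetic_config` (audio parameters).
#' @param seed noise seed.
#' @return list with `waveform`, `fs`, `pulse_centers` (seconds).
#' @export
synth_audio <- function(labels, config = synthetic_config(), seed = 1) {
  au <- config$audio
  fs <- au$fs
  frame_rate <- config$frame_rate
  n <- ceiling(length(labels) / frame_rate * fs)
  set.seed(seed)
  w <- stats::rnorm(n, 0, au$noise_sd)
  pc <- numeric(0)
  spans <- function(mode) logical_bouts(labels == mode)
  ps <- spans(1L)
  for (i in seq_len(nrow(ps))) {
    t0 <- (ps$start[i] - 1) / frame_rate; t1 <- ps$end[i] / frame_rate
    centers <- seq(t0 + au$ipi_ms / 2000, t1, by = au$ipi_ms / 1000)
    for (ct in centers) {
      p <- gaussian_pulse(fs, au$pulse_carrier_hz, au$pulse_width_ms)
      ci <- round(ct * fs)
      idx <- (ci - (length(p) - 1) %/% 2):(ci + (length(p) - 1) %/% 2)
      ok <- idx >= 1 & idx <= n
      w[idx[ok]] <- w[idx[ok]] + p[ok]
      pc <- c(pc, ct)
    }
  }
  ss <- spans(2L)
  for (i in seq_len(nrow(ss))) {
    i0 <- round((ss$start[i] - 1) / frame_rate * fs) + 1
    i1 <- min(n, round(ss$end[i] / frame_rate * fs))
    t <- (i0:i1) / fs
    w[i0:i1] <- w[i0:i1] + sin(2 * pi * au$sine_carrier_hz * t)
  }
  list(waveform = w, fs = fs, pulse_centers = pc)
}

#' Artificial pulse-song playback stimulus
#'
#' A regular train of 4 ms-wide, 250 Hz carrier pulses at a 36 ms
#' inter-pulse interval, played at `n_amplitude_steps` increasing
#' amplitudes, each held for `step_duration_s`.
#'
#' @param config a `synthetic_config`.
#' @param step_duration_s override the per-amplitude duration (seconds).
#' @return list with `waveform`, `fs`, `pulse_centers`, `amplitudes`,
#'   `step_onsets_s`.
#' @export
playback_stimulus <- function(config = synthetic_config(),
                              step_duration_s = NULL) {
  au <- config$audio
  if (is.null(step_duration_s)) step_duration_s <- au$step_duration_s
  fs <- au$fs
  n_steps <- au$n_amplitude_steps
  amps <- seq(1 / n_steps, 1, length.out = n_steps)
  total <- n_steps * step_duration_s
  n <- round(total * fs)
  w <- numeric(n)
  centers <- seq(au$ipi_ms / 2000, total, by = au$ipi_ms / 1000)
  p1 <- gaussian_pulse(fs, au$pulse_carrier_hz, au$pulse_width_ms)
  half <- (length(p1) - 1) %/% 2
  for (ct in centers) {
    amp <- amps[pmin(floor(ct / step_duration_s) + 1, n_steps)]
    ci <- round(ct * fs)
    idx <- (ci - half):(ci + half)
    ok <- idx >= 1 & idx <= n
    w[idx[ok]] <- w[idx[ok]] + amp * p1[ok]
  }
  list(waveform = w, fs = fs, pulse_centers = centers, amplitudes = amps,
       step_onsets_s = (seq_len(n_steps) - 1) * step_duration_s)
}
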
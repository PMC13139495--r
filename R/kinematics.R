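BODY_PARTS <- c("head", "neck", "thorax", "abdomen", "left_wingtip", "right_wingtip")

#' Two-fly pose track container
#'
#' @param time strictly increasing frame times in seconds.
#' @param fly0,fly1 numeric arrays `T x 6 x 2` (frames x body parts x x/y),
#'   coordinates in mm; body parts in the order head, neck, thorax, abdomen,
#'   left_wingtip, right_wingtip. `NA` marks missing keypoints.
#' @param frame_rate sampling rate in Hz.
#' @return object of class `pose_pair`.
#' @export
pose_pair <- function(time, fly0, fly1, frame_rate) {
  stopifnot(length(dim(fly0)) == 3, length(dim(fly1)) == 3,
            dim(fly0)[2] == 6, dim(fly1)[2] == 6,
            dim(fly0)[3] == 2, dim(fly1)[3] == 2)
  if (dim(fly0)[1] != length(time) || dim(fly1)[1] != length(time))
    stop("frame counts differ between time axis and coordinate arrays")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  dimnames(fly0) <- dimnames(fly1) <- list(NULL, BODY_PARTS, c("x", "y"))
  structure(list(time = time, flies = list(fly0, fly1),
                 frame_rate = frame_rate),
            class = "pose_pair")
}

#' @export
print.pose_pair <- function(x, ...) {
  cat(sprintf("pose_pair: %d frames at %g Hz (%.1f s)\n",
              length(x$time), x$frame_rate, diff(range(x$time))))
  invisible(x)
}

#' Read a two-fly pose table (long CSV: frame, fly, bodypart, x, y)
#'
#' @param path CSV path.
#' @param mm_per_px calibration factor applied to x/y.
#' @param frame_rate acquisition rate in Hz.
#' @return a `pose_pair`.
#' @export
read_pose_csv <- function(path, mm_per_px = 1, frame_rate = 100) {
  df <- utils::read.csv(path)
  need <- c("frame", "fly", "bodypart", "x", "y")
  if (!all(need %in% names(df))) stop("pose CSV must have columns ", paste(need, collapse = ", "))
  frames <- sort(unique(df$frame))
  arr <- function(id) {
    a <- array(NA_real_, c(length(frames), 6, 2))
    sub <- df[df$fly == id, ]
    fi <- match(sub$frame, frames); pi_ <- match(sub$bodypart, BODY_PARTS)
    a[cbind(fi, pi_, 1)] <- sub$x * mm_per_px
    a[cbind(fi, pi_, 2)] <- sub$y * mm_per_px
    a
  }
  pose_pair((frames - frames[1]) / frame_rate, arr(0), arr(1), frame_rate)
}

#' Write a pose_pair back to the long CSV format
#' @param pose a `pose_pair`.
#' @param path output path.
#' @export
write_pose_csv <- function(pose, path) {
  rows <- do.call(rbind, lapply(0:1, function(id) {
    a <- pose$flies[[id + 1]]
    do.call(rbind, lapply(seq_along(BODY_PARTS), function(p)
      data.frame(frame = seq_along(pose$time) - 1L, fly = id,
                 bodypart = BODY_PARTS[p], x = a[, p, 1], y = a[, p, 2])))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
}

# centred finite-difference gradient, one-sided at the ends
fd_gradient <- function(x, dt) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  g <- numeric(n)
  g[1] <- (x[2] - x[1]) / dt
  g[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  g
}

# unwrap a radian angle series (remove 2*pi jumps)
unwrap_angle <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(a[1], a[1] + cumsum(d))
}

# linear interpolation of short NA gaps; returns values + logical valid mask
interp_gaps <- function(x, max_gap) {
  if (!anyNA(x)) return(list(x = x, valid = rep(TRUE, length(x))))
  idx <- which(!is.na(x))
  if (length(idx) < 2) stop("too few valid samples to interpolate keypoints")
  filled <- stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
  valid <- rep(TRUE, length(x))
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (i in which(r$values & r$lengths > max_gap))
    valid[starts[i]:ends[i]] <- FALSE
  list(x = filled, valid = valid)
}

# anti-aliased resampling of one channel from rate_in to rate_out
resample_channel <- function(x, time_in, time_out, rate_in, rate_out) {
  if (rate_out < rate_in) {
    bf <- signal::butter(4, 0.8 * rate_out / rate_in, type = "low")
    x <- signal::filtfilt(bf, x)
  }
  stats::approx(time_in, x, xout = time_out, rule = 2)$y
}

#' Kinematic feedback features from a two-fly pose track
#'
#' Downsamples the pose to `target_rate` (low-pass filtering before
#' decimation), then derives the 10 feedback features: signed forward
#' velocity along the head-abdomen body axis (`cFV`, `pFV`, mm/s), lateral
#' speed (`cLS`, `pLS`, magnitudes), rotational speed of the unwrapped body
#' angle (`cRS`, `pRS`, deg/s), thorax-thorax distance (`dis`, mm), the
#' relative angles `ctheta` (courter position in the partner's frame) and
#' `ptheta` (partner direction in the courter's frame, both deg in
#' [0, 180]), and the body-angle difference `phi` (deg). Missing keypoints
#' are linearly interpolated up to `max_gap_s`; longer gaps mark frames
#' invalid (column `valid`).
#'
#' @param pose a `pose_pair`.
#' @param target_rate output rate in Hz (default 30).
#' @param courter which fly (0/1) is treated as the courter for the c/p
#'   naming; [assign_roles()] works from the symmetric columns.
#' @param max_gap_s keypoint interpolation budget in seconds (default 0.2).
#' @return data.frame with `t`, the 10 features, symmetric helper columns
#'   `theta0`, `theta1`, `body_angle0`, `body_angle1`, and `valid`;
#'   attributes `frame_rate`, `fly_length` (per fly, median head-abdomen
#'   distance), `courter`.
#' @export
compute_features <- function(pose, target_rate = 30, courter = 0L,
                             max_gap_s = 0.2) {
  stopifnot(inherits(pose, "pose_pair"))
  if (length(pose$time) < 2) stop("pose track too short (need >= 2 frames)")
  max_gap <- max(1L, round(max_gap_s * pose$frame_rate))

  dur <- pose$time[length(pose$time)]
  time_out <- seq(pose$time[1], dur, by = 1 / target_rate)
  nT <- length(time_out)
  if (nT < 2) stop("pose track too short at the target rate")

  valid <- rep(TRUE, nT)
  res <- lapply(1:2, function(fl) {
    a <- pose$flies[[fl]]
    out <- array(NA_real_, c(nT, 6, 2))
    for (p in 1:6) for (d in 1:2) {
      ig <- interp_gaps(a[, p, d], max_gap)
      if (p %in% c(1, 3, 4) && !all(ig$valid)) {
        vr <- stats::approx(pose$time, as.numeric(ig$valid), xout = time_out,
                            method = "constant", rule = 2)$y
        valid <<- valid & (vr > 0.5)
      }
      out[, p, d] <- resample_channel(ig$x, pose$time, time_out,
                                      pose$frame_rate, target_rate)
    }
    out
  })
  if (mean(valid) < 0.5)
    stop("more than half of the frames miss head/thorax/abdomen keypoints beyond the interpolation budget")

  dt <- 1 / target_rate
  per_fly <- lapply(res, function(a) {
    thx <- a[, 3, 1]; thy <- a[, 3, 2]
    axx <- a[, 1, 1] - a[, 4, 1]; axy <- a[, 1, 2] - a[, 4, 2]
    ang <- unwrap_angle(atan2(axy, axx))
    ux <- cos(ang); uy <- sin(ang)
    vx <- fd_gradient(thx, dt); vy <- fd_gradient(thy, dt)
    list(thx = thx, thy = thy, ang = ang,
         fv = vx * ux + vy * uy,
         ls = abs(-vx * uy + vy * ux),
         rs = abs(fd_gradient(ang, dt)) * 180 / pi,
         fly_length = stats::median(sqrt(axx^2 + axy^2)))
  })

  dxv <- per_fly[[2]]$thx - per_fly[[1]]$thx
  dyv <- per_fly[[2]]$thy - per_fly[[1]]$thy
  dis <- sqrt(dxv^2 + dyv^2)
  # theta_i: angle between fly i's body axis and the line from fly i to the other
  ang_line0 <- atan2(dyv, dxv); ang_line1 <- atan2(-dyv, -dxv)
  wrap180 <- function(a) abs(((a + pi) %% (2 * pi)) - pi) * 180 / pi
  theta0 <- wrap180(per_fly[[1]]$ang - ang_line0)
  theta1 <- wrap180(per_fly[[2]]$ang - ang_line1)
  phi <- (((per_fly[[1]]$ang - per_fly[[2]]$ang) * 180 / pi + 180) %% 360) - 180
  if (courter == 1L) phi <- -phi

  ci <- courter + 1L; pi_ <- 2L - courter
  feats <- data.frame(
    t = time_out,
    cFV = per_fly[[ci]]$fv, pFV = per_fly[[pi_]]$fv,
    cLS = per_fly[[ci]]$ls, pLS = per_fly[[pi_]]$ls,
    cRS = per_fly[[ci]]$rs, pRS = per_fly[[pi_]]$rs,
    dis = dis,
    ctheta = if (courter == 0L) theta1 else theta0,
    ptheta = if (courter == 0L) theta0 else theta1,
    phi = phi,
    theta0 = theta0, theta1 = theta1,
    body_angle0 = per_fly[[1]]$ang * 180 / pi,
    body_angle1 = per_fly[[2]]$ang * 180 / pi,
    valid = valid)
  attr(feats, "frame_rate") <- target_rate
  attr(feats, "fly_length") <- c(per_fly[[1]]$fly_length, per_fly[[2]]$fly_length)
  attr(feats, "courter") <- courter
  feats
}

#' Extract the 10-column model feature matrix from a feature table
#' @param features output of [compute_features()] (or any data.frame with
#'   the 10 named columns).
#' @return numeric matrix `T x 10`.
#' @export
feature_matrix <- function(features) {
  cols <- c("cFV", "pFV", "cLS", "pLS", "cRS", "pRS", "dis",
            "ctheta", "ptheta", "phi")
  as.matrix(features[, cols])
}

#' Per-frame interaction mask and courter role assignment
#'
#' A fly qualifies as courter at a frame when the pair is closer than
#' `dist_max` and the other fly lies within `fov_deg` of its heading. When
#' both qualify (mutual facing) the previously assigned courter is retained;
#' at the first mutual frame the fly facing the partner more directly (the
#' smaller own angle) is chosen, ties to fly 0. The courter's position in
#' the partner's frame splits interactions into head (`ctheta < 90`) and
#' tail (`ctheta >= 90`) quadrants.
#'
#' @param features output of [compute_features()] (needs `theta0`, `theta1`,
#'   `dis`, `valid`).
#' @param dist_max interaction distance threshold, mm (default 8).
#' @param fov_deg field-of-view half-angle, degrees (default 60).
#' @return data.frame with `interacting`, `courter_id` (0/1 or NA),
#'   `head_quadrant`, `tail_quadrant`, `ctheta_courter`; attribute
#'   `frame_rate`.
#' @export
assign_roles <- function(features, dist_max = 8, fov_deg = 60) {
  nT <- nrow(features)
  q0 <- features$dis < dist_max & features$theta0 < fov_deg & features$valid
  q1 <- features$dis < dist_max & features$theta1 < fov_deg & features$valid
  interacting <- q0 | q1
  courter <- rep(NA_integer_, nT)
  last <- NA_integer_
  for (t in seq_len(nT)) {
    if (!interacting[t]) next
    if (q0[t] && q1[t]) {
      if (!is.na(last)) courter[t] <- last
      else if (features$theta0[t] < features$theta1[t]) courter[t] <- 0L
      else if (features$theta1[t] < features$theta0[t]) courter[t] <- 1L
      else courter[t] <- 0L
    } else courter[t] <- if (q0[t]) 0L else 1L
    last <- courter[t]
  }
  cth <- ifelse(is.na(courter), NA_real_,
                ifelse(courter == 0L, features$theta1, features$theta0))
  out <- data.frame(interacting = interacting, courter_id = courter,
                    head_quadrant = interacting & !is.na(cth) & cth < 90,
                    tail_quadrant = interacting & !is.na(cth) & cth >= 90,
                    ctheta_courter = cth)
  attr(out, "frame_rate") <- attr(features, "frame_rate")
  out
}

# run-length bouts of a logical vector: data.frame(start, end) frame indices
logical_bouts <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values %in% TRUE)
  data.frame(start = starts[keep], end = ends[keep])
}

# merge bouts whose gaps are < merge_gap frames, then drop bouts shorter
# than min_len frames; returns the smoothed logical mask
smooth_bouts <- function(x, min_len, merge_gap) {
  b <- logical_bouts(x)
  out <- rep(FALSE, length(x))
  if (nrow(b) == 0) return(out)
  merged <- b[1, , drop = FALSE]
  if (nrow(b) > 1) for (i in 2:nrow(b)) {
    if (b$start[i] - merged$end[nrow(merged)] - 1 < merge_gap)
      merged$end[nrow(merged)] <- b$end[i]
    else merged <- rbind(merged, b[i, ])
  }
  merged <- merged[merged$end - merged$start + 1 >= min_len, , drop = FALSE]
  for (i in seq_len(nrow(merged))) out[merged$start[i]:merged$end[i]] <- TRUE
  out
}

#' Head/tail quadrant occupancy during interactions
#'
#' Quadrant bouts separated by less than `min_bout` seconds are merged and
#' bouts shorter than `min_bout` are dropped (removing transients), then
#' `P(quadrant | interaction)` is the fraction of smoothed quadrant frames
#' among the interacting frames covered by either smoothed quadrant.
#'
#' @param mask output of [assign_roles()].
#' @param min_bout minimum bout length / merge gap in seconds (default 0.5).
#' @param frame_rate frames per second (taken from `mask` if absent).
#' @return list with `head`, `tail` fractions (summing to 1), frame counts,
#'   and `defined` (FALSE when there are no interacting frames).
#' @export
quadrant_probability <- function(mask, min_bout = 0.5,
                                 frame_rate = attr(mask, "frame_rate")) {
  if (is.null(frame_rate)) stop("frame_rate unknown")
  if (!any(mask$interacting))
    return(list(defined = FALSE, head = NA_real_, tail = NA_real_,
                n_interacting = 0L))
  k <- max(1L, round(min_bout * frame_rate))
  head_s <- smooth_bouts(mask$head_quadrant, k, k)
  tail_s <- smooth_bouts(mask$tail_quadrant, k, k)
  covered <- (head_s | tail_s) & mask$interacting
  denom <- sum(covered)
  if (denom == 0)
    return(list(defined = FALSE, head = NA_real_, tail = NA_real_,
                n_interacting = sum(mask$interacting)))
  nh <- sum(head_s & covered); nt <- sum(tail_s & covered)
  list(defined = TRUE, head = nh / denom, tail = nt / denom,
       n_head = nh, n_tail = nt, n_interacting = sum(mask$interacting))
}

#' Polar histogram of the courter's position around the partner
#'
#' Radial axis in partner fly lengths (15 equal bins up to 3 lengths,
#' farther frames excluded); angular axis |ctheta| in 36 bins of 5 degrees
#' (0 = partner's head, 180 = tail). Counts are normalized to a density
#' summing to 1.
#'
#' @param features feature table; `mask` from [assign_roles()].
#' @param mask interaction mask.
#' @param fly_length partner fly length in mm (default: from `features`
#'   attributes, fly 1's length when the courter is fly 0).
#' @param n_radial,max_lengths,ang_bin binning parameters.
#' @return list with `density` (15 x 36), bin edges, `n_used`.
#' @export
polar_occupancy <- function(features, mask, fly_length = NULL,
                            n_radial = 15, max_lengths = 3, ang_bin = 5) {
  if (is.null(fly_length)) {
    fl <- attr(features, "fly_length")
    if (is.null(fl)) stop("fly_length unknown")
    fly_length <- fl[2 - attr(features, "courter")]
  }
  use <- mask$interacting & !is.na(mask$ctheta_courter)
  r <- features$dis[use] / fly_length
  a <- mask$ctheta_courter[use]
  keep <- r <= max_lengths
  r <- r[keep]; a <- pmin(a[keep], 180 - 1e-9)
  ri <- pmin(pmax(ceiling(r / (max_lengths / n_radial)), 1L), n_radial)
  ai <- pmin(floor(a / ang_bin), 180 / ang_bin - 1) + 1L
  h <- matrix(0, n_radial, 180 / ang_bin)
  for (i in seq_along(r)) h[ri[i], ai[i]] <- h[ri[i], ai[i]] + 1
  d <- if (sum(h) > 0) h / sum(h) else h
  list(density = d,
       radial_edges = seq(0, max_lengths, length.out = n_radial + 1),
       angular_edges = seq(0, 180, by = ang_bin), n_used = length(r))
}

#' Detect tail-to-head interaction transitions
#'
#' An event is a tail-quadrant interaction epoch of at least `min_dur`
#' seconds followed (within `max_gap` seconds) by a head-quadrant epoch of
#' at least `min_dur` seconds; the event time is the first head frame.
#'
#' @param features feature table (for the time axis).
#' @param mask interaction mask from [assign_roles()].
#' @param min_dur minimum epoch duration, seconds (default 2).
#' @param max_gap tolerated gap between the epochs, seconds (default 0.5).
#' @return numeric vector of event times (seconds).
#' @export
detect_head_transitions <- function(features, mask, min_dur = 2,
                                    max_gap = 0.5) {
  fr <- attr(mask, "frame_rate")
  if (is.null(fr)) fr <- attr(features, "frame_rate")
  k <- round(min_dur * fr)
  tails <- logical_bouts(mask$tail_quadrant)
  heads <- logical_bouts(mask$head_quadrant)
  tails <- tails[tails$end - tails$start + 1 >= k, , drop = FALSE]
  heads <- heads[heads$end - heads$start + 1 >= k, , drop = FALSE]
  ev <- numeric(0)
  for (i in seq_len(nrow(tails))) {
    nxt <- heads[heads$start > tails$end[i] &
                   heads$start - tails$end[i] - 1 <= max_gap * fr, , drop = FALSE]
    if (nrow(nxt) > 0) ev <- c(ev, features$t[nxt$start[1]])
  }
  sort(unique(ev))
}

#' Wing-extension detection
#'
#' The wing angle is the angle between the head-thorax line and the
#' thorax-wingtip line. A bilateral extension (`bwe`) has both angles above
#' `bwe_threshold`; a unilateral extension (`uwe`) has exactly one wing
#' above the uwe threshold. When reference per-frame uwe labels are given,
#' the uwe threshold is chosen per trial as the angle maximizing frame
#' agreement with them (exhaustive sweep); otherwise `uwe_default` is used.
#'
#' @param pose a `pose_pair`.
#' @param fly which fly (0/1) to analyse.
#' @param reference_uwe_labels optional logical vector (one per pose frame).
#' @param uwe_default fallback uwe threshold, degrees (default 30).
#' @param bwe_threshold bilateral threshold, degrees (default 30).
#' @return list with `uwe`, `bwe` logical masks, `wing_angles` (T x 2,
#'   degrees), `uwe_threshold`.
#' @export
wing_extensions <- function(pose, fly = 0L, reference_uwe_labels = NULL,
                            uwe_default = 30, bwe_threshold = 30) {
  a <- pose$flies[[fly + 1L]]
  nT <- length(pose$time)
  if (!is.null(reference_uwe_labels) && length(reference_uwe_labels) != nT)
    stop("reference labels length does not match the pose track")
  hx <- a[, 1, 1] - a[, 3, 1]; hy <- a[, 1, 2] - a[, 3, 2]
  wang <- sapply(c(5, 6), function(p) {
    wx <- a[, p, 1] - a[, 3, 1]; wy <- a[, p, 2] - a[, 3, 2]
    # angle between the two (undirected) lines: 0 = wing folded along the body
    d <- abs(hx * wx + hy * wy) / (sqrt(hx^2 + hy^2) * sqrt(wx^2 + wy^2))
    acos(pmin(pmax(d, 0), 1)) * 180 / pi
  })
  uwe_at <- function(thr) (wang[, 1] > thr) != (wang[, 2] > thr)
  thr <- uwe_default
  if (!is.null(reference_uwe_labels)) {
    cand <- seq(1, 89, by = 1)
    agree <- vapply(cand, function(th)
      sum(uwe_at(th) == reference_uwe_labels), 0L)
    thr <- cand[which.max(agree)]
  }
  list(uwe = uwe_at(thr),
       bwe = wang[, 1] > bwe_threshold & wang[, 2] > bwe_threshold,
       wing_angles = wang, uwe_threshold = thr)
}

#' Song enrichment in windows preceding tail-to-head transitions
#'
#' Compares the per-window song probability in the `window_L` seconds before
#' each transition against `n_control` random windows whose endpoints lie at
#' least `control_margin` seconds from any transition. Windows whose
#' interaction ratio is below `min_interaction` are discarded in both sets.
#'
#' @param song logical per-frame song indicator (30 Hz).
#' @param interacting logical per-frame interaction indicator.
#' @param transitions transition times in seconds.
#' @param time frame time axis (seconds).
#' @param window_L window length, seconds.
#' @param n_control number of random control windows (default 100).
#' @param min_interaction minimum interaction ratio (default 0.25).
#' @param control_margin control endpoint distance from transitions,
#'   seconds (default 60).
#' @param seed RNG seed for control placement.
#' @return list with `pre` and `control` per-window song probabilities and
#'   their means; both empty (with a warning) when no eligible windows exist.
#' @export
song_enrichment_before_transitions <- function(song, interacting, transitions,
                                               time, window_L,
                                               n_control = 100,
                                               min_interaction = 0.25,
                                               control_margin = 60, seed = 1) {
  fr <- 1 / stats::median(diff(time))
  w <- round(window_L * fr)
  window_prob <- function(end_idx) {
    s <- end_idx - w + 1
    if (s < 1) return(c(NA, NA))
    idx <- s:end_idx
    c(mean(song[idx]), mean(interacting[idx]))
  }
  pre <- vapply(transitions, function(tt) {
    window_prob(max(1, which.min(abs(time - tt)) - 1))
  }, numeric(2))
  pre_ok <- !is.na(pre[1, ]) & pre[2, ] >= min_interaction
  pre_p <- pre[1, pre_ok]

  set.seed(seed)
  eligible <- which(seq_along(time) >= w)
  if (length(transitions) > 0) {
    dmin <- vapply(time, function(tt) min(abs(tt - transitions)), 0)
    eligible <- eligible[dmin[eligible] >= control_margin]
  }
  if (length(eligible) == 0) {
    warning("no eligible control windows")
    return(list(pre = pre_p, control = numeric(0),
                mean_pre = mean(pre_p), mean_control = NA_real_))
  }
  ends <- sample(eligible, min(n_control, length(eligible)),
                 replace = length(eligible) < n_control)
  ctl <- vapply(ends, window_prob, numeric(2))
  ctl_ok <- !is.na(ctl[1, ]) & ctl[2, ] >= min_interaction
  ctl_p <- ctl[1, ctl_ok]
  list(pre = pre_p, control = ctl_p,
       mean_pre = if (length(pre_p)) mean(pre_p) else NA_real_,
       mean_control = if (length(ctl_p)) mean(ctl_p) else NA_real_)
}
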
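# Pose fixtures built from analytic trajectories via the scripted-skeleton
# builder; compute_features must recover the scripted kinematics within
# finite-difference error.

skeleton_pose <- function(pos0, ang0, pos1, ang1, frame_rate = 30) {
  tt <- (seq_len(nrow(pos0)) - 1) / frame_rate
  pose_pair(tt, songrules:::make_skeleton(pos0, ang0),
            songrules:::make_skeleton(pos1, ang1), frame_rate)
}

test_that("a stationary pair has zero speeds", {
  n <- 90
  pose <- skeleton_pose(matrix(c(0, 0), n, 2, byrow = TRUE), rep(0, n),
                        matrix(c(5, 0), n, 2, byrow = TRUE), rep(pi, n))
  f <- compute_features(pose)
  for (col in c("cFV", "pFV", "cLS", "pLS", "cRS", "pRS"))
    expect_lt(max(abs(f[[col]])), 1e-9)
  expect_equal(f$dis, rep(5, nrow(f)), tolerance = 1e-9)
})

test_that("translation along the heading appears as pure forward velocity", {
  n <- 90; v <- 10; fr <- 30
  x <- v * (seq_len(n) - 1) / fr
  pose <- skeleton_pose(cbind(x, 0), rep(0, n),
                        cbind(x + 30, 0), rep(0, n))
  f <- compute_features(pose)
  mid <- 10:(nrow(f) - 10)
  expect_equal(f$cFV[mid], rep(v, length(mid)), tolerance = 1e-6)
  expect_lt(max(abs(f$cLS[mid])), 1e-6)
})

test_that("rotation at 90 deg/s is recovered within finite-difference error", {
  fr <- 30; n <- 121
  tt <- (seq_len(n) - 1) / fr
  ang <- pi / 2 * tt                 # 90 deg/s
  r <- 4
  pos <- cbind(r * cos(ang), r * sin(ang))
  pose <- skeleton_pose(pos, ang + pi / 2, cbind(rep(20, n), 0), rep(0, n))
  f <- compute_features(pose)
  mid <- 15:(n - 15)
  expect_equal(f$cRS[mid], rep(90, length(mid)), tolerance = 1e-3)
  # tangential motion: |v| = r * omega along the heading
  expect_equal(f$cFV[mid], rep(r * pi / 2, length(mid)), tolerance = 0.02)
})

make_role_features <- function(dis, theta0, theta1, n = 10, frame_rate = 30) {
  f <- data.frame(dis = rep(dis, n), theta0 = rep(theta0, n),
                  theta1 = rep(theta1, n), valid = TRUE)
  attr(f, "frame_rate") <- frame_rate
  f
}

test_that("interaction requires 8 mm proximity and a 60 degree field of view", {
  m <- assign_roles(make_role_features(5, 30, 170))
  expect_true(all(m$interacting))
  expect_true(all(m$courter_id == 0))
  expect_false(any(assign_roles(make_role_features(20, 30, 170))$interacting))
  expect_false(any(assign_roles(make_role_features(5, 80, 170))$interacting))
})

test_that("the initial courter is retained during mutual facing", {
  # fly 0 courts alone, then both face each other
  f <- rbind(make_role_features(5, 30, 170, n = 5),
             make_role_features(5, 30, 20, n = 5))
  attr(f, "frame_rate") <- 30
  m <- assign_roles(f)
  expect_true(all(m$courter_id == 0))
  # at first contact both qualify: the more directly facing fly courts
  m2 <- assign_roles(make_role_features(5, 10, 40))
  expect_true(all(m2$courter_id == 0))
  m3 <- assign_roles(make_role_features(5, 40, 10))
  expect_true(all(m3$courter_id == 1))
})

test_that("role assignment is invariant to global translation and rotation", {
  set.seed(8)
  n <- 60
  walk <- function(x0) {
    p <- matrix(0, n, 2); p[1, ] <- x0
    for (t in 2:n) p[t, ] <- p[t - 1, ] + rnorm(2, 0, 0.15)
    p
  }
  p0 <- walk(c(0, 0)); p1 <- walk(c(4, 0))
  a0 <- runif(n, -pi, pi); a1 <- runif(n, -pi, pi)
  base <- assign_roles(compute_features(skeleton_pose(p0, a0, p1, a1)))
  th <- 1.1; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(12, -7)
  tf <- function(p) sweep(p %*% t(R), 2, shift, "+")
  moved <- assign_roles(compute_features(
    skeleton_pose(tf(p0), a0 + th, tf(p1), a1 + th)))
  expect_equal(moved$interacting, base$interacting)
  expect_equal(moved$courter_id, base$courter_id)
  expect_equal(moved$head_quadrant, base$head_quadrant)
})

quadrant_mask <- function(ctheta_seq, frame_rate = 30) {
  n <- length(ctheta_seq)
  m <- data.frame(interacting = rep(TRUE, n),
                  courter_id = 0L,
                  head_quadrant = ctheta_seq < 90,
                  tail_quadrant = ctheta_seq >= 90,
                  ctheta_courter = ctheta_seq)
  attr(m, "frame_rate") <- frame_rate
  m
}

test_that("quadrant occupancy smooths short bouts and counts frames", {
  fr <- 30
  # constant head quadrant -> fraction 1
  qp <- quadrant_probability(quadrant_mask(rep(45, 120)))
  expect_equal(qp$head, 1)
  expect_equal(qp$head + qp$tail, 1)

  # a 0.4 s head bout inside a long tail epoch is dropped
  seqs <- c(rep(120, 90), rep(45, 12), rep(120, 90))
  qp2 <- quadrant_probability(quadrant_mask(seqs))
  expect_equal(qp2$head, 0)

  # two head bouts separated by 0.3 s merge; frame-counting oracle
  seqs3 <- c(rep(120, 60), rep(45, 30), rep(120, 9), rep(45, 30), rep(120, 60))
  qp3 <- quadrant_probability(quadrant_mask(seqs3))
  # merged head bout spans 30 + 9 + 30 frames; tail keeps 60 + 60
  expect_equal(qp3$head, 69 / (69 + 120))
  expect_equal(qp3$tail, 120 / (69 + 120))

  # no interaction -> flagged undefined, not 0/0
  m <- quadrant_mask(rep(45, 10))
  m$interacting <- FALSE; m$head_quadrant <- FALSE; m$tail_quadrant <- FALSE
  attr(m, "frame_rate") <- fr
  expect_false(quadrant_probability(m)$defined)
})

test_that("polar occupancy bins by fly length and drops far frames", {
  n <- 100
  f <- data.frame(dis = rep(2.5, n))   # exactly 1 fly length of 2.5 mm
  m <- quadrant_mask(rep(0, n))
  h <- polar_occupancy(f, m, fly_length = 2.5)
  expect_equal(sum(h$density), 1)
  expect_equal(sum(h$density > 0), 1L)          # single occupied bin
  expect_equal(which(rowSums(h$density) > 0), 5L)  # 1 length = bin 5 of 15

  f2 <- data.frame(dis = rep(10, n))            # 4 fly lengths: excluded
  h2 <- polar_occupancy(f2, m, fly_length = 2.5)
  expect_equal(h2$n_used, 0L)

  set.seed(3)
  angles <- runif(3000, 0, 180)
  f3 <- data.frame(dis = rep(2.5, 3000))
  h3 <- polar_occupancy(f3, quadrant_mask(angles), fly_length = 2.5)
  marg <- colSums(h3$density)
  expect_lt(max(abs(marg - 1 / 36)), 0.015)     # near-uniform angular marginal
})

test_that("tail-to-head transitions require two-second epochs on both sides", {
  fr <- 30
  mk <- function(...) {
    v <- c(...)
    f <- data.frame(t = (seq_along(v) - 1) / fr)
    attr(f, "frame_rate") <- fr
    list(f = f, m = quadrant_mask(v, fr))
  }
  a <- mk(rep(120, 90), rep(45, 90))            # 3 s tail then 3 s head
  expect_length(detect_head_transitions(a$f, a$m), 1)
  expect_equal(detect_head_transitions(a$f, a$m), 90 / fr)

  b <- mk(rep(120, 30), rep(45, 90))            # 1 s tail only
  expect_length(detect_head_transitions(b$f, b$m), 0)

  c3 <- mk(rep(120, 90), rep(45, 45), rep(120, 90))  # 1.5 s head
  expect_length(detect_head_transitions(c3$f, c3$m), 0)
})

test_that("transition count is invariant to frame-rate doubling", {
  pat <- c(rep(120, 75), rep(45, 80), rep(120, 100), rep(45, 70))
  fr <- 30
  f30 <- data.frame(t = (seq_along(pat) - 1) / fr)
  attr(f30, "frame_rate") <- fr
  n30 <- length(detect_head_transitions(f30, quadrant_mask(pat, fr)))
  pat2 <- rep(pat, each = 2)
  f60 <- data.frame(t = (seq_along(pat2) - 1) / 60)
  attr(f60, "frame_rate") <- 60
  n60 <- length(detect_head_transitions(f60, quadrant_mask(pat2, 60)))
  expect_equal(n30, n60)
  expect_equal(n30, 2L)   # both tail epochs exceed 2 s, as do both head epochs
})

test_that("wing extension thresholds work and the uwe threshold is recoverable", {
  n <- 300
  set.seed(12)
  wl <- runif(n, 0, 70); wr <- runif(n, 0, 70)
  pos <- matrix(0, n, 2)
  a <- songrules:::make_skeleton(pos, rep(0, n), wing_left = wl,
                                 wing_right = wr)
  pose <- pose_pair((seq_len(n) - 1) / 30, a,
                    songrules:::make_skeleton(pos + 10, rep(0, n)), 30)
  w <- wing_extensions(pose, fly = 0)
  expect_equal(w$bwe, wl > 30 & wr > 30, tolerance = 0)
  expect_equal(unname(w$wing_angles[, 1]), wl, tolerance = 0.5)

  # labels generated with a known 25 degree cut are recovered by the sweep
  ref <- (wl > 25) != (wr > 25)
  w25 <- wing_extensions(pose, fly = 0, reference_uwe_labels = ref)
  expect_equal(w25$uwe_threshold, 25, tolerance = 1)
  expect_error(wing_extensions(pose, reference_uwe_labels = ref[1:10]),
               "length")
})

test_that("song enrichment compares pre-transition and control windows", {
  fr <- 30; n <- fr * 600
  tt <- (seq_len(n) - 1) / fr
  inter <- rep(TRUE, n)
  trans <- c(200, 400)

  # constant song: no enrichment
  r <- song_enrichment_before_transitions(rep(TRUE, n), inter, trans, tt,
                                          window_L = 10, seed = 2)
  expect_equal(r$mean_pre, r$mean_control)
  expect_equal(r$mean_pre, 1)

  # song confined to the 10 s before each transition
  song <- rep(FALSE, n)
  for (tr in trans) song[tt >= tr - 10 & tt < tr] <- TRUE
  r2 <- song_enrichment_before_transitions(song, inter, trans, tt,
                                           window_L = 10, seed = 2)
  expect_gt(r2$mean_pre, 0.9)
  expect_gt(r2$mean_pre, r2$mean_control + 0.5)

  # windows with a low interaction ratio are discarded
  inter3 <- rep(FALSE, n)       # 0% interaction < 25% requirement
  r3 <- song_enrichment_before_transitions(song, inter3, trans, tt,
                                           window_L = 10, seed = 2)
  expect_length(r3$pre, 0)
})

test_that("pose CSV round-trips through the reader", {
  sc <- simulate_pose_scenario("male_turns", duration = 3, seed = 5)
  tmp <- tempfile(fileext = ".csv")
  write_pose_csv(sc$pose, tmp)
  # the reader rebuilds time from the stated acquisition rate
  back <- read_pose_csv(tmp, mm_per_px = 1, frame_rate = 30)
  expect_equal(back$flies[[1]], sc$pose$flies[[1]], tolerance = 1e-12)
  expect_equal(back$time, sc$pose$time, tolerance = 1e-12)
})
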
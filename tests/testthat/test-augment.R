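test_that("hand dimension sampling reproduces the stated distributions", {
  set.seed(1)
  d <- sample_hand_dimensions(hand_dimension_distribution(), 100000)
  expect_equal(mean(d$hand_length) * 100, 19.3, tolerance = 0.02 / 19.3)
  expect_lt(abs(sd(d$hand_length) * 100 - 1.25), 0.02)
  expect_lt(abs(sd(d$index_ring_ratio) - 0.05), 0.002)
  # truncation excludes non-physical hands
  expect_lte(max(abs(d$hand_length - 0.193)), 4 * 0.0125)
  expect_lte(max(abs(d$index_ring_ratio - 1)), 4 * 0.05)
})

test_that("hand-size augmentation never touches the angle data", {
  m <- hand_model_default()
  motion <- test_gesture_motion(m)
  expect_length(hand_size_augment(motion, m, n_variants = 0), 0)
  set.seed(2)
  variants <- hand_size_augment(motion, m, n_variants = 5)
  for (v in variants) {
    expect_identical(v$motion$angles, motion$angles)
    fk <- rest_markers(v$model)
    expect_equal(sqrt(sum(fk["middle_tip", ]^2)), v$hand_length,
                 tolerance = 1e-9)
    expect_equal(sum(v$model$fingers$index$segments) /
                   sum(v$model$fingers$ring$segments),
                 v$index_ring_ratio, tolerance = 1e-9)
    expect_identical(v$motion$meta$source_take, take_id(motion))
  }
})

test_that("variance trace reduces to known oracles", {
  m <- hand_model_default()
  dofs <- dof_names(m)
  n <- 60
  # constant motion: D is identically zero
  ang <- matrix(5, n, length(dofs), dimnames = list(NULL, dofs))
  const <- joint_angle_motion((1:n) / 30, ang)
  expect_true(all(variance_trace(const, 5)$D == 0))
  # single moving joint: D equals the sliding standard deviation
  ang1 <- ang * 0
  ang1[, "INDEX_PIP"] <- 40 * sin(2 * pi * (1:n) / 30)
  one <- joint_angle_motion((1:n) / 30, ang1)
  prof <- variance_trace(one, 7)
  oracle_sd <- vapply(seq_len(n - 6), function(i) {
    sd(ang1[i:(i + 6), "INDEX_PIP"])
  }, numeric(1))
  expect_equal(prof$D, oracle_sd, tolerance = 1e-9)
  # multi-joint: D^2 equals the brute-force covariance trace
  set.seed(3)
  angm <- ang * 0
  for (j in sample(ncol(angm), 6)) angm[, j] <- rnorm(n, 0, 10)
  multi <- joint_angle_motion((1:n) / 30, angm)
  profm <- variance_trace(multi, 6, columns = colnames(angm))
  for (i in c(1, 20, n - 5)) {
    W <- angm[i:(i + 5), ]
    tr <- 0
    for (j in seq_len(ncol(W))) {
      mu <- mean(W[, j])
      tr <- tr + sum((W[, j] - mu)^2) / (nrow(W) - 1)
    }
    expect_equal(profm$D[i]^2, tr, tolerance = 1e-9)
  }
  expect_error(variance_trace(multi, 100), "longer than")
  expect_error(variance_trace(multi, 1), "at least 2")
})

test_that("key poses are the prominent extrema plus the endpoints", {
  mk_profile <- function(d, n_frames) {
    structure(list(D = d, D_norm = (d - min(d)) / diff(range(d)),
                   frame_index = seq_along(d) + 2, window_length = 5,
                   n_frames = n_frames),
              class = "variance_profile")
  }
  # monotone profile: endpoints only
  mono <- mk_profile(seq(0, 1, length.out = 30), 34)
  expect_identical(extract_key_poses(mono), c(1L, 34L))
  # one clean peak: start, peak, end
  x <- exp(-((1:30) - 15)^2 / 20)
  one <- mk_profile(x, 34)
  kp <- extract_key_poses(one)
  expect_identical(kp, c(1L, 17L, 34L))
  # sub-threshold ripple on the same peak is filtered by prominence
  set.seed(4)
  ripple <- x + 0.02 * sin((1:30) * 2)
  two <- mk_profile(ripple, 34)
  expect_identical(extract_key_poses(two, warp_config(prominence_threshold = 0.1)),
                   c(1L, 17L, 34L))
  # short profile returns endpoints
  short <- structure(list(D = c(0, 1), D_norm = c(0, 1), frame_index = c(2, 3),
                          window_length = 2, n_frames = 6),
                     class = "variance_profile")
  expect_identical(extract_key_poses(short), c(1L, 6L))
})

test_that("Fourier resampling is exact on band-limited signals", {
  n <- 50; t <- (0:(n - 1)) / n
  x <- 2 * sin(2 * pi * 4 * t) - cos(2 * pi * 7 * t)
  expect_identical(resample_fourier(x, n), x)
  for (n2 in c(100, 75, 37)) {
    t2 <- (0:(n2 - 1)) / n2
    ref <- 2 * sin(2 * pi * 4 * t2) - cos(2 * pi * 7 * t2)
    expect_equal(resample_fourier(x, n2), ref, tolerance = 1e-9)
  }
  expect_error(resample_fourier(x, 1), "at least 2")
})

test_that("a zero-noise warp is the identity up to filtering tolerance", {
  m <- hand_model_default()
  motion <- test_gesture_motion(m, n_frames = 60)
  kp <- extract_key_poses(variance_trace(motion, 5))
  out <- time_warp(motion, kp, warp_config(noise_bound = 0))
  expect_identical(nrow(out$angles), nrow(motion$angles))
  expect_lt(max(abs(out$angles - motion$angles)), 0.5)
})

test_that("warp durations follow the drawn multipliers", {
  m <- hand_model_default()
  motion <- test_gesture_motion(m, n_frames = 61)
  # single segment with u fixed at +0.4: duration scales by 1.4
  out <- time_warp(motion, c(1, 61), u = 0.4)
  dt <- median(diff(motion$times))
  d_in <- motion$times[61] - motion$times[1]
  d_out <- out$times[length(out$times)] - out$times[1]
  expect_lt(abs(d_out - 1.4 * d_in), dt + 1e-9)
  expect_identical(out$meta$u, 0.4)
  expect_identical(out$meta$source_take, take_id(motion))
  expect_error(time_warp(motion, c(1, 61), u = c(0.1, 0.2)),
               "one value per")
})

test_that("warp noise is bounded and uniform", {
  set.seed(42)
  u <- draw_warp_noise(100000, 0.4)
  expect_lte(max(abs(u)), 0.4)
  ks <- suppressWarnings(ks.test(u, "punif", -0.4, 0.4))
  expect_gt(ks$p.value, 0.01)
})

test_that("warped takes preserve key poses and stay near the source range", {
  m <- hand_model_default()
  set.seed(5)
  motion <- test_gesture_motion(m, n_frames = 80)
  kp <- extract_key_poses(variance_trace(motion, 5))
  jn <- finger_joint_names(m)
  for (rep in 1:5) {
    out <- time_warp(motion, kp, warp_config())
    # mapped key poses: cumulative segment lengths locate the warped keys
    seg_len <- diff(kp)
    new_len <- round(seg_len * (1 + out$meta$u))
    new_kp <- cumsum(c(1, new_len))
    for (k in seq_along(kp)) {
      expect_lt(max(abs(out$angles[new_kp[k], jn] - motion$angles[kp[k], jn])),
                2)
    }
    # amplitude never exceeds the source range by more than 2 degrees
    for (j in jn) {
      expect_lte(max(out$angles[, j]), max(motion$angles[, j]) + 2)
      expect_gte(min(out$angles[, j]), min(motion$angles[, j]) - 2)
    }
    # no instantaneous jumps at segment joins
    max_step_src <- max(abs(diff(motion$angles[, jn])))
    expect_lte(max(abs(diff(out$angles[, jn]))), 2 * max_step_src + 1e-9)
  }
})
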
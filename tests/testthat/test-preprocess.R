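make_fk_sequence <- function(model, motion) {
  project_to_markers(motion, model)
}

test_that("mirroring is a warning no-op on right hands and an involution", {
  m <- hand_model_default()
  motion <- test_gesture_motion(m)
  seq_r <- make_fk_sequence(m, motion)
  expect_warning(out <- mirror_to_right(seq_r), "already right-handed")
  expect_equal(out$positions, seq_r$positions)

  seq_l <- seq_r
  seq_l$handedness <- "left"
  once <- mirror_to_right(seq_l)
  expect_identical(once$handedness, "right")
  twice <- once
  twice$handedness <- "left"
  twice <- mirror_to_right(twice)
  expect_equal(twice$positions, seq_l$positions, tolerance = 1e-12)
})

test_that("mirroring flips the thumb side and preserves all distances", {
  m <- hand_model_default()
  seq_r <- make_fk_sequence(m, test_gesture_motion(m, n_frames = 5))
  seq_l <- seq_r
  seq_l$handedness <- "left"
  out <- mirror_to_right(seq_l)
  i <- 3
  # thumb CMC x relative to wrist changes sign
  rel_before <- seq_l$positions[i, 2, 1] - seq_l$positions[i, 1, 1]
  rel_after <- out$positions[i, 2, 1] - out$positions[i, 1, 1]
  expect_equal(rel_after, -rel_before, tolerance = 1e-12)
  d_before <- as.matrix(dist(seq_l$positions[i, , ]))
  d_after <- as.matrix(dist(out$positions[i, , ]))
  expect_equal(d_after, d_before, tolerance = 1e-12)
  # mirrored chirality is detected
  expect_identical(detect_handedness(seq_r$positions[1, , ]), "right")
  expect_identical(detect_handedness(seq_l$positions[1, , ] *
                                       matrix(c(-1, 1, 1), 21, 3,
                                              byrow = TRUE)), "left")
})

test_that("segment scaling restores model bone lengths frame by frame", {
  m <- hand_model_default()
  se <- gloveforge:::.segment_edges(m)
  seg_lengths <- function(P) {
    apply(se$edges, 1, function(e) sqrt(sum((P[e[2], ] - P[e[1], ])^2)))
  }
  seq0 <- make_fk_sequence(m, test_gesture_motion(m, n_frames = 10))
  # already at model lengths: identity
  out0 <- scale_segments(seq0, m)
  expect_equal(out0$positions, seq0$positions, tolerance = 1e-12)
  # uniform 2x input: lengths restored, directions and wrist kept
  seq2 <- seq0
  seq2$positions <- seq0$positions * 2
  out2 <- scale_segments(seq2, m)
  for (i in c(1, 5, 10)) {
    expect_equal(seg_lengths(out2$positions[i, , ]), se$lengths,
                 tolerance = 1e-9)
    expect_equal(out2$positions[i, 1, ], seq2$positions[i, 1, ])
  }
  v_in <- seq2$positions[3, 9, ] - seq2$positions[3, 8, ]
  v_out <- out2$positions[3, 9, ] - out2$positions[3, 8, ]
  expect_equal(v_out / sqrt(sum(v_out^2)), v_in / sqrt(sum(v_in^2)),
               tolerance = 1e-9)
  # per-frame drifting scale (monocular-style input)
  set.seed(1)
  seqd <- make_fk_sequence(m, test_gesture_motion(m, n_frames = 10))
  drift <- runif(10, 0.8, 1.2)
  for (i in 1:10) seqd$positions[i, , ] <- seqd$positions[i, , ] * drift[i]
  outd <- scale_segments(seqd, m)
  for (i in 1:10) {
    expect_equal(seg_lengths(outd$positions[i, , ]), se$lengths,
                 tolerance = 1e-9)
  }
})

test_that("wrist translation pins marker 0 in every frame", {
  m <- hand_model_default()
  seq0 <- make_fk_sequence(m, test_gesture_motion(m, n_frames = 8))
  shifted <- seq0
  set.seed(2)
  for (i in 1:8) shifted$positions[i, , ] <-
    shifted$positions[i, , ] + matrix(rnorm(3), 21, 3, byrow = TRUE)
  out <- translate_to_wrist(shifted, m)
  target <- rest_markers(m)[1, ]
  for (i in 1:8) expect_equal(out$positions[i, 1, ], target,
                              tolerance = 1e-12)
  # already-at-target input is untouched
  out0 <- translate_to_wrist(seq0, m)
  expect_equal(out0$positions, seq0$positions, tolerance = 1e-12)
})

test_that("Kabsch recovers exact and noisy rotations", {
  set.seed(3)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rotation(P, P), diag(3), tolerance = 1e-9)
  Rz <- gloveforge:::rotation_about_axis(c(0, 0, 1), pi / 2)
  expect_equal(kabsch_rotation(P, P %*% t(Rz)), Rz, tolerance = 1e-9)
  # proper rotation always
  R <- kabsch_rotation(P, P %*% t(Rz))
  expect_equal(det(R), 1, tolerance = 1e-9)
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-9)
  # noisy recovery, checked against a brute-force rotation search
  R0 <- gloveforge:::rotation_about_axis(c(1, 2, -1), 0.8)
  Q <- P %*% t(R0) + matrix(rnorm(30, 0, 1e-3), 10, 3)
  Rk <- kabsch_rotation(P, Q)
  expect_lt(geodesic_deg(Rk, R0), 0.5)
  bf <- brute_force_rotation(sweep(P, 2, colMeans(P)),
                             sweep(Q, 2, colMeans(Q)), n_samples = 20000)
  expect_lte(sum((sweep(P, 2, colMeans(P)) %*% t(Rk) -
                    sweep(Q, 2, colMeans(Q)))^2), bf$sse + 1e-12)
  expect_lt(geodesic_deg(Rk, bf$R), 5)
  # degenerate input
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_rotation(line, line), "degenerate")
})

test_that("preprocessing is equivariant under similarity transforms", {
  m <- hand_model_default()
  motion <- test_gesture_motion(m, n_frames = 12)
  seq0 <- make_fk_sequence(m, motion)
  ref <- preprocess_sequence(seq0, m)
  # scaled x3, rotated 45 degrees, translated
  R <- gloveforge:::rotation_about_axis(c(0, 1, 1), pi / 4)
  seqT <- seq0
  for (i in seq_along(seq0$times)) {
    seqT$positions[i, , ] <- (3 * seq0$positions[i, , ]) %*% t(R) +
      matrix(c(0.5, -1, 2), 21, 3, byrow = TRUE)
  }
  out <- preprocess_sequence(seqT, m)
  expect_lt(max(abs(out$positions - ref$positions)), 1e-6)
  # left-hand version recovers identically after mirroring
  seqL <- seqT
  for (i in seq_along(seq0$times)) {
    wx <- seqL$positions[i, 1, 1]
    seqL$positions[i, , 1] <- 2 * wx - seqL$positions[i, , 1]
  }
  seqL$handedness <- "left"
  outL <- preprocess_sequence(seqL, m)
  expect_lt(max(abs(outL$positions - ref$positions)), 1e-6)
})

test_that("palm-anchored Kabsch reproduces model-compatible input exactly", {
  m <- hand_model_default()
  seq0 <- make_fk_sequence(m, test_gesture_motion(m, n_frames = 12))
  out <- preprocess_sequence(seq0, m, kabsch_markers = palm_marker_indices())
  expect_lt(max(abs(out$positions - seq0$positions)), 1e-6)
})

test_that("preprocessing is idempotent and never worsens rest alignment", {
  m <- hand_model_default()
  motion <- test_gesture_motion(m, n_frames = 10)
  seq0 <- make_fk_sequence(m, motion)
  R <- gloveforge:::rotation_about_axis(c(1, 0, 2), 0.6)
  seqT <- seq0
  for (i in seq_along(seq0$times)) {
    seqT$positions[i, , ] <- (2 * seq0$positions[i, , ]) %*% t(R) + 0.3
  }
  once <- preprocess_sequence(seqT, m)
  twice <- preprocess_sequence(once, m)
  expect_lt(max(abs(twice$positions - once$positions)), 1e-9)
  # the Kabsch step improves (or preserves) distance to the rest markers
  target <- rest_markers(m)
  pre_rot <- translate_to_wrist(scale_segments(seqT, m), m)
  for (i in seq_along(seq0$times)) {
    d_after <- mean(sqrt(rowSums((once$positions[i, , ] - target)^2)))
    d_before <- mean(sqrt(rowSums((pre_rot$positions[i, , ] - target)^2)))
    expect_lte(d_after, d_before + 1e-12)
  }
})

test_that("marker CSV writer and reader round-trip", {
  m <- hand_model_default()
  seq0 <- make_fk_sequence(m, test_gesture_motion(m, n_frames = 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_marker_csv(seq0, path)
  back <- read_marker_csv(path)
  expect_equal(back$times, seq0$times, tolerance = 1e-9)
  expect_equal(back$positions, seq0$positions, tolerance = 1e-9)
  expect_error(read_marker_csv(path, col_map = c("nope", rep("x", 63))),
               "missing columns")
})
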
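test_that("trajectory resampling is exact on aligned grids and polynomials", {
  t <- seq(0, 1, by = 0.01)
  p <- cbind(0.1 * t, -0.2 * t + 0.05, 0 * t)
  q <- matrix(rep(c(1, 0, 0, 0), length(t)), ncol = 4, byrow = TRUE)
  same <- resample_trajectory(t, p, q, 100)
  expect_equal(same$times, t, tolerance = 1e-12)
  expect_equal(same$p, p, tolerance = 1e-12, ignore_attr = TRUE)
  # linear positions stay exactly linear under 4x upsampling
  up <- resample_trajectory(t, p, q, 400)
  expect_equal(up$p[, 1], 0.1 * up$times, tolerance = 1e-12)
  expect_equal(up$p[, 2], -0.2 * up$times + 0.05, tolerance = 1e-12)
  expect_error(resample_trajectory(t, p, q, -5), "positive")
  expect_error(resample_trajectory(t[1:3], p[1:3, ], q[1:3, ], 10),
               "at least 4")
})

test_that("slerp upsampling matches the closed-form axis-angle interpolation", {
  Om <- 1.5
  t <- seq(0, 1, by = 0.05)
  q <- t(sapply(t, function(ti) {
    gloveforge:::quat_from_axis_angle(c(0, 1, 0), Om * ti)
  }))
  p <- matrix(0, length(t), 3)
  up <- resample_trajectory(t, p, q, 100)
  ref <- t(sapply(up$times, function(ti) {
    gloveforge:::quat_from_axis_angle(c(0, 1, 0), Om * ti)
  }))
  sign_fix <- sign(rowSums(up$q * ref))
  expect_equal(up$q * sign_fix, ref, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("numerical acceleration matches closed forms", {
  t <- seq(0, 2, by = 0.01)
  # constant position: zero acceleration
  expect_equal(linear_acceleration(matrix(1, length(t), 3), t),
               matrix(0, length(t), 3), tolerance = 1e-9)
  # quadratic position: exactly g, endpoints included
  g <- 9.80665
  p <- cbind(0 * t, 0 * t, 0.5 * g * t^2)
  a <- linear_acceleration(p, t)
  expect_equal(a[, 3], rep(g, length(t)), tolerance = 1e-6)
  # circular motion reproduces the centripetal magnitude within 1%
  r <- 0.1; w <- 5
  pc <- cbind(r * cos(w * t), r * sin(w * t), 0)
  ac <- linear_acceleration(pc, t)
  mid <- 10:(length(t) - 10)
  expect_equal(mean(sqrt(rowSums(ac[mid, ]^2))), r * w^2,
               tolerance = 0.01)
  expect_error(linear_acceleration(p[1:2, ], t[1:2]), "at least 3")
})

test_that("quaternion angular velocity recovers constant rotation rates", {
  t <- seq(0, 2, by = 0.01)
  qconst <- matrix(rep(c(1, 0, 0, 0), length(t)), ncol = 4, byrow = TRUE)
  expect_equal(angular_velocity_quat(qconst, t),
               matrix(0, length(t), 3), tolerance = 1e-12)
  Om <- 2
  q <- t(sapply(t, function(ti) {
    gloveforge:::quat_from_axis_angle(c(0, 0, 1), Om * ti)
  }))
  w <- angular_velocity_quat(q, t)
  mid <- 5:(length(t) - 5)
  expect_equal(sqrt(rowSums(w[mid, ]^2)), rep(Om, length(mid)),
               tolerance = 1e-3 / Om)
  expect_equal(w[100, ], c(0, 0, Om), tolerance = 1e-3)
  expect_error(angular_velocity_quat(q * 1.1, t), "unit")
})

test_that("matrix-path angular velocity agrees with the quaternion path", {
  # smooth, slow multi-axis rotation: the two independent numerical paths
  # must agree once the ground-frame result is rotated into the body frame
  t <- seq(0, 2, by = 0.01)
  q <- t(sapply(t, function(ti) {
    gloveforge:::quat_normalize(gloveforge:::quat_mult(
      gloveforge:::quat_from_axis_angle(c(1, 0, 0), 0.15 * sin(ti)),
      gloveforge:::quat_from_axis_angle(c(0, 0, 1), 0.2 * ti)
    ))
  }))
  w_s <- angular_velocity_quat(q, t)
  Rl <- lapply(seq_len(nrow(q)), function(i) {
    gloveforge:::quat_to_matrix(q[i, ])
  })
  res <- angular_velocity_matrix(Rl, t)
  # compare where both paths use central differences (the two boundary
  # samples come from one-sided formulas with a larger truncation constant)
  interior <- 2:(length(t) - 1)
  err <- max(vapply(interior, function(i) {
    max(abs(res$omega[i, ] - Rl[[i]] %*% w_s[i, ]))
  }, numeric(1)))
  expect_lt(err, 1e-6)
  expect_lt(res$sym_residual, 1e-3)
  expect_error(angular_velocity_matrix(lapply(1:5, function(i) diag(3) * 2), t[1:5]),
               "proper rotation")
})

test_that("ideal readings encode gravity, orientation and the constant field", {
  t <- seq(0, 1, by = 0.01); n <- length(t)
  params <- imu_error_params()
  idq <- matrix(rep(c(1, 0, 0, 0), n), ncol = 4, byrow = TRUE)
  still <- list(times = t, p = matrix(0.3, n, 3), q = idq)
  r <- ideal_readings(still, params)
  expect_equal(r$accel[10, ], c(0, 0, 9.80665), tolerance = 1e-9)
  expect_equal(r$gyro[10, ], c(0, 0, 0), tolerance = 1e-9)
  expect_equal(r$mag[10, ], params$magnetic_field, tolerance = 1e-9)
  # upside-down (180 degrees about x): gravity reading flips
  qx <- gloveforge:::quat_from_axis_angle(c(1, 0, 0), pi)
  flip <- list(times = t, p = matrix(0, n, 3),
               q = matrix(rep(qx, n), ncol = 4, byrow = TRUE))
  rf <- ideal_readings(flip, params)
  expect_equal(rf$accel[10, ], c(0, 0, -9.80665), tolerance = 1e-9)
  # free fall: specific force vanishes
  pf <- cbind(0 * t, 0 * t, 1 - 0.5 * 9.80665 * t^2)
  ff <- ideal_readings(list(times = t, p = pf, q = idq), params)
  expect_lt(max(abs(ff$accel[5:(n - 5), ])), 0.05)
  # magnetometer magnitude is invariant under arbitrary rotation
  set.seed(6)
  qs <- t(sapply(t, function(ti) {
    gloveforge:::quat_from_axis_angle(c(1, 2, 0.5), 2 * ti)
  }))
  rm_ <- ideal_readings(list(times = t, p = matrix(0, n, 3), q = qs), params)
  mags <- sqrt(rowSums(rm_$mag^2))
  expect_lt(diff(range(mags)), 1e-9)
  # gyro readings ignore rigid translations of the trajectory
  r_shift <- ideal_readings(list(times = t, p = matrix(5, n, 3), q = qs),
                            params)
  r_base <- ideal_readings(list(times = t, p = matrix(0, n, 3), q = qs),
                           params)
  expect_equal(r_shift$gyro, r_base$gyro, tolerance = 1e-12)
  expect_equal(r_shift$accel, r_base$accel, tolerance = 1e-9)
})

test_that("the error model is the identity at neutral parameters", {
  t <- seq(0, 1, by = 0.01); n <- length(t)
  set.seed(7)
  ideal <- list(times = t, accel = matrix(rnorm(n * 3), n, 3),
                gyro = matrix(rnorm(n * 3), n, 3),
                mag = matrix(rnorm(n * 3, 20, 5), n, 3))
  neutral <- imu_error_params(
    accel = imu_modality_params(), gyro = imu_modality_params(),
    mag = imu_modality_params())
  out <- apply_error_model(ideal, neutral)
  expect_identical(out$accel, ideal$accel)
  expect_identical(out$gyro, ideal$gyro)
  expect_identical(out$mag, ideal$mag)
})

test_that("constant bias and noise density behave as specified", {
  t <- seq(0, 999.99, by = 0.01); n <- length(t)
  zeros <- matrix(0, n, 3)
  ideal <- list(times = t, accel = zeros, gyro = zeros, mag = zeros)
  set.seed(8)
  biased <- imu_error_params(
    accel = imu_modality_params(constant_bias = c(0.1, 0, 0)),
    gyro = imu_modality_params(), mag = imu_modality_params())
  out <- apply_error_model(ideal, biased)
  expect_equal(colMeans(out$accel) - colMeans(ideal$accel), c(0.1, 0, 0),
               tolerance = 1e-9)
  # white noise: sd = noise_density * sqrt(rate / 2), within 5%
  N <- 0.004
  noisy <- imu_error_params(
    sample_rate = 100,
    accel = imu_modality_params(noise_density = N),
    gyro = imu_modality_params(), mag = imu_modality_params())
  out2 <- apply_error_model(ideal, noisy)
  expect_equal(sd(out2$accel), N * sqrt(50), tolerance = 0.05)
  # saturation and quantization
  satp <- imu_error_params(
    accel = imu_modality_params(measurement_range = 0.5, resolution = 0.25),
    gyro = imu_modality_params(), mag = imu_modality_params())
  ideal2 <- ideal
  ideal2$accel[, 1] <- seq(-2, 2, length.out = n)
  out3 <- apply_error_model(ideal2, satp)
  expect_lte(max(abs(out3$accel)), 0.5)
  expect_true(all(abs(out3$accel / 0.25 - round(out3$accel / 0.25)) < 1e-9))
})

test_that("IMU readings round-trip through CSV", {
  m <- hand_model_default()
  motion <- test_gesture_motion(m, n_frames = 30)
  r <- simulate_imu(m, motion, "index_distal", noisy = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_imu_csv(r, path)
  back <- read_imu_csv(path)
  expect_equal(back$accel, r$accel, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$gyro, r$gyro, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$mag, r$mag, tolerance = 1e-9, ignore_attr = TRUE)
})
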
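# IMU synthesis: accelerometer, gyroscope and magnetometer readings from a
# sensor site's pose trajectory, plus a parametric error model.
#
# Ground frame: z-up, gravity (0, 0, -9.80665) m/s^2. The accelerometer
# measures specific force, so a sensor at rest with identity orientation
# reads (0, 0, +9.80665): the gravity decomposition across axes is what makes
# hand orientation visible in accelerometer data.

STANDARD_GRAVITY <- 9.80665

#' IMU error model parameters
#'
#' Parameters follow the conventional inertial-sensor error taxonomy:
#' saturation range, quantization resolution, constant bias, axis
#' misalignment, scale factor, white noise density, bias instability
#' (low-pass filtered noise) and random walk (integrated noise). Defaults are
#' datasheet-style values for a wearable-grade IMU: resolution and noise
#' density set per modality, the remaining stochastic terms zero.
#'
#' @param sample_rate Output sampling rate in Hz.
#' @param gravity Gravity magnitude, m/s^2.
#' @param magnetic_field Ground-frame magnetic field vector, microtesla.
#' @param accel,gyro,mag Per-modality parameter lists; see
#'   [imu_modality_params()].
#' @return A list of class `imu_error_params`.
#' @export
imu_error_params <- function(sample_rate = 100,
                             gravity = STANDARD_GRAVITY,
                             magnetic_field = c(19, 0, -45),
                             accel = imu_modality_params(
                               measurement_range = 8 * STANDARD_GRAVITY,
                               resolution = 0.0024,
                               noise_density = 0.002),
                             gyro = imu_modality_params(
                               measurement_range = deg2rad(2000),
                               resolution = deg2rad(0.07),
                               noise_density = deg2rad(0.01)),
                             mag = imu_modality_params(
                               measurement_range = 1300,
                               resolution = 0.3,
                               noise_density = 0.1)) {
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(sample_rate = sample_rate, gravity = gravity,
                 magnetic_field = magnetic_field,
                 accel = accel, gyro = gyro, mag = mag),
            class = "imu_error_params")
}

#' Error parameters of one IMU modality
#'
#' @param measurement_range Saturation limit (symmetric), modality units.
#' @param resolution Quantization step; 0 disables quantization.
#' @param constant_bias Per-axis additive bias (length 1 or 3).
#' @param noise_density White noise density, units/sqrt(Hz).
#' @param bias_instability Standard deviation of the first-order-filtered
#'   bias noise, modality units.
#' @param random_walk Rate random walk density, units*sqrt(Hz) per step.
#' @param axis_misalignment `3 x 3` mixing matrix (identity = aligned).
#' @param scale_factor Per-axis multiplicative gain (length 1 or 3).
#' @return A parameter list.
#' @export
imu_modality_params <- function(measurement_range = Inf, resolution = 0,
                                constant_bias = c(0, 0, 0),
                                noise_density = 0, bias_instability = 0,
                                random_walk = 0,
                                axis_misalignment = diag(3),
                                scale_factor = c(1, 1, 1)) {
  if (measurement_range <= 0) stop("measurement_range must be positive")
  if (resolution < 0) stop("resolution must be non-negative")
  list(measurement_range = measurement_range, resolution = resolution,
       constant_bias = rep(constant_bias, length.out = 3),
       noise_density = noise_density, bias_instability = bias_instability,
       random_walk = random_walk, axis_misalignment = axis_misalignment,
       scale_factor = rep(scale_factor, length.out = 3))
}

#' Resample a pose trajectory to a uniform rate
#'
#' Positions are interpolated with cubic splines per coordinate; quaternions
#' with spherical linear interpolation between hemisphere-aligned
#' neighbours, renormalized at every output sample.
#'
#' @param times Source timestamps (seconds, at least 4 frames).
#' @param p `n x 3` position matrix (m).
#' @param q `n x 4` unit quaternion matrix (scalar first).
#' @param rate Target rate in Hz.
#' @return List with uniform `times`, `p` and `q`.
#' @export
resample_trajectory <- function(times, p, q, rate) {
  if (rate <= 0) stop("rate must be positive")
  if (length(times) < 4) stop("at least 4 frames are required")
  t_new <- seq(times[1], times[length(times)], by = 1 / rate)
  p_new <- sapply(1:3, function(ax) {
    stats::spline(times, p[, ax], xout = t_new, method = "fmm")$y
  })
  # hemisphere alignment along the source sequence
  qs <- q
  for (i in 2:nrow(qs)) {
    if (sum(qs[i - 1, ] * qs[i, ]) < 0) qs[i, ] <- -qs[i, ]
  }
  q_new <- matrix(NA_real_, length(t_new), 4)
  j <- 1
  for (i in seq_along(t_new)) {
    while (j < length(times) - 1 && times[j + 1] <= t_new[i]) j <- j + 1
    h <- (t_new[i] - times[j]) / (times[j + 1] - times[j])
    h <- max(0, min(1, h))
    q_new[i, ] <- quat_slerp(qs[j, ], qs[j + 1, ], h)[1, ]
    q_new[i, ] <- quat_normalize(q_new[i, ])
  }
  list(times = t_new, p = p_new, q = q_new)
}

#' Linear acceleration by numerical differentiation (ground frame)
#'
#' Second central differences of the position; the endpoints use one-sided
#' second-order formulas.
#'
#' @param p `n x 3` position matrix (m), uniformly sampled.
#' @param times Uniform timestamps (seconds).
#' @return `n x 3` acceleration matrix (m/s^2).
#' @export
linear_acceleration <- function(p, times) {
  n <- nrow(p)
  if (n < 3) stop("at least 3 samples are required")
  dt <- times[2] - times[1]
  a <- matrix(NA_real_, n, 3)
  for (ax in 1:3) {
    x <- p[, ax]
    a[2:(n - 1), ax] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
    a[1, ax] <- (2 * x[1] - 5 * x[2] + 4 * x[3] - x[4]) / dt^2
    a[n, ax] <- (2 * x[n] - 5 * x[n - 1] + 4 * x[n - 2] - x[n - 3]) / dt^2
  }
  a
}

#' Angular velocity from the quaternion trajectory (sensor frame)
#'
#' Implements `omega = 2 q* (dq/dt)` for attitude quaternions (sensor to
#' ground), with the derivative taken by central differences. The vector
#' part is the body-frame angular velocity.
#'
#' @param q `n x 4` sign-continuous unit quaternion matrix.
#' @param times Uniform timestamps.
#' @return `n x 3` angular velocity matrix (rad/s, sensor frame).
#' @export
angular_velocity_quat <- function(q, times) {
  n <- nrow(q)
  if (n < 3) stop("at least 3 samples are required")
  norms <- sqrt(rowSums(q^2))
  if (any(abs(norms - 1) > 1e-6)) stop("q must be unit quaternions")
  if (any(rowSums(q[-n, ] * q[-1, ]) < 0)) {
    stop("q must be sign-continuous (resolve hemisphere flips first)")
  }
  dt <- times[2] - times[1]
  dq <- matrix(NA_real_, n, 4)
  dq[2:(n - 1), ] <- (q[3:n, ] - q[1:(n - 2), ]) / (2 * dt)
  dq[1, ] <- (-3 * q[1, ] + 4 * q[2, ] - q[3, ]) / (2 * dt)
  dq[n, ] <- (3 * q[n, ] - 4 * q[n - 1, ] + q[n - 2, ]) / (2 * dt)
  omega <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    w <- 2 * quat_mult(quat_conj(q[i, ]), dq[i, ])
    omega[i, ] <- w[2:4]
  }
  omega
}

#' Angular velocity from the rotation-matrix trajectory (ground frame)
#'
#' Uses the skew-symmetric matrix `S(omega) = (dR/dt) R^T` where `R(t)` maps
#' sensor-frame vectors to the ground frame; the extracted `omega` is the
#' ground-frame angular velocity. The symmetric residual of `S` is returned
#' as a numerical-quality metric.
#'
#' @param R_list List of `3 x 3` rotation matrices.
#' @param times Uniform timestamps.
#' @return List with `omega` (`n x 3`, rad/s, ground frame) and
#'   `sym_residual` (max absolute symmetric part of `S`).
#' @export
angular_velocity_matrix <- function(R_list, times) {
  n <- length(R_list)
  if (n < 3) stop("at least 3 samples are required")
  for (R in R_list[c(1, n)]) {
    if (abs(det(R) - 1) > 1e-6) stop("inputs must be proper rotation matrices")
  }
  dt <- times[2] - times[1]
  omega <- matrix(NA_real_, n, 3)
  sym_res <- 0
  dR <- function(i) {
    if (i == 1) {
      (-3 * R_list[[1]] + 4 * R_list[[2]] - R_list[[3]]) / (2 * dt)
    } else if (i == n) {
      (3 * R_list[[n]] - 4 * R_list[[n - 1]] + R_list[[n - 2]]) / (2 * dt)
    } else {
      (R_list[[i + 1]] - R_list[[i - 1]]) / (2 * dt)
    }
  }
  for (i in seq_len(n)) {
    S <- dR(i) %*% t(R_list[[i]])
    omega[i, ] <- c(S[3, 2], S[1, 3], S[2, 1])
    sym_res <- max(sym_res, max(abs(S + t(S)) / 2))
  }
  list(omega = omega, sym_residual = sym_res)
}

#' Error-free IMU readings in the sensor frame
#'
#' The accelerometer reads specific force: the ground-frame linear
#' acceleration minus gravity, rotated into the sensor frame (a stationary,
#' level sensor reads `(0, 0, +g)`). The gyroscope reads the sensor-frame
#' angular velocity; the magnetometer reads the constant ground-frame field
#' rotated into the sensor frame, so its magnitude is time-invariant.
#'
#' @param kin List with `times`, `p`, `q` (uniform rate), e.g. from
#'   [resample_trajectory()].
#' @param params An [imu_error_params()].
#' @return List with `times` and `n x 3` matrices `accel` (m/s^2), `gyro`
#'   (rad/s) and `mag` (microtesla).
#' @export
ideal_readings <- function(kin, params = imu_error_params()) {
  n <- nrow(kin$p)
  a_g <- linear_acceleration(kin$p, kin$times)
  omega_s <- angular_velocity_quat(kin$q, kin$times)
  g_vec <- c(0, 0, -params$gravity)
  accel <- matrix(NA_real_, n, 3)
  mag <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    qc <- quat_conj(kin$q[i, ])
    accel[i, ] <- quat_rotate(qc, a_g[i, ] - g_vec)
    mag[i, ] <- quat_rotate(qc, params$magnetic_field)
  }
  list(times = kin$times, accel = accel, gyro = omega_s, mag = mag)
}

.apply_modality_errors <- function(x, mp, rate) {
  n <- nrow(x)
  y <- x %*% t(mp$axis_misalignment %*% diag(mp$scale_factor))
  y <- sweep(y, 2, mp$constant_bias, `+`)
  if (mp$noise_density > 0) {
    sd_w <- mp$noise_density * sqrt(rate / 2)
    y <- y + matrix(stats::rnorm(n * 3, 0, sd_w), n, 3)
  }
  if (mp$bias_instability > 0) {
    # first-order filtered white noise (slowly wandering bias)
    alpha <- 0.01
    for (ax in 1:3) {
      w <- stats::rnorm(n, 0, mp$bias_instability)
      y[, ax] <- y[, ax] + as.numeric(stats::filter(sqrt(2 * alpha - alpha^2) * w,
                                                    1 - alpha, "recursive"))
    }
  }
  if (mp$random_walk > 0) {
    step_sd <- mp$random_walk / sqrt(rate)
    y <- y + apply(matrix(stats::rnorm(n * 3, 0, step_sd), n, 3), 2, cumsum)
  }
  y <- pmin(pmax(y, -mp$measurement_range), mp$measurement_range)
  if (mp$resolution > 0) y <- round(y / mp$resolution) * mp$resolution
  y
}

#' Apply the parametric error model to ideal readings
#'
#' Per modality:
#' `y = quantize(saturate(M diag(s) x + bias + white + bias_inst + walk))`
#' with white-noise standard deviation `noise_density * sqrt(rate / 2)`,
#' bias instability as first-order filtered white noise and random walk as
#' integrated white noise. With all parameters at their neutral values the
#' model is the identity.
#'
#' @param ideal Output of [ideal_readings()].
#' @param params An [imu_error_params()].
#' @return List of the same shape with noisy `accel`, `gyro`, `mag`.
#' @export
apply_error_model <- function(ideal, params = imu_error_params()) {
  list(times = ideal$times,
       accel = .apply_modality_errors(ideal$accel, params$accel,
                                      params$sample_rate),
       gyro = .apply_modality_errors(ideal$gyro, params$gyro,
                                     params$sample_rate),
       mag = .apply_modality_errors(ideal$mag, params$mag,
                                    params$sample_rate))
}

#' Simulate IMU readings for a sensor site over a motion
#'
#' Convenience wrapper: computes the site trajectory by forward kinematics,
#' resamples it to the IMU rate, differentiates to ideal readings and
#' applies the error model.
#'
#' @param model A `hand_model`.
#' @param motion A `joint_angle_motion`.
#' @param site Sensor site name.
#' @param params An [imu_error_params()].
#' @param noisy Apply the error model (default) or return ideal readings.
#' @return List with `times`, `accel`, `gyro`, `mag`.
#' @export
simulate_imu <- function(model, motion, site, params = imu_error_params(),
                         noisy = TRUE) {
  traj <- sensor_site_trajectory(model, motion, site)
  kin <- resample_trajectory(traj$times, traj$p, traj$q, params$sample_rate)
  ideal <- ideal_readings(kin, params)
  if (noisy) apply_error_model(ideal, params) else ideal
}

#' Write simulated IMU readings to CSV
#'
#' Columns: `time, ax, ay, az, gx, gy, gz, mx, my, mz` (seconds, m/s^2,
#' rad/s, microtesla).
#'
#' @param readings Output of [simulate_imu()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(readings, path) {
  df <- data.frame(time = readings$times,
                   ax = readings$accel[, 1], ay = readings$accel[, 2],
                   az = readings$accel[, 3],
                   gx = readings$gyro[, 1], gy = readings$gyro[, 2],
                   gz = readings$gyro[, 3],
                   mx = readings$mag[, 1], my = readings$mag[, 2],
                   mz = readings$mag[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read simulated IMU readings from CSV
#' @param path CSV written by [write_imu_csv()].
#' @return List with `times`, `accel`, `gyro`, `mag`.
#' @export
read_imu_csv <- function(path) {
  df <- utils::read.csv(path)
  list(times = df$time,
       accel = as.matrix(df[, c("ax", "ay", "az")]),
       gyro = as.matrix(df[, c("gx", "gy", "gz")]),
       mag = as.matrix(df[, c("mx", "my", "mz")]))
}
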
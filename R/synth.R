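# Synthetic gesture generation: parametric joint-angle vocabularies,
# forward projection to noisy marker sequences, and labeled multi-subject
# benchmark datasets, so the whole pipeline is testable without external
# motion datasets.

#' Define a gesture template
#'
#' A gesture is an ordered set of key poses (time fraction plus a sparse
#' map of joint angles in degrees; unnamed joints stay at 0) connected by
#' smoothstep interpolation. Per-take jitter perturbs the key-pose angles
#' and the take duration, producing within-class variation.
#'
#' @param name Gesture name.
#' @param key_poses List of `list(time = fraction in [0, 1],
#'   angles = named degrees)`, time fractions increasing.
#' @param angle_jitter_sd Per-joint key-pose jitter (degrees).
#' @param duration_sd Take duration jitter (seconds).
#' @return A list of class `gesture_template`.
#' @export
gesture_template <- function(name, key_poses, angle_jitter_sd = 2,
                             duration_sd = 0.2) {
  fr <- vapply(key_poses, `[[`, numeric(1), "time")
  if (any(fr < 0 | fr > 1) || any(diff(fr) <= 0)) {
    stop("key pose time fractions must be increasing within [0, 1]")
  }
  structure(list(name = name, key_poses = key_poses,
                 angle_jitter_sd = angle_jitter_sd,
                 duration_sd = duration_sd),
            class = "gesture_template")
}

# smoothstep: C1 interpolation, monotone between endpoints so interpolated
# angles never leave the range spanned by adjacent key poses
.smoothstep <- function(t) t * t * (3 - 2 * t)

#' Generate one take from a gesture template
#'
#' Produces a smooth joint-angle trajectory through the (jittered) key
#' poses. Jittered key-pose angles are clipped to the model joint limits, so
#' an in-limits template always yields an in-limits take; a deliberate
#' out-of-limits template (for IK diagnostics tests) is passed through.
#'
#' @param template A `gesture_template`.
#' @param model A `hand_model`.
#' @param rate Sample rate (Hz).
#' @param duration Nominal duration (s).
#' @param session Session identifier label.
#' @param jitter Apply per-take jitter (disable for reproducible
#'   fixed-shape takes).
#' @return A `joint_angle_motion` labeled with the gesture name.
#' @export
generate_take <- function(template, model, rate = 30, duration = 3,
                          session = "s01", jitter = TRUE) {
  if (rate <= 0 || duration <= 0) stop("rate and duration must be positive")
  if (jitter && template$duration_sd > 0) {
    duration <- max(0.5, duration + stats::rnorm(1, 0, template$duration_sd))
  }
  n <- max(2L, as.integer(round(duration * rate)))
  times <- (seq_len(n) - 1) / rate
  frac <- times / times[n]
  dofs <- dof_names(model)
  jt <- model$joints[match(dofs, model$joints$name), ]
  keys <- template$key_poses
  key_t <- vapply(keys, `[[`, numeric(1), "time")
  key_mat <- matrix(0, length(keys), length(dofs),
                    dimnames = list(NULL, dofs))
  for (i in seq_along(keys)) {
    ang <- keys[[i]]$angles
    if (length(ang)) {
      unknown <- setdiff(names(ang), dofs)
      if (length(unknown)) stop("unknown joints: ", paste(unknown, collapse = ", "))
      key_mat[i, names(ang)] <- ang
    }
  }
  if (jitter && template$angle_jitter_sd > 0) {
    jit <- matrix(stats::rnorm(length(key_mat), 0, template$angle_jitter_sd),
                  nrow(key_mat), ncol(key_mat))
    # keep the wrist and untouched joints clean: jitter only active columns
    active <- colSums(abs(key_mat)) > 0
    key_mat[, active] <- key_mat[, active] + jit[, active, drop = FALSE]
    in_limits <- all(key_mat[, active] >= matrix(jt$lo[active], nrow(key_mat),
                                                 sum(active), byrow = TRUE) - 1e-9)
    key_mat[, active] <- pmin(pmax(key_mat[, active],
                                   matrix(jt$lo[active], nrow(key_mat),
                                          sum(active), byrow = TRUE)),
                              matrix(jt$hi[active], nrow(key_mat),
                                     sum(active), byrow = TRUE))
  }
  # anchor key poses at 0 and 1 if the template leaves them open
  if (key_t[1] > 0) { key_t <- c(0, key_t); key_mat <- rbind(key_mat[1, ], key_mat) }
  nk <- length(key_t)
  if (key_t[nk] < 1) { key_t <- c(key_t, 1); key_mat <- rbind(key_mat, key_mat[nk, ]) }
  ang <- matrix(NA_real_, n, length(dofs), dimnames = list(NULL, dofs))
  seg <- findInterval(frac, key_t, rightmost.closed = TRUE)
  seg[seg >= length(key_t)] <- length(key_t) - 1L
  for (i in seq_len(n)) {
    s <- seg[i]
    h <- (frac[i] - key_t[s]) / (key_t[s + 1] - key_t[s])
    w <- .smoothstep(max(0, min(1, h)))
    ang[i, ] <- (1 - w) * key_mat[s, ] + w * key_mat[s + 1, ]
  }
  joint_angle_motion(times, ang, activity = template$name, session = session)
}

#' Project a joint-angle motion to a synthetic marker sequence
#'
#' Forward kinematics per frame plus isotropic Gaussian marker noise;
#' optional per-frame uniform scale drift in `[0.8, 1.2]` and per-frame
#' random rigid jitter emulate the arbitrary, drifting coordinate frames of
#' monocular 3D pose estimators (exactly the errors preprocessing removes).
#'
#' @param motion A `joint_angle_motion`.
#' @param model A `hand_model`.
#' @param noise_sd_mm Marker noise standard deviation (mm).
#' @param scale_drift Apply per-frame random uniform scaling about the
#'   wrist.
#' @param frame_rigid_jitter Apply per-frame random rotation (up to
#'   `jitter_angle_deg`) and translation.
#' @param jitter_angle_deg Maximum rigid-jitter rotation (degrees).
#' @return A `marker_sequence` (source `"video_keypoints"` when any
#'   corruption is enabled, `"mocap"` otherwise).
#' @export
project_to_markers <- function(motion, model, noise_sd_mm = 0,
                               scale_drift = FALSE,
                               frame_rigid_jitter = FALSE,
                               jitter_angle_deg = 30) {
  n <- length(motion$times)
  pos <- array(NA_real_, c(n, 21, 3))
  for (i in seq_len(n)) {
    pose <- motion_frame_pose(model, motion, i)
    fk <- forward_kinematics(model, pose)
    if (scale_drift) {
      s <- stats::runif(1, 0.8, 1.2)
      wrist <- fk[1, ]
      fk <- sweep(fk, 2, wrist) * s
      fk <- sweep(fk, 2, -wrist)
    }
    if (frame_rigid_jitter) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      R <- rotation_about_axis(ax, deg2rad(stats::runif(1, -jitter_angle_deg,
                                                        jitter_angle_deg)))
      fk <- fk %*% t(R)
      fk <- sweep(fk, 2, stats::rnorm(3, 0, 0.05), `+`)
    }
    if (noise_sd_mm > 0) {
      fk <- fk + matrix(stats::rnorm(21 * 3, 0, noise_sd_mm / 1000), 21, 3)
    }
    pos[i, , ] <- fk
  }
  corrupted <- scale_drift || frame_rigid_jitter || noise_sd_mm > 0
  marker_sequence(motion$times, pos, handedness = "right",
                  source = if (corrupted) "video_keypoints" else "mocap")
}

# staggered flex bumps for a non-thumb finger: each joint peaks at a
# different key pose, which decorrelates the joints of the finger
.finger_bump_keys <- function(finger, amp = c(45, 70, 50), abd = 12) {
  fu <- toupper(finger)
  mcp <- paste0(fu, "_MCP_FLEXION"); pip <- paste0(fu, "_PIP")
  dip <- paste0(fu, "_DIP"); ab <- paste0(fu, "_ABDUCTION")
  list(
    list(time = 0, angles = c()),
    list(time = 0.2, angles = stats::setNames(c(amp[1], 5, 0, abd),
                                              c(mcp, pip, dip, ab))),
    list(time = 0.45, angles = stats::setNames(c(15, amp[2], 15, -abd / 2),
                                               c(mcp, pip, dip, ab))),
    list(time = 0.7, angles = stats::setNames(c(30, 10, amp[3], 0),
                                              c(mcp, pip, dip, ab))),
    list(time = 1, angles = c())
  )
}

# synchronized curl shared by middle/ring/pinky: role-paired joints carry
# identical time series across the three fingers
.curl_angles <- function(scale) {
  out <- c()
  for (f in c("middle", "ring", "pinky")) {
    fu <- toupper(f)
    out <- c(out, stats::setNames(c(50, 65, 40) * scale,
                                  c(paste0(fu, "_MCP_FLEXION"),
                                    paste0(fu, "_PIP"), paste0(fu, "_DIP"))))
  }
  out
}

#' The pinch gesture vocabulary with known-optimal sensor sites
#'
#' A three-gesture construction in which the thumb and index finger are the
#' only discriminative actors while middle, ring and pinky perform an
#' identical synchronized curl in every gesture: their cross-finger
#' correlation is ~1, so their inter-finger independence collapses to ~0
#' and every informative (top-ranked) sensor site must lie on the thumb or
#' index finger. In `"pinch"` thumb and index flex together; in `"point"`
#' only the index oscillates (the thumb is still); in `"thumbs_up"` only
#' the thumb moves.
#'
#' @param angle_jitter_sd,duration_sd Per-take jitter parameters.
#' @return Named list of `gesture_template` objects.
#' @export
pinch_vocabulary <- function(angle_jitter_sd = 2, duration_sd = 0.2) {
  curl <- function(t, s) list(time = t, angles = .curl_angles(s))
  thumb <- function(cmc, mcp, ip) {
    stats::setNames(c(cmc, 12, mcp, ip),
                    c("THUMB_CMC_FLEXION", "THUMB_CMC_ABDUCTION",
                      "THUMB_MCP", "THUMB_IP"))
  }
  idx <- function(mcp, pip, dip) {
    stats::setNames(c(mcp, 8, pip, dip),
                    c("INDEX_MCP_FLEXION", "INDEX_ABDUCTION", "INDEX_PIP",
                      "INDEX_DIP"))
  }
  list(
    pinch = gesture_template("pinch", list(
      list(time = 0, angles = c()),
      list(time = 0.2, angles = c(thumb(35, 5, 0), idx(40, 5, 0),
                                  .curl_angles(0.4))),
      list(time = 0.45, angles = c(thumb(10, 40, 10), idx(10, 60, 10),
                                   .curl_angles(1))),
      list(time = 0.7, angles = c(thumb(25, 5, 45), idx(25, 10, 45),
                                  .curl_angles(0.4))),
      list(time = 1, angles = c())
    ), angle_jitter_sd, duration_sd),
    point = gesture_template("point", list(
      list(time = 0, angles = c()),
      list(time = 0.15, angles = c(idx(50, 10, 5), .curl_angles(0.5))),
      list(time = 0.35, angles = c(idx(5, 70, 10), .curl_angles(1))),
      list(time = 0.55, angles = c(idx(45, 15, 50), .curl_angles(0.5))),
      list(time = 0.8, angles = c(idx(10, 50, 60), .curl_angles(0.9))),
      list(time = 1, angles = c())
    ), angle_jitter_sd, duration_sd),
    thumbs_up = gesture_template("thumbs_up", list(
      list(time = 0, angles = c()),
      list(time = 0.15, angles = c(thumb(45, 10, 5), .curl_angles(0.5))),
      list(time = 0.35, angles = c(thumb(5, 50, 10), .curl_angles(1))),
      list(time = 0.55, angles = c(thumb(40, 15, 60), .curl_angles(0.5))),
      list(time = 0.8, angles = c(thumb(10, 45, 70), .curl_angles(0.9))),
      list(time = 1, angles = c())
    ), angle_jitter_sd, duration_sd)
  )
}

#' Default gesture vocabulary (case-study style hand gestures)
#'
#' Angle templates for thumbs-up, fist, rocker sign and finger spreading.
#' The values are documented fixtures chosen to be anatomically plausible
#' and within the default joint limits.
#'
#' @param angle_jitter_sd,duration_sd Per-take jitter parameters.
#' @return Named list of `gesture_template` objects.
#' @export
gesture_vocabulary <- function(angle_jitter_sd = 2, duration_sd = 0.2) {
  all_flex <- function(fingers, mcp, pip, dip) {
    out <- c()
    for (f in fingers) {
      fu <- toupper(f)
      out <- c(out, stats::setNames(c(mcp, pip, dip),
                                    c(paste0(fu, "_MCP_FLEXION"),
                                      paste0(fu, "_PIP"),
                                      paste0(fu, "_DIP"))))
    }
    out
  }
  spread_abd <- c(INDEX_ABDUCTION = 20, MIDDLE_ABDUCTION = 8,
                  RING_ABDUCTION = 15, PINKY_ABDUCTION = 22)
  list(
    thumbs_up = gesture_template("thumbs_up", list(
      list(time = 0, angles = c()),
      list(time = 0.4, angles = c(all_flex(c("index", "middle", "ring",
                                             "pinky"), 75, 95, 60),
                                  THUMB_CMC_ABDUCTION = 40)),
      list(time = 0.7, angles = c(all_flex(c("index", "middle", "ring",
                                             "pinky"), 75, 95, 60),
                                  THUMB_CMC_ABDUCTION = 40)),
      list(time = 1, angles = c())
    ), angle_jitter_sd, duration_sd),
    fist = gesture_template("fist", list(
      list(time = 0, angles = c()),
      list(time = 0.45, angles = c(all_flex(FINGERS[-1], 80, 100, 65),
                                   THUMB_CMC_FLEXION = 45, THUMB_MCP = 45,
                                   THUMB_IP = 50)),
      list(time = 0.65, angles = c(all_flex(FINGERS[-1], 80, 100, 65),
                                   THUMB_CMC_FLEXION = 45, THUMB_MCP = 45,
                                   THUMB_IP = 50)),
      list(time = 1, angles = c())
    ), angle_jitter_sd, duration_sd),
    rocker = gesture_template("rocker", list(
      list(time = 0, angles = c()),
      list(time = 0.4, angles = c(all_flex(c("middle", "ring"), 80, 100, 60),
                                  THUMB_CMC_FLEXION = 40, THUMB_MCP = 40)),
      list(time = 0.7, angles = c(all_flex(c("middle", "ring"), 80, 100, 60),
                                  THUMB_CMC_FLEXION = 40, THUMB_MCP = 40)),
      list(time = 1, angles = c())
    ), angle_jitter_sd, duration_sd),
    spread = gesture_template("spread", list(
      list(time = 0, angles = c()),
      list(time = 0.4, angles = spread_abd),
      list(time = 0.7, angles = spread_abd),
      list(time = 1, angles = c())
    ), angle_jitter_sd, duration_sd)
  )
}

#' Build a labeled synthetic benchmark dataset
#'
#' Generates `takes_per_gesture` takes per template, distributed round-robin
#' over `n_subjects` subjects whose hand dimensions are sampled from the
#' anthropometric distribution (each subject's takes pair with their scaled
#' hand model).
#'
#' @param vocabulary Named list of `gesture_template` objects.
#' @param n_subjects Number of simulated subjects.
#' @param takes_per_gesture Takes per gesture.
#' @param base_model Base `hand_model` to resize per subject.
#' @param dist A [hand_dimension_distribution()].
#' @param rate,duration Sampling rate (Hz) and nominal take duration (s).
#' @return List with `dataset` (a `motion_dataset`), `models` (one
#'   `hand_model` per take) and `subjects` (sampled dimensions).
#' @export
build_benchmark <- function(vocabulary, n_subjects = 3,
                            takes_per_gesture = 6,
                            base_model = hand_model_default(),
                            dist = hand_dimension_distribution(),
                            rate = 30, duration = 3) {
  dims <- sample_hand_dimensions(dist, n_subjects)
  subject_models <- lapply(seq_len(n_subjects), function(i) {
    scale_model(base_model, dims$hand_length[i], dims$index_ring_ratio[i])
  })
  takes <- list(); models <- list()
  for (tpl in vocabulary) {
    for (k in seq_len(takes_per_gesture)) {
      subj <- (k - 1) %% n_subjects + 1
      session <- sprintf("subj%02d_take%02d", subj, k)
      takes[[length(takes) + 1]] <- generate_take(tpl, subject_models[[subj]],
                                                  rate = rate,
                                                  duration = duration,
                                                  session = session)
      models[[length(models) + 1]] <- subject_models[[subj]]
    }
  }
  list(dataset = motion_dataset(takes), models = models, subjects = dims)
}
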
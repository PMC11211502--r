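# Forward kinematics of the hand chain: poses to marker positions and
# sensor-site frames.

#' Construct a hand pose
#'
#' A pose holds all 26 DOF: the 20 finger joint angles (degrees), the wrist
#' position (m) and the wrist orientation as a scalar-first unit quaternion
#' (attitude: rotates wrist-frame vectors into the ground frame).
#'
#' @param model A `hand_model`.
#' @param angles Named numeric vector of finger joint angles in degrees;
#'   missing joints default to 0. Unknown names are an error.
#' @param wrist_position Numeric length-3, meters.
#' @param wrist_orientation Unit quaternion (scalar first).
#' @return An object of class `hand_pose`.
#' @export
hand_pose <- function(model, angles = NULL, wrist_position = c(0, 0, 0),
                      wrist_orientation = c(1, 0, 0, 0)) {
  joint_names <- finger_joint_names(model)
  full <- stats::setNames(numeric(length(joint_names)), joint_names)
  if (!is.null(angles) && length(angles)) {
    unknown <- setdiff(names(angles), joint_names)
    if (length(unknown)) {
      stop("unknown joint name(s): ", paste(unknown, collapse = ", "))
    }
    full[names(angles)] <- angles
  }
  nq <- sqrt(sum(wrist_orientation^2))
  if (abs(nq - 1) > 1e-6) stop("wrist_orientation must be a unit quaternion")
  structure(list(
    angles = full,
    wrist_position = as.numeric(wrist_position),
    wrist_orientation = wrist_orientation / nq
  ), class = "hand_pose")
}

# Per-finger chain in the wrist frame. Returns, for every finger, the joint
# point positions (rows: base joint, then one per articulated segment end)
# and the rotation matrix of each phalanx segment frame.
.finger_chain_local <- function(model, finger, angles) {
  f <- model$fingers[[finger]]
  jt <- model$joints[model$joints$finger == finger, ]
  ax <- function(i) c(jt$axis_x[i], jt$axis_y[i], jt$axis_z[i])
  th <- deg2rad(angles[jt$name])
  segs <- f$segments
  base <- f$base_offset
  # first two DOF act at the finger base joint (MCP, or thumb CMC):
  # abduction about the local z-ish axis, then flexion
  R1 <- f$base_rot %*% rotation_about_axis(ax(2), th[2]) %*%
    rotation_about_axis(ax(1), th[1])
  p <- matrix(NA_real_, 4, 3)
  Rs <- vector("list", 3)
  p[1, ] <- base
  p[2, ] <- base + R1 %*% c(0, segs[[1]], 0)
  R2 <- R1 %*% rotation_about_axis(ax(3), th[3])
  p[3, ] <- p[2, ] + R2 %*% c(0, segs[[2]], 0)
  R3 <- R2 %*% rotation_about_axis(ax(4), th[4])
  p[4, ] <- p[3, ] + R3 %*% c(0, segs[[3]], 0)
  Rs[[1]] <- R1; Rs[[2]] <- R2; Rs[[3]] <- R3
  list(points = p, frames = Rs)
}

# Full chain in the ground frame: 21 markers plus per-finger segment frames.
.hand_chain <- function(model, pose) {
  Rw <- quat_to_matrix(pose$wrist_orientation)
  tw <- pose$wrist_position
  markers <- matrix(NA_real_, 21, 3)
  markers[1, ] <- tw  # marker 0: wrist
  frames <- list()
  row <- 2
  for (f in FINGERS) {
    ch <- .finger_chain_local(model, f, pose$angles)
    pts <- t(Rw %*% t(ch$points)) + matrix(tw, 4, 3, byrow = TRUE)
    markers[row:(row + 3), ] <- pts
    frames[[f]] <- list(points = pts,
                        frames = lapply(ch$frames, function(R) Rw %*% R))
    row <- row + 4
  }
  list(markers = markers, fingers = frames)
}

#' Forward kinematics: ground-frame positions of the 21 markers
#'
#' Markers follow the 0-20 numbering: wrist, then base joint to fingertip for
#' thumb, index, middle, ring and pinky in turn.
#'
#' @param model A `hand_model`.
#' @param pose A `hand_pose` covering every DOF.
#' @return A 21 x 3 numeric matrix (meters), rows named by marker.
#' @export
#' @examples
#' m <- hand_model_default()
#' fk <- forward_kinematics(m, hand_pose(m))
#' fk["wrist", ]  # the wrist marker sits at the wrist origin
forward_kinematics <- function(model, pose) {
  stopifnot(inherits(pose, "hand_pose"))
  if (any(abs(pose$angles) > 360)) stop("joint angles must be within +/-360 degrees")
  out <- .hand_chain(model, pose)$markers
  rownames(out) <- model$markers$name
  out
}

#' Rest-pose marker layout of a model
#'
#' Markers of the zero pose (all angles 0, wrist at the origin with identity
#' orientation); this is the Kabsch alignment target used in preprocessing.
#'
#' @param model A `hand_model`.
#' @return A 21 x 3 matrix (meters).
#' @export
rest_markers <- function(model) {
  forward_kinematics(model, hand_pose(model))
}

#' Position and orientation of a candidate sensor site
#'
#' Sites sit at phalanx midpoints (thumb: also the metacarpal midpoint) and
#' inherit the segment frame: local y along the bone, z dorsal at rest. The
#' returned quaternion is the attitude of the site (it rotates sensor-frame
#' vectors into the ground frame); its conjugate maps ground-frame vectors
#' into the sensor frame.
#'
#' @param model A `hand_model`.
#' @param pose A `hand_pose`.
#' @param site Sensor site name, e.g. `"index_distal"`.
#' @return List with `p` (3-vector, m) and `q` (unit quaternion, scalar
#'   first).
#' @export
sensor_frame_kinematics <- function(model, pose, site) {
  idx <- match(site, model$sensor_sites$name)
  if (is.na(idx)) stop("unknown sensor site: ", site)
  finger <- model$sensor_sites$finger[idx]
  bone <- model$sensor_sites$bone[idx]
  ch <- .hand_chain(model, pose)$fingers[[finger]]
  seg_i <- if (finger == "thumb") {
    match(bone, c("metacarpal", "proximal", "distal"))
  } else {
    match(bone, c("proximal", "middle", "distal"))
  }
  p <- (ch$points[seg_i, ] + ch$points[seg_i + 1, ]) / 2
  list(p = as.numeric(p), q = matrix_to_quat(ch$frames[[seg_i]]))
}

#' Sensor-site trajectory over a joint-angle motion
#'
#' Runs forward kinematics frame by frame and returns the site's position and
#' attitude time series, with quaternion sign continuity enforced.
#'
#' @param model A `hand_model`.
#' @param motion A `joint_angle_motion`.
#' @param site Sensor site name.
#' @return List with `times`, `p` (n x 3) and `q` (n x 4).
#' @export
sensor_site_trajectory <- function(model, motion, site) {
  n <- length(motion$times)
  p <- matrix(NA_real_, n, 3)
  q <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    pose <- motion_frame_pose(model, motion, i)
    sk <- sensor_frame_kinematics(model, pose, site)
    p[i, ] <- sk$p
    qi <- sk$q
    if (i > 1 && sum(q[i - 1, ] * qi) < 0) qi <- -qi
    q[i, ] <- qi
  }
  list(times = motion$times, p = p, q = q)
}

#' Trajectories of several sensor sites in one forward-kinematics pass
#'
#' Equivalent to calling [sensor_site_trajectory()] per site but computes
#' the hand chain once per frame.
#'
#' @param model A `hand_model`.
#' @param motion A `joint_angle_motion`.
#' @param sites Character vector of site names.
#' @return Named list of per-site trajectories (`times`, `p`, `q`).
#' @export
sensor_site_trajectories <- function(model, motion, sites) {
  idx <- match(sites, model$sensor_sites$name)
  if (anyNA(idx)) stop("unknown sensor site(s): ",
                       paste(sites[is.na(idx)], collapse = ", "))
  n <- length(motion$times)
  out <- lapply(sites, function(s) {
    list(times = motion$times, p = matrix(NA_real_, n, 3),
         q = matrix(NA_real_, n, 4))
  })
  names(out) <- sites
  for (i in seq_len(n)) {
    pose <- motion_frame_pose(model, motion, i)
    ch <- .hand_chain(model, pose)$fingers
    for (k in seq_along(sites)) {
      finger <- model$sensor_sites$finger[idx[k]]
      bone <- model$sensor_sites$bone[idx[k]]
      seg_i <- if (finger == "thumb") {
        match(bone, c("metacarpal", "proximal", "distal"))
      } else {
        match(bone, c("proximal", "middle", "distal"))
      }
      fc <- ch[[finger]]
      out[[k]]$p[i, ] <- (fc$points[seg_i, ] + fc$points[seg_i + 1, ]) / 2
      qi <- matrix_to_quat(fc$frames[[seg_i]])
      if (i > 1 && sum(out[[k]]$q[i - 1, ] * qi) < 0) qi <- -qi
      out[[k]]$q[i, ] <- qi
    }
  }
  out
}

#' Hand pose of one frame of a joint-angle motion
#'
#' @param model A `hand_model`.
#' @param motion A `joint_angle_motion`.
#' @param i Frame index.
#' @return A `hand_pose`.
#' @export
motion_frame_pose <- function(model, motion, i) {
  ang <- motion$angles[i, finger_joint_names(model)]
  wp <- c(0, 0, 0)
  Rw <- diag(3)
  if (all(c("WRIST_TX", "WRIST_TY", "WRIST_TZ") %in% colnames(motion$angles))) {
    wp <- as.numeric(motion$angles[i, c("WRIST_TX", "WRIST_TY", "WRIST_TZ")])
  }
  if (all(c("WRIST_RX", "WRIST_RY", "WRIST_RZ") %in% colnames(motion$angles))) {
    e <- deg2rad(as.numeric(motion$angles[i, c("WRIST_RX", "WRIST_RY",
                                               "WRIST_RZ")]))
    Rw <- euler_xyz_to_matrix(e[1], e[2], e[3])
  }
  hand_pose(model, angles = ang, wrist_position = wp,
            wrist_orientation = matrix_to_quat(Rw))
}

# Edge list of the 20 hand segments (marker index pairs, 1-based) with their
# model rest lengths; used by per-segment scaling and validation.
.segment_edges <- function(model) {
  edges <- matrix(NA_integer_, 20, 2)
  lens <- numeric(20)
  k <- 1
  row0 <- 2
  for (f in FINGERS) {
    base_len <- sqrt(sum(model$fingers[[f]]$base_offset^2))
    segs <- model$fingers[[f]]$segments
    edges[k, ] <- c(1, row0); lens[k] <- base_len; k <- k + 1
    for (s in 1:3) {
      edges[k, ] <- c(row0 + s - 1, row0 + s); lens[k] <- segs[[s]]; k <- k + 1
    }
    row0 <- row0 + 4
  }
  list(edges = edges, lengths = lens)
}
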
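# Per-frame constrained inverse kinematics, quality diagnostics and take
# filtering.
#
# The solver exploits the tree structure of the hand: the wrist frame is
# recovered in closed form by a Kabsch fit over the rigid palm markers, and
# each finger's 4 DOF are then solved independently by damped nonlinear least
# squares on its three moving markers, with soft quadratic penalties outside
# the joint limits.

#' Construct a joint-angle motion
#'
#' @param times Strictly increasing numeric vector (seconds).
#' @param angles `n x 26` numeric matrix, columns named by DOF: the 20 finger
#'   joints in degrees plus `WRIST_TX/TY/TZ` (m) and `WRIST_RX/RY/RZ`
#'   (degrees, intrinsic XYZ Euler).
#' @param activity Gesture/activity label.
#' @param session Recording session identifier.
#' @return An object of class `joint_angle_motion`.
#' @export
joint_angle_motion <- function(times, angles, activity = NA_character_,
                               session = NA_character_) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  angles <- as.matrix(angles)
  if (nrow(angles) != length(times)) stop("angles must have one row per time")
  if (is.null(colnames(angles))) stop("angle columns must be named")
  structure(list(times = times, angles = angles, activity = activity,
                 session = session),
            class = "joint_angle_motion")
}

#' @export
print.joint_angle_motion <- function(x, ...) {
  cat(sprintf("<joint_angle_motion> %d frames, %d DOF, activity=%s session=%s\n",
              length(x$times), ncol(x$angles), x$activity, x$session))
  invisible(x)
}

#' Inverse kinematics configuration
#'
#' @param limit_penalty_weight Weight of the soft quadratic limit penalty.
#'   The penalty residual is `sqrt(weight)` times the excess beyond a limit
#'   in degrees, competing against marker residuals in meters; the default
#'   weights 1 degree of violation like 1 mm of marker error. Set to 0 to
#'   disable constraints.
#' @param max_iterations Iteration cap of the least-squares solver.
#' @param tolerance Convergence tolerance of the solver.
#' @param mde_filter_threshold Mean-distance-error threshold (mm) used by
#'   [filter_takes()].
#' @param warm_start Warm-start each frame from the previous frame's pose.
#' @return A list of class `ik_config`.
#' @export
ik_config <- function(limit_penalty_weight = 1e-6, max_iterations = 200,
                      tolerance = 1e-8, mde_filter_threshold = 10,
                      warm_start = TRUE) {
  if (mde_filter_threshold <= 0) stop("mde_filter_threshold must be positive")
  structure(list(limit_penalty_weight = limit_penalty_weight,
                 max_iterations = max_iterations, tolerance = tolerance,
                 mde_filter_threshold = mde_filter_threshold,
                 warm_start = warm_start), class = "ik_config")
}

# Closed-form wrist frame from the rigid palm markers.
.solve_wrist <- function(model, targets) {
  idx <- palm_marker_indices()
  rest <- rest_markers(model)[idx, ]
  obs <- targets[idx, ]
  rc <- colMeans(rest); oc <- colMeans(obs)
  R <- kabsch_rotation(sweep(rest, 2, rc), sweep(obs, 2, oc), center = FALSE)
  t <- oc - as.numeric(R %*% rc)
  list(R = R, t = t)
}

# Residuals of one finger: 9 marker coordinates plus 4 soft limit penalties.
.finger_residuals <- function(theta, model, finger, local_targets, jt, w) {
  names(theta) <- jt$name
  ch <- .finger_chain_local(model, finger, theta)
  res <- as.numeric(ch$points[2:4, ] - local_targets)
  if (w > 0) {
    excess <- pmax(0, jt$lo - theta) + pmax(0, theta - jt$hi)
    res <- c(res, sqrt(w) * excess)
  }
  res
}

# Forward-difference Jacobian with an absolute step in degrees: a relative
# step collapses for joints sitting numerically at zero.
.finger_jacobian <- function(theta, model, finger, local_targets, jt, w,
                             h = 1e-6) {
  r0 <- .finger_residuals(theta, model, finger, local_targets, jt, w)
  J <- matrix(NA_real_, length(r0), length(theta))
  for (k in seq_along(theta)) {
    tp <- theta
    tp[k] <- tp[k] + h
    J[, k] <- (.finger_residuals(tp, model, finger, local_targets, jt, w) -
                 r0) / h
  }
  J
}

.solve_finger <- function(model, finger, local_targets, init, cfg) {
  jt <- model$joints[model$joints$finger == finger, ]
  fit_one <- function(start) {
    fit <- minpack.lm::nls.lm(
      par = start, fn = .finger_residuals, jac = .finger_jacobian,
      model = model, finger = finger,
      local_targets = local_targets, jt = jt, w = cfg$limit_penalty_weight,
      control = minpack.lm::nls.lm.control(
        maxiter = cfg$max_iterations, ftol = cfg$tolerance,
        ptol = cfg$tolerance))
    list(par = fit$par, sse = sum(fit$fvec^2))
  }
  best <- fit_one(init)
  # retry from a mid-flexion start if the first basin is poor (> ~1 mm rms)
  if (best$sse > 3 * (1e-3)^2) {
    alt <- pmin(pmax((jt$lo + jt$hi) / 2, jt$lo), jt$hi)
    cand <- fit_one(alt)
    if (cand$sse < best$sse) best <- cand
  }
  stats::setNames(best$par, jt$name)
}

#' Solve the inverse kinematics of a single frame
#'
#' @param model A `hand_model`.
#' @param target_markers Preprocessed `21 x 3` marker positions (m).
#' @param init Initial `hand_pose` (warm start); defaults to the rest pose.
#' @param cfg An [ik_config()].
#' @return List with `pose` (a `hand_pose`) and `mde` (mean Euclidean marker
#'   distance in mm between the fitted and target markers).
#' @export
solve_frame <- function(model, target_markers, init = NULL,
                        cfg = ik_config()) {
  if (is.null(init)) init <- hand_pose(model)
  wrist <- .solve_wrist(model, target_markers)
  local_targets_all <- sweep(target_markers, 2, wrist$t) %*% wrist$R
  angles <- numeric(0)
  row0 <- 2
  for (f in FINGERS) {
    jt_names <- model$joints$name[model$joints$finger == f]
    lt <- local_targets_all[(row0 + 1):(row0 + 3), , drop = FALSE]
    th <- .solve_finger(model, f, lt, init$angles[jt_names], cfg)
    angles <- c(angles, th)
    row0 <- row0 + 4
  }
  pose <- hand_pose(model, angles = angles, wrist_position = wrist$t,
                    wrist_orientation = matrix_to_quat(wrist$R))
  mde <- frame_mde(model, pose, target_markers)
  init_mde <- frame_mde(model, init, target_markers)
  if (mde > init_mde + 1e-12) {
    pose <- init
    mde <- init_mde
  }
  list(pose = pose, mde = mde)
}

#' Mean marker distance error of a pose against target markers (mm)
#'
#' @param model A `hand_model`.
#' @param pose A `hand_pose`.
#' @param target_markers `21 x 3` matrix (m).
#' @return Mean Euclidean distance over the 21 markers, in millimeters.
#' @export
frame_mde <- function(model, pose, target_markers) {
  fk <- forward_kinematics(model, pose)
  mean(sqrt(rowSums((fk - target_markers)^2))) * 1000
}

#' Solve a whole marker sequence
#'
#' Frames are solved in order; with `cfg$warm_start` each frame starts from
#' the previous solution. Returns the joint-angle motion (Table-style CSV
#' columns) and aggregate quality diagnostics: mean/sd of the per-frame MDE,
#' the constraint violation ratio CVR (% of frame-joint pairs outside the
#' limits, computed on the unclipped solution) and the mean/sd violation
#' magnitude CVM (degrees past the limit, over violating pairs only).
#'
#' @param model A `hand_model`.
#' @param seq A preprocessed `marker_sequence`.
#' @param cfg An [ik_config()].
#' @param activity,session Labels attached to the motion.
#' @return List with `motion` (a `joint_angle_motion`) and `diagnostics`.
#' @export
solve_sequence <- function(model, seq, cfg = ik_config(),
                           activity = NA_character_,
                           session = NA_character_) {
  stopifnot(inherits(seq, "marker_sequence"))
  n <- length(seq$times)
  if (n == 0) stop("empty sequence")
  dofs <- dof_names(model)
  ang <- matrix(NA_real_, n, length(dofs), dimnames = list(NULL, dofs))
  mde <- numeric(n)
  init <- NULL
  for (i in seq_len(n)) {
    sol <- solve_frame(model, seq$positions[i, , ], init = init, cfg = cfg)
    pose <- sol$pose
    mde[i] <- sol$mde
    ang[i, names(pose$angles)] <- pose$angles
    ang[i, c("WRIST_TX", "WRIST_TY", "WRIST_TZ")] <- pose$wrist_position
    e <- matrix_to_euler_xyz(quat_to_matrix(pose$wrist_orientation))
    ang[i, c("WRIST_RX", "WRIST_RY", "WRIST_RZ")] <- rad2deg(e)
    if (cfg$warm_start) init <- pose
  }
  motion <- joint_angle_motion(seq$times, ang, activity = activity,
                               session = session)
  diagnostics <- ik_diagnostics(motion, model, mde_series = mde)
  list(motion = motion, diagnostics = diagnostics)
}

#' Quality diagnostics of a joint-angle motion
#'
#' @param motion A `joint_angle_motion`.
#' @param model A `hand_model` supplying the joint limits.
#' @param mde_series Optional per-frame MDE series (mm) from the solver.
#' @return List with `mde_mean`, `mde_std` (mm), `cvr` (%), `cvm_mean`,
#'   `cvm_std` (degrees over violating pairs) and `mde_series`.
#' @export
ik_diagnostics <- function(motion, model, mde_series = NULL) {
  jt <- model$joints[model$joints$finger != "wrist", ]
  A <- motion$angles[, jt$name, drop = FALSE]
  lo <- matrix(jt$lo, nrow(A), nrow(jt), byrow = TRUE)
  hi <- matrix(jt$hi, nrow(A), nrow(jt), byrow = TRUE)
  excess <- pmax(0, lo - A) + pmax(0, A - hi)
  violating <- excess > 1e-9
  list(
    mde_mean = if (is.null(mde_series)) NA_real_ else mean(mde_series),
    mde_std = if (is.null(mde_series)) NA_real_ else stats::sd(mde_series),
    cvr = 100 * mean(violating),
    cvm_mean = if (any(violating)) mean(excess[violating]) else NA_real_,
    cvm_std = if (sum(violating) > 1) stats::sd(excess[violating]) else NA_real_,
    mde_series = mde_series
  )
}

#' Clip all finger joint angles to the model limits
#'
#' In-limit values are untouched; the operation is idempotent.
#'
#' @param motion A `joint_angle_motion`.
#' @param model A `hand_model`.
#' @return The clipped `joint_angle_motion`.
#' @export
clip_to_limits <- function(motion, model) {
  jt <- model$joints[model$joints$finger != "wrist", ]
  out <- motion
  for (i in seq_len(nrow(jt))) {
    nm <- jt$name[i]
    if (nm %in% colnames(out$angles)) {
      out$angles[, nm] <- pmin(pmax(out$angles[, nm], jt$lo[i]), jt$hi[i])
    }
  }
  out
}

#' Filter takes by IK quality
#'
#' Two filtering styles are offered: a hard mean-distance-error threshold
#' (keep takes with `mde_mean <= threshold_mm`), or keeping the `best_k`
#' takes per activity ranked by `mde_mean` (both may be combined; the
#' threshold is applied first).
#'
#' @param takes List of entries, each a list with `motion` and `diagnostics`
#'   (as produced by [solve_sequence()]).
#' @param threshold_mm MDE threshold in mm, or `NULL` to skip.
#' @param best_k Number of best takes to keep per activity, or `NULL`.
#' @return List with `kept` and `discarded`; the partition is exhaustive.
#' @export
filter_takes <- function(takes, threshold_mm = NULL, best_k = NULL) {
  if (!is.null(threshold_mm) && threshold_mm <= 0) {
    stop("threshold_mm must be positive")
  }
  mde <- vapply(takes, function(t) t$diagnostics$mde_mean, numeric(1))
  keep <- rep(TRUE, length(takes))
  if (!is.null(threshold_mm)) keep <- mde <= threshold_mm
  if (!is.null(best_k)) {
    act <- vapply(takes, function(t) as.character(t$motion$activity),
                  character(1))
    for (a in unique(act)) {
      idx <- which(act == a & keep)
      if (length(idx) > best_k) {
        drop_idx <- idx[order(mde[idx])][-seq_len(best_k)]
        keep[drop_idx] <- FALSE
      }
    }
  }
  list(kept = takes[keep], discarded = takes[!keep])
}

#' Write a joint-angle motion as a CSV motion file
#'
#' First column `Time`, then one column per DOF. An optional diagnostics
#' list is written alongside as a JSON sidecar (`<path>.json`).
#'
#' @param motion A `joint_angle_motion`.
#' @param path Output CSV path.
#' @param diagnostics Optional diagnostics list.
#' @return `path`, invisibly.
#' @export
write_motion_csv <- function(motion, path, diagnostics = NULL) {
  df <- data.frame(Time = motion$times, check.names = FALSE)
  for (cn in colnames(motion$angles)) df[[cn]] <- motion$angles[, cn]
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(diagnostics)) {
    side <- diagnostics
    side$activity <- motion$activity
    side$session <- motion$session
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a joint-angle motion from a CSV motion file
#'
#' @param path CSV path with a `Time` column followed by DOF columns.
#' @param activity,session Labels to attach.
#' @return A `joint_angle_motion`.
#' @export
read_motion_csv <- function(path, activity = NA_character_,
                            session = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"Time" %in% names(df)) stop("motion file must have a 'Time' column")
  joint_angle_motion(df$Time, as.matrix(df[setdiff(names(df), "Time")]),
                     activity = activity, session = session)
}
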
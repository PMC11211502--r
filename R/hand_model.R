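# Kinematic right-hand model: 26 degrees of freedom (6 wrist + 4 per finger),
# 21 markers and 15 candidate sensor sites.
#
# Wrist frame convention: x radial (towards the thumb), y distal (along the
# fingers), z dorsal (out of the back of the hand). Units are meters; joint
# angles are stored in degrees in poses and motion files.

FINGERS <- c("thumb", "index", "middle", "ring", "pinky")

# Default geometry as fractions of hand length (wrist to middle fingertip).
# The palm accounts for 0.55 of hand length; non-thumb finger segments follow
# anthropometric proximal:middle:distal proportions, with per-finger totals
# expressed relative to the middle finger (index = ring at rest, so the
# index:ring ratio of the base model is exactly 1).
.hand_geometry_fractions <- function() {
  list(
    base_offsets = list(
      thumb  = c(0.160, 0.120, -0.020),
      index  = c(0.115, 0.530, 0),
      middle = c(0.000, 0.550, 0),
      ring   = c(-0.115, 0.530, 0),
      pinky  = c(-0.230, 0.470, 0)
    ),
    segments = list(
      thumb  = c(metacarpal = 0.190, proximal = 0.160, distal = 0.120),
      index  = c(proximal = 0.23275, middle = 0.11875, distal = 0.07600),
      middle = c(proximal = 0.24500, middle = 0.12500, distal = 0.08000),
      ring   = c(proximal = 0.23275, middle = 0.11875, distal = 0.07600),
      pinky  = c(proximal = 0.18375, middle = 0.09375, distal = 0.06000)
    )
  )
}

.default_joint_table <- function() {
  rows <- list()
  # thumb: CMC flexion/abduction, MCP, IP
  rows[[1]] <- data.frame(
    name = c("THUMB_CMC_FLEXION", "THUMB_CMC_ABDUCTION", "THUMB_MCP",
             "THUMB_IP"),
    finger = "thumb",
    role = c("CMC_flex", "CMC_abd", "MCP", "IP"),
    axis_x = c(-1, 0, -1, -1), axis_y = 0, axis_z = c(0, 1, 0, 0),
    lo = c(-30, -10, 0, -10), hi = c(60, 60, 60, 80),
    stringsAsFactors = FALSE
  )
  # non-thumb fingers: MCP flexion + abduction, PIP, DIP.
  # Abduction is positive away from the middle finger, hence the sign of the
  # z axis differs between the radial and ulnar side of the hand.
  abd_sign <- c(index = -1, middle = -1, ring = 1, pinky = 1)
  for (f in c("index", "middle", "ring", "pinky")) {
    fu <- toupper(f)
    rows[[length(rows) + 1]] <- data.frame(
      name = c(paste0(fu, "_MCP_FLEXION"), paste0(fu, "_ABDUCTION"),
               paste0(fu, "_PIP"), paste0(fu, "_DIP")),
      finger = f,
      role = c("MCP_flex", "MCP_abd", "PIP", "DIP"),
      axis_x = c(-1, 0, -1, -1), axis_y = 0,
      axis_z = c(0, abd_sign[[f]], 0, 0),
      lo = c(-20, -25, 0, -10), hi = c(90, 25, 110, 90),
      stringsAsFactors = FALSE
    )
  }
  # wrist: 3 translational + 3 rotational DOF (free hand motion)
  rows[[length(rows) + 1]] <- data.frame(
    name = c("WRIST_TX", "WRIST_TY", "WRIST_TZ",
             "WRIST_RX", "WRIST_RY", "WRIST_RZ"),
    finger = "wrist",
    role = "wrist_dof",
    axis_x = c(1, 0, 0, 1, 0, 0), axis_y = c(0, 1, 0, 0, 1, 0),
    axis_z = c(0, 0, 1, 0, 0, 1),
    lo = c(-10, -10, -10, -360, -360, -360),
    hi = c(10, 10, 10, 360, 360, 360),
    stringsAsFactors = FALSE
  )
  do.call(rbind, rows)
}

.marker_table <- function() {
  # Marker numbering 0-20: wrist, then 4 per finger (base joint to tip),
  # thumb first, then index, middle, ring, pinky.
  point_names <- c(
    "wrist",
    "thumb_cmc", "thumb_mcp", "thumb_ip", "thumb_tip",
    "index_mcp", "index_pip", "index_dip", "index_tip",
    "middle_mcp", "middle_pip", "middle_dip", "middle_tip",
    "ring_mcp", "ring_pip", "ring_dip", "ring_tip",
    "pinky_mcp", "pinky_pip", "pinky_dip", "pinky_tip"
  )
  data.frame(
    index = 0:20,
    name = point_names,
    finger = c("wrist", rep(FINGERS, each = 4)),
    stringsAsFactors = FALSE
  )
}

.sensor_site_table <- function() {
  sites <- list()
  for (f in FINGERS) {
    bones <- if (f == "thumb") {
      c("distal", "proximal", "metacarpal")
    } else {
      c("distal", "middle", "proximal")
    }
    sites[[f]] <- data.frame(
      name = paste(f, bones, sep = "_"),
      finger = f, bone = bones, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, sites)
  rownames(out) <- NULL
  out
}

#' Construct the default 26-DOF right-hand model
#'
#' The model is a pure kinematic chain: a 6-DOF wrist (free translation and
#' rotation) and five fingers with 4 DOF each. Non-thumb fingers articulate at
#' the metacarpophalangeal joint (flexion + abduction) and have hinge PIP and
#' DIP joints; the thumb articulates at the carpometacarpal joint (flexion +
#' abduction) and has hinge MCP and IP joints. It carries 21 markers (wrist
#' plus four per finger, numbered 0-20) and 15 candidate sensor sites, three
#' per finger at the midpoints of the distal/middle/proximal phalanges (for
#' the thumb: distal/proximal phalanx and metacarpal).
#'
#' @param hand_length Wrist-to-middle-fingertip distance in meters at rest.
#'   Defaults to the adult population mean of 0.193 m.
#' @return An object of class `hand_model`.
#' @export
#' @examples
#' m <- hand_model_default()
#' nrow(m$joints)  # 26 degrees of freedom
hand_model_default <- function(hand_length = 0.193) {
  stopifnot(hand_length > 0)
  geom <- .hand_geometry_fractions()
  base_offsets <- lapply(geom$base_offsets, function(v) v * hand_length)
  segments <- lapply(geom$segments, function(v) v * hand_length)
  # thumb base frame: local +y points along the thumb ray (rolled towards +x)
  thumb_rot <- rotation_about_axis(c(0, 0, 1), deg2rad(-55))
  base_rots <- list(thumb = thumb_rot, index = diag(3), middle = diag(3),
                    ring = diag(3), pinky = diag(3))
  fingers <- lapply(FINGERS, function(f) {
    list(base_offset = base_offsets[[f]], base_rot = base_rots[[f]],
         segments = segments[[f]])
  })
  names(fingers) <- FINGERS
  finger_totals <- vapply(FINGERS, function(f) {
    segs <- fingers[[f]]$segments
    if (f == "thumb") sum(segs[c("proximal", "distal")]) else sum(segs)
  }, numeric(1))
  model <- structure(list(
    hand_length = hand_length,
    fingers = fingers,
    joints = .default_joint_table(),
    markers = .marker_table(),
    sensor_sites = .sensor_site_table(),
    finger_ratios = finger_totals / finger_totals[["middle"]]
  ), class = "hand_model")
  validate_hand_model(model)
  model
}

#' Validate the structural invariants of a hand model
#'
#' Asserts 26 total DOF, 4 per finger, 21 markers, 15 sensor sites, positive
#' bone lengths and well-ordered joint limits.
#'
#' @param model A `hand_model`.
#' @return The model, invisibly. Errors if any invariant fails.
#' @export
validate_hand_model <- function(model) {
  stopifnot(inherits(model, "hand_model"))
  if (nrow(model$joints) != 26) stop("model must expose exactly 26 DOF")
  for (f in FINGERS) {
    nf <- sum(model$joints$finger == f)
    if (nf != 4) stop(sprintf("finger '%s' must have 4 DOF, has %d", f, nf))
  }
  if (sum(model$joints$finger == "wrist") != 6) {
    stop("wrist must contribute 6 DOF")
  }
  if (nrow(model$markers) != 21) stop("model must define exactly 21 markers")
  if (nrow(model$sensor_sites) != 15) {
    stop("model must define exactly 15 sensor sites")
  }
  for (f in FINGERS) {
    segs <- model$fingers[[f]]$segments
    if (any(segs <= 0)) stop("all bone lengths must be positive")
  }
  if (any(model$joints$lo >= model$joints$hi)) {
    stop("every joint must have lower < upper limit")
  }
  invisible(model)
}

#' Finger joint names of a model (the 20 angular finger DOF)
#' @param model A `hand_model`.
#' @return Character vector of 20 joint names in model order.
#' @export
finger_joint_names <- function(model) {
  model$joints$name[model$joints$finger != "wrist"]
}

#' All 26 DOF column names (finger joints, then wrist DOF)
#' @param model A `hand_model`.
#' @return Character vector of length 26.
#' @export
dof_names <- function(model) {
  c(finger_joint_names(model),
    model$joints$name[model$joints$finger == "wrist"])
}

#' Rescale a hand model to a target hand length and index:ring ratio
#'
#' All geometry is scaled uniformly so the wrist-to-middle-fingertip rest
#' distance equals `hand_length`; the index and ring phalanges are then
#' counter-scaled (geometric mean split, which leaves their combined size
#' unchanged) so the ratio of index to ring total finger length equals
#' `index_ring_ratio`. All other finger proportions are preserved.
#'
#' @param model A `hand_model`.
#' @param hand_length Target wrist-to-middle-fingertip distance (m).
#' @param index_ring_ratio Target index:ring total-length ratio.
#' @return A new `hand_model`.
#' @export
scale_model <- function(model, hand_length, index_ring_ratio = NULL) {
  if (!is.numeric(hand_length) || hand_length <= 0) {
    stop("hand_length must be positive")
  }
  if (is.null(index_ring_ratio)) {
    index_ring_ratio <- model$finger_ratios[["index"]] /
      model$finger_ratios[["ring"]]
  }
  if (index_ring_ratio <= 0) stop("index_ring_ratio must be positive")
  s <- hand_length / model$hand_length
  out <- model
  for (f in FINGERS) {
    out$fingers[[f]]$base_offset <- model$fingers[[f]]$base_offset * s
    out$fingers[[f]]$segments <- model$fingers[[f]]$segments * s
  }
  r0 <- sum(out$fingers$index$segments) / sum(out$fingers$ring$segments)
  si <- sqrt(index_ring_ratio / r0)
  out$fingers$index$segments <- out$fingers$index$segments * si
  out$fingers$ring$segments <- out$fingers$ring$segments / si
  out$hand_length <- hand_length
  finger_totals <- vapply(FINGERS, function(f) {
    segs <- out$fingers[[f]]$segments
    if (f == "thumb") sum(segs[c("proximal", "distal")]) else sum(segs)
  }, numeric(1))
  out$finger_ratios <- finger_totals / finger_totals[["middle"]]
  validate_hand_model(out)
  out
}

#' Serialize a hand model to YAML
#'
#' @param model A `hand_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hand_model <- function(model, path) {
  doc <- list(
    hand_length = model$hand_length,
    fingers = lapply(model$fingers, function(f) {
      list(base_offset = as.numeric(f$base_offset),
           base_rot = as.numeric(f$base_rot),
           segments = as.list(f$segments))
    }),
    joints = lapply(seq_len(nrow(model$joints)), function(i) {
      as.list(model$joints[i, ])
    }),
    finger_ratios = as.list(model$finger_ratios)
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Load a hand model from a YAML document written by [write_hand_model()]
#'
#' The loader revalidates every structural invariant.
#'
#' @param path YAML file path.
#' @return A `hand_model`.
#' @export
read_hand_model <- function(path) {
  doc <- yaml::read_yaml(path)
  fingers <- lapply(doc$fingers, function(f) {
    list(base_offset = as.numeric(f$base_offset),
         base_rot = matrix(as.numeric(f$base_rot), 3, 3),
         segments = unlist(f$segments))
  })
  joints <- do.call(rbind, lapply(doc$joints, function(j) {
    as.data.frame(j, stringsAsFactors = FALSE)
  }))
  model <- structure(list(
    hand_length = doc$hand_length,
    fingers = fingers,
    joints = joints,
    markers = .marker_table(),
    sensor_sites = .sensor_site_table(),
    finger_ratios = unlist(doc$finger_ratios)
  ), class = "hand_model")
  validate_hand_model(model)
  model
}

#' @export
print.hand_model <- function(x, ...) {
  cat("<hand_model> 26 DOF right hand\n")
  cat(sprintf("  hand length: %.4f m\n", x$hand_length))
  cat(sprintf("  markers: %d, sensor sites: %d\n",
              nrow(x$markers), nrow(x$sensor_sites)))
  invisible(x)
}
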
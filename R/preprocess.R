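# Preprocessing of raw key-point sequences: mirroring, per-segment scaling,
# wrist translation and Kabsch rotation onto the model rest pose.

#' Construct a marker sequence
#'
#' @param times Strictly increasing numeric vector (seconds).
#' @param positions `n x 21 x 3` array of key-point positions. Arbitrary
#'   units on input; meters after preprocessing.
#' @param handedness `"right"` or `"left"`.
#' @param source `"mocap"` or `"video_keypoints"`.
#' @return An object of class `marker_sequence`.
#' @export
marker_sequence <- function(times, positions,
                            handedness = c("right", "left"),
                            source = c("mocap", "video_keypoints")) {
  handedness <- match.arg(handedness)
  source <- match.arg(source)
  times <- as.numeric(times)
  if (length(times) < 1) stop("empty sequence")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  d <- dim(positions)
  if (length(d) != 3 || d[1] != length(times) || d[2] != 21 || d[3] != 3) {
    stop("positions must be an n x 21 x 3 array matching times")
  }
  structure(list(times = times, positions = positions,
                 handedness = handedness, source = source),
            class = "marker_sequence")
}

#' @export
print.marker_sequence <- function(x, ...) {
  cat(sprintf("<marker_sequence> %d frames, %s hand, source %s\n",
              length(x$times), x$handedness, x$source))
  invisible(x)
}

#' Detect handedness from the marker geometry of the first frame
#'
#' Uses the sign of the volume spanned by (wrist, thumb CMC, index MCP,
#' pinky MCP). The thumb base sits out of the palm plane, so the tetrahedron
#' is non-degenerate even for a flat hand, and its signed volume flips under
#' mirroring in any coordinate frame.
#'
#' @param positions One frame, `21 x 3`.
#' @return `"right"` or `"left"`.
#' @export
detect_handedness <- function(positions) {
  w <- positions[1, ]
  v1 <- positions[2, ] - w    # thumb CMC
  v2 <- positions[6, ] - w    # index MCP
  v3 <- positions[18, ] - w   # pinky MCP
  vol <- det(cbind(v1, v2, v3))
  # the thumb base is palmar (negative volume) on a right hand
  if (vol <= 0) "right" else "left"
}

#' Mirror a left-hand sequence into a right-hand one
#'
#' Negates x-coordinates about the sagittal plane through the wrist marker
#' (normal to the x-axis). Inter-marker distances are preserved. Applying it
#' to an already right-handed sequence is a warning no-op.
#'
#' @param seq A `marker_sequence`.
#' @return A right-handed `marker_sequence`.
#' @export
mirror_to_right <- function(seq) {
  stopifnot(inherits(seq, "marker_sequence"))
  if (seq$handedness == "right") {
    warning("sequence is already right-handed; mirroring skipped")
    return(seq)
  }
  pos <- seq$positions
  for (i in seq_along(seq$times)) {
    wx <- pos[i, 1, 1]
    pos[i, , 1] <- 2 * wx - pos[i, , 1]
  }
  out <- seq
  out$positions <- pos
  out$handedness <- "right"
  out
}

#' Rescale every hand segment to its model bone length
#'
#' Works outward from the wrist along the 20 hand segments (wrist to each
#' finger base, then along the phalanges), replacing each segment by a vector
#' of the model's rest length in the observed direction, so the chain stays
#' connected and the wrist marker is unchanged. Handles monocular estimators
#' whose bone lengths drift per frame. A zero-length observed segment reuses
#' the previous frame's direction; a zero-length segment in the first frame
#' is an error.
#'
#' @param seq A right-handed `marker_sequence`.
#' @param model A `hand_model`.
#' @return A `marker_sequence` with per-frame segment lengths equal to the
#'   model's.
#' @export
scale_segments <- function(seq, model) {
  stopifnot(inherits(seq, "marker_sequence"))
  if (seq$handedness != "right") stop("scale_segments expects a right-handed sequence")
  se <- .segment_edges(model)
  pos <- seq$positions
  out <- pos
  n <- length(seq$times)
  prev_dir <- matrix(NA_real_, nrow(se$edges), 3)
  for (i in seq_len(n)) {
    for (k in seq_len(nrow(se$edges))) {
      a <- se$edges[k, 1]; b <- se$edges[k, 2]
      v <- pos[i, b, ] - pos[i, a, ]
      len <- sqrt(sum(v^2))
      if (len < 1e-12) {
        if (i == 1 || anyNA(prev_dir[k, ])) {
          stop("zero-length segment in the first frame; cannot infer direction")
        }
        dir <- prev_dir[k, ]
      } else {
        dir <- v / len
      }
      prev_dir[k, ] <- dir
      out[i, b, ] <- out[i, a, ] + dir * se$lengths[k]
    }
  }
  res <- seq
  res$positions <- out
  res
}

#' Translate every frame so the wrist marker coincides with the model wrist
#'
#' @param seq A `marker_sequence`.
#' @param model A `hand_model`; the target is its rest wrist position (the
#'   origin for the default model).
#' @return A translated `marker_sequence`.
#' @export
translate_to_wrist <- function(seq, model) {
  stopifnot(inherits(seq, "marker_sequence"))
  target <- rest_markers(model)[1, ]
  pos <- seq$positions
  for (i in seq_along(seq$times)) {
    shift <- target - pos[i, 1, ]
    pos[i, , ] <- pos[i, , ] + matrix(shift, 21, 3, byrow = TRUE)
  }
  out <- seq
  out$positions <- pos
  out
}

#' Optimal rotation between two paired point sets (Kabsch algorithm)
#'
#' Finds the proper rotation `R` minimizing `sum ||R P_i - Q_i||^2` via the
#' SVD of the cross-covariance, with the standard sign flip of the smallest
#' singular direction to exclude reflections.
#'
#' @param P,Q `n x 3` matrices of paired points, `n >= 3`.
#' @param center Center both sets on their centroids first (default). Set to
#'   `FALSE` to find the optimal rotation about the origin, e.g. when both
#'   sets are already pinned at a common wrist point.
#' @return A `3 x 3` proper rotation matrix (`det = +1`).
#' @export
kabsch_rotation <- function(P, Q, center = TRUE) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3) stop("P and Q must be matching n x 3 matrices")
  if (nrow(P) < 3) stop("at least 3 point pairs are required")
  if (center) {
    P <- sweep(P, 2, colMeans(P))
    Q <- sweep(Q, 2, colMeans(Q))
  }
  H <- t(P) %*% Q
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate (rank < 2) point set; rotation is not determined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  R
}

#' Full preprocessing pipeline for a key-point sequence
#'
#' Applies, in order: mirroring (left hands only), per-segment scaling to the
#' model bone lengths, wrist translation, and a per-frame Kabsch rotation of
#' all markers about the wrist onto the model's rest-pose markers. The
#' per-frame rotation absorbs the arbitrary and possibly drifting coordinate
#' frame of monocular 3D estimators.
#'
#' @param seq A `marker_sequence`.
#' @param model A `hand_model`.
#' @param kabsch_markers Integer marker indices (1-21) used as Kabsch
#'   correspondences; defaults to all 21. `palm_marker_indices()` restricts
#'   the alignment to the rigid palm points, which leaves finger motion and
#'   wrist orientation untouched.
#' @return A preprocessed, model-compatible `marker_sequence` in meters.
#' @export
preprocess_sequence <- function(seq, model, kabsch_markers = 1:21) {
  stopifnot(inherits(seq, "marker_sequence"))
  if (seq$handedness == "left") seq <- mirror_to_right(seq)
  seq <- scale_segments(seq, model)
  seq <- translate_to_wrist(seq, model)
  target <- rest_markers(model)
  wrist <- target[1, ]
  pos <- seq$positions
  for (i in seq_along(seq$times)) {
    Pc <- sweep(pos[i, kabsch_markers, , drop = TRUE], 2, wrist)
    Qc <- sweep(target[kabsch_markers, , drop = TRUE], 2, wrist)
    R <- kabsch_rotation(Pc, Qc, center = FALSE)
    pos[i, , ] <- sweep(sweep(pos[i, , ], 2, wrist) %*% t(R), 2, -wrist)
  }
  out <- seq
  out$positions <- pos
  if (anyNA(out$positions)) stop("NaN in preprocessed positions")
  out
}

#' Indices of the rigid palm markers
#'
#' The wrist, the thumb CMC and the four non-thumb MCP markers do not move
#' with finger articulation; they pin the wrist frame exactly.
#'
#' @return Integer vector of 1-based marker indices.
#' @export
palm_marker_indices <- function() c(1L, 2L, 6L, 10L, 14L, 18L)

#' Read a marker sequence from CSV
#'
#' Expects the header `time, m0_x, m0_y, m0_z, ..., m20_z`; an arbitrary
#' header can be adapted with `col_map`, a character vector of the 64 column
#' names to use in that order (time first), which covers TRC-style exports.
#'
#' @param path CSV file path.
#' @param handedness,source Metadata for the sequence.
#' @param col_map Optional character vector (length 64) naming the time and
#'   coordinate columns in marker order.
#' @return A `marker_sequence`.
#' @export
read_marker_csv <- function(path, handedness = "right", source = "mocap",
                            col_map = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(col_map)) {
    col_map <- c("time", paste0("m", rep(0:20, each = 3), "_",
                                rep(c("x", "y", "z"), 21)))
  }
  missing <- setdiff(col_map, names(df))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  times <- df[[col_map[1]]]
  pos <- array(NA_real_, c(nrow(df), 21, 3))
  for (m in 1:21) {
    for (ax in 1:3) {
      pos[, m, ax] <- df[[col_map[1 + (m - 1) * 3 + ax]]]
    }
  }
  marker_sequence(times, pos, handedness = handedness, source = source)
}

#' Write a marker sequence to CSV (`time, m0_x, ..., m20_z`)
#'
#' @param seq A `marker_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(seq, path) {
  n <- length(seq$times)
  out <- data.frame(time = seq$times)
  for (m in 1:21) {
    for (ax in 1:3) {
      out[[paste0("m", m - 1, "_", c("x", "y", "z")[ax])]] <- seq$positions[, m, ax]
    }
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
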
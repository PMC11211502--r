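# Sensor placement scoring: joint-angle independence and correlation scores
# over a labeled motion dataset, and the resulting ranking of the 15
# candidate phalanx sensor sites.

#' Assemble a labeled motion dataset
#'
#' @param takes List of `joint_angle_motion` objects, each carrying
#'   `activity` and `session` labels.
#' @return A list of class `motion_dataset` with the takes and the
#'   activity/session index.
#' @export
motion_dataset <- function(takes) {
  acts <- vapply(takes, function(t) as.character(t$activity), character(1))
  sess <- vapply(takes, function(t) as.character(t$session), character(1))
  if (anyNA(acts)) stop("every take must carry an activity label")
  structure(list(takes = takes, activity = acts, session = sess,
                 activities = sort(unique(acts))),
            class = "motion_dataset")
}

#' Pearson correlation with the zero-variance convention
#'
#' The quotient of the covariance of two signals and the product of their
#' standard deviations. A constant series carries no movement information,
#' so if either standard deviation is zero the correlation is defined as 0.
#'
#' @param x,y Equal-length numeric series (`n >= 2`).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("series must have at least 2 samples")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  stats::cor(x, y)
}

# Joint column name for (finger, ordinal role index j = 1..4).
# Cross-finger pairing for the redundancy score: thumb roles are paired by
# position in the chain (CMC_flex <-> MCP_flex, CMC_abd <-> abduction,
# MCP <-> PIP, IP <-> DIP).
.joint_by_ordinal <- function(finger, j) {
  if (finger == "thumb") {
    c("THUMB_CMC_FLEXION", "THUMB_CMC_ABDUCTION", "THUMB_MCP", "THUMB_IP")[j]
  } else {
    fu <- toupper(finger)
    c(paste0(fu, "_MCP_FLEXION"), paste0(fu, "_ABDUCTION"),
      paste0(fu, "_PIP"), paste0(fu, "_DIP"))[j]
  }
}

# Named joint of a finger by role label used in scoring formulas.
.joint_by_role <- function(finger, role) {
  fu <- toupper(finger)
  if (finger == "thumb") {
    switch(role, CMC = "THUMB_CMC_FLEXION", MCP = "THUMB_MCP",
           IP = "THUMB_IP", stop("unknown thumb role: ", role))
  } else {
    switch(role, MCP = paste0(fu, "_MCP_FLEXION"), PIP = paste0(fu, "_PIP"),
           DIP = paste0(fu, "_DIP"), stop("unknown role: ", role))
  }
}

# Average of r over sessions within each activity, then equally weighted
# across activities (activity imbalance must not bias the score).
.session_activity_mean_r <- function(ds, col_x, col_y) {
  per_activity <- vapply(ds$activities, function(a) {
    idx <- which(ds$activity == a)
    rs <- vapply(idx, function(i) {
      A <- ds$takes[[i]]$angles
      if (!all(c(col_x, col_y) %in% colnames(A))) {
        stop("missing joint column: ", col_x, " or ", col_y)
      }
      pearson_r(A[, col_x], A[, col_y])
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  mean(per_activity)
}

#' Inter-joint independence of two joints of one finger
#'
#' One minus the absolute value of the session- and activity-averaged
#' Pearson correlation between the two joint-angle series. Each activity is
#' weighted equally regardless of its session count. Note the absolute
#' value is taken of the *averaged* (signed) correlation, so opposite-signed
#' correlations across activities can cancel.
#'
#' @param ds A `motion_dataset`.
#' @param finger Finger name.
#' @param j1,j2 Joint role labels (`"MCP"`, `"PIP"`, `"DIP"`; thumb:
#'   `"CMC"`, `"MCP"`, `"IP"`).
#' @return Independence score in `[0, 1]`.
#' @export
inter_joint_independence <- function(ds, finger, j1, j2) {
  c1 <- .joint_by_role(finger, j1)
  c2 <- .joint_by_role(finger, j2)
  1 - abs(.session_activity_mean_r(ds, c1, c2))
}

#' Degree of redundancy of a finger in one activity
#'
#' For every other finger the Pearson correlation between role-paired joints
#' is averaged over the 4 joint pairs and the activity's sessions; the
#' absolute value of that average measures how well the finger's motion is
#' predicted by the other finger. The redundancy is the maximum over the
#' other fingers.
#'
#' @param ds A `motion_dataset`.
#' @param finger Finger name.
#' @param activity Activity label.
#' @return Redundancy in `[0, 1]`.
#' @export
finger_redundancy <- function(ds, finger, activity) {
  idx <- which(ds$activity == activity)
  if (!length(idx)) stop("unknown activity: ", activity)
  others <- setdiff(FINGERS, finger)
  vals <- vapply(others, function(f2) {
    mean_r <- mean(vapply(1:4, function(j) {
      c1 <- .joint_by_ordinal(finger, j)
      c2 <- .joint_by_ordinal(f2, j)
      mean(vapply(idx, function(i) {
        A <- ds$takes[[i]]$angles
        pearson_r(A[, c1], A[, c2])
      }, numeric(1)))
    }, numeric(1)))
    abs(mean_r)
  }, numeric(1))
  max(vals)
}

#' Inter-finger independence of a finger
#'
#' One minus the finger's best-case (minimum over activities) degree of
#' redundancy: a finger that is uncorrelated with every other finger in at
#' least one activity is fully independent.
#'
#' @param ds A `motion_dataset`.
#' @param finger Finger name.
#' @return Independence in `[0, 1]`.
#' @export
inter_finger_independence <- function(ds, finger) {
  d <- vapply(ds$activities, function(a) finger_redundancy(ds, finger, a),
              numeric(1))
  1 - min(d)
}

# Anatomical tie-break order: thumb to pinky, distal to proximal.
.anatomical_order <- function() {
  unlist(lapply(FINGERS, function(f) {
    bones <- if (f == "thumb") c("distal", "proximal", "metacarpal") else
      c("distal", "middle", "proximal")
    paste(f, bones, sep = "_")
  }))
}

#' Importance scores and ranking of the 15 candidate sensor sites
#'
#' Scores combine inter-joint independence G (within a finger) and
#' inter-finger independence H. Non-thumb fingers: the distal site scores
#' `H_f`; the middle site `G(DIP, PIP) * H_f`; the proximal site
#' `G(PIP, MCP) * G(DIP, MCP) * H_f`. Thumb: distal `H`; proximal
#' `G(IP, MCP) * H`; metacarpal `G(IP, CMC) * G(MCP, CMC) * H`. Sites are
#' ranked by descending score with a deterministic anatomical tie-break
#' (thumb to pinky, distal to proximal).
#'
#' @param ds A `motion_dataset`.
#' @param model A `hand_model` (supplies the candidate site set).
#' @return A list of class `placement_scores` with `G`, `D_fa`, `H`, `I`,
#'   `ranking` (site names, most important first) and `degenerate` (TRUE
#'   when all scores are 0 and the ranking is tie-break only).
#' @export
importance_scores <- function(ds, model = hand_model_default()) {
  if (!length(ds$takes)) stop("dataset is empty")
  H <- vapply(FINGERS, function(f) inter_finger_independence(ds, f),
              numeric(1))
  D_fa <- sapply(ds$activities, function(a) {
    vapply(FINGERS, function(f) finger_redundancy(ds, f, a), numeric(1))
  })
  if (is.null(dim(D_fa))) D_fa <- matrix(D_fa, nrow = 5,
                                         dimnames = list(FINGERS, ds$activities))
  G <- list()
  I <- stats::setNames(numeric(15), .anatomical_order())
  for (f in FINGERS) {
    if (f == "thumb") {
      g_ip_mcp <- inter_joint_independence(ds, f, "IP", "MCP")
      g_ip_cmc <- inter_joint_independence(ds, f, "IP", "CMC")
      g_mcp_cmc <- inter_joint_independence(ds, f, "MCP", "CMC")
      G[[f]] <- c(IP_MCP = g_ip_mcp, IP_CMC = g_ip_cmc, MCP_CMC = g_mcp_cmc)
      I[paste0(f, "_distal")] <- H[[f]]
      I[paste0(f, "_proximal")] <- g_ip_mcp * H[[f]]
      I[paste0(f, "_metacarpal")] <- g_ip_cmc * g_mcp_cmc * H[[f]]
    } else {
      g_dip_pip <- inter_joint_independence(ds, f, "DIP", "PIP")
      g_pip_mcp <- inter_joint_independence(ds, f, "PIP", "MCP")
      g_dip_mcp <- inter_joint_independence(ds, f, "DIP", "MCP")
      G[[f]] <- c(DIP_PIP = g_dip_pip, PIP_MCP = g_pip_mcp,
                  DIP_MCP = g_dip_mcp)
      I[paste0(f, "_distal")] <- H[[f]]
      I[paste0(f, "_middle")] <- g_dip_pip * H[[f]]
      I[paste0(f, "_proximal")] <- g_pip_mcp * g_dip_mcp * H[[f]]
    }
  }
  ord <- order(-I, match(names(I), .anatomical_order()))
  structure(list(G = G, D_fa = D_fa, H = H, I = I,
                 ranking = names(I)[ord],
                 degenerate = all(I < 1e-12)),
            class = "placement_scores")
}

#' @export
print.placement_scores <- function(x, ...) {
  cat("<placement_scores> site ranking (most important first):\n")
  for (i in seq_along(x$ranking)) {
    cat(sprintf("  %2d. %-18s I = %.4f\n", i, x$ranking[i],
                x$I[[x$ranking[i]]]))
  }
  if (x$degenerate) cat("  (degenerate: all scores zero, tie-break order)\n")
  invisible(x)
}

#' Nested candidate sensor sets from a ranking
#'
#' Set `i` holds the `i` highest-ranked sites, so the sets are nested; the
#' complementary worst-`i` sets (lowest-ranked sites) are also emitted for
#' best-versus-worst design comparisons.
#'
#' @param scores A `placement_scores`.
#' @param k Number of sets (`1 <= k <= 15`).
#' @return List with `best` and `worst`, each a list of `k` character
#'   vectors of site names.
#' @export
candidate_sets <- function(scores, k) {
  if (k < 1 || k > 15) stop("k must be between 1 and 15")
  best <- lapply(seq_len(k), function(i) scores$ranking[seq_len(i)])
  worst <- lapply(seq_len(k), function(i) rev(scores$ranking)[seq_len(i)])
  list(best = best, worst = worst)
}

#' Write a placement report (scores, ranking, candidate sets) as JSON
#'
#' @param scores A `placement_scores`.
#' @param path Output JSON path.
#' @param k Number of candidate sets to include.
#' @return `path`, invisibly.
#' @export
write_placement_report <- function(scores, path, k = 7) {
  sets <- candidate_sets(scores, k)
  doc <- list(
    H = as.list(scores$H),
    G = lapply(scores$G, as.list),
    D_fa = apply(scores$D_fa, 2, as.list),
    importance = as.list(scores$I),
    ranking = scores$ranking,
    candidate_sets = sets,
    degenerate = scores$degenerate
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
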
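# Independent oracles and fixture builders used across the suite. Each
# oracle is deliberately written as a separate, naive code path (homogeneous
# transforms, brute-force searches, nested loops) so it cannot share bugs
# with the implementation it checks.

# --- homogeneous-transform FK oracle -------------------------------------

hom_rot <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c <- cos(th); s <- sin(th); C <- 1 - c
  R <- matrix(c(
    a[1] * a[1] * C + c, a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
    a[2] * a[1] * C + a[3] * s, a[2] * a[2] * C + c, a[2] * a[3] * C - a[1] * s,
    a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, a[3] * a[3] * C + c
  ), 3, 3, byrow = TRUE)
  H <- diag(4); H[1:3, 1:3] <- R
  H
}

hom_trans <- function(v) { H <- diag(4); H[1:3, 4] <- v; H }

hom_apply <- function(H, p) as.numeric((H %*% c(p, 1))[1:3])

# Index-finger marker positions for a given (flex, abd, pip, dip), composed
# by hand from the model geometry with 4x4 homogeneous matrices.
oracle_index_markers <- function(model, flex, abd, pip, dip) {
  f <- model$fingers$index
  L <- f$segments
  base <- hom_trans(f$base_offset)
  # model convention: abduction about the finger's abd axis first, then
  # flexion about (-1, 0, 0); index abd axis is (0, 0, -1)
  H1 <- base %*% hom_rot(c(0, 0, -1), abd) %*% hom_rot(c(-1, 0, 0), flex)
  p_mcp <- hom_apply(base, c(0, 0, 0))
  p_pip <- hom_apply(H1 %*% hom_trans(c(0, L[["proximal"]], 0)), c(0, 0, 0))
  H2 <- H1 %*% hom_trans(c(0, L[["proximal"]], 0)) %*% hom_rot(c(-1, 0, 0), pip)
  p_dip <- hom_apply(H2 %*% hom_trans(c(0, L[["middle"]], 0)), c(0, 0, 0))
  H3 <- H2 %*% hom_trans(c(0, L[["middle"]], 0)) %*% hom_rot(c(-1, 0, 0), dip)
  p_tip <- hom_apply(H3 %*% hom_trans(c(0, L[["distal"]], 0)), c(0, 0, 0))
  rbind(mcp = p_mcp, pip = p_pip, dip = p_dip, tip = p_tip)
}

# --- random in-limit poses -----------------------------------------------

random_in_limit_pose <- function(model, margin = 5, wrist = TRUE) {
  jt <- model$joints[model$joints$finger != "wrist", ]
  ang <- stats::setNames(stats::runif(nrow(jt), jt$lo + margin,
                                      jt$hi - margin), jt$name)
  if (wrist) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    q <- gloveforge:::quat_from_axis_angle(ax, stats::runif(1, -pi / 2, pi / 2))
    hand_pose(model, ang, wrist_position = stats::rnorm(3, 0, 0.1),
              wrist_orientation = q)
  } else {
    hand_pose(model, ang)
  }
}

# --- brute-force rotation search oracle ----------------------------------

brute_force_rotation <- function(P, Q, n_samples = 20000) {
  best <- NULL; best_sse <- Inf
  for (i in seq_len(n_samples)) {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- gloveforge:::quat_to_matrix(q)
    sse <- sum((P %*% t(R) - Q)^2)
    if (sse < best_sse) { best_sse <- sse; best <- R }
  }
  list(R = best, sse = best_sse)
}

geodesic_deg <- function(R1, R2) {
  gloveforge:::rad2deg(gloveforge:::rotation_angle_between(R1, R2))
}

# --- placement brute-force oracle (naive nested loops) -------------------

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  if (den == 0) return(0)
  sum((x - mx) * (y - my)) / den
}

oracle_placement <- function(ds) {
  fingers <- c("thumb", "index", "middle", "ring", "pinky")
  acts <- sort(unique(ds$activity))
  col_ord <- function(f, j) {
    if (f == "thumb") {
      c("THUMB_CMC_FLEXION", "THUMB_CMC_ABDUCTION", "THUMB_MCP", "THUMB_IP")[j]
    } else {
      fu <- toupper(f)
      c(paste0(fu, "_MCP_FLEXION"), paste0(fu, "_ABDUCTION"),
        paste0(fu, "_PIP"), paste0(fu, "_DIP"))[j]
    }
  }
  avg_r <- function(c1, c2) {
    tot <- 0
    for (a in acts) {
      idx <- which(ds$activity == a)
      s <- 0
      for (i in idx) s <- s + oracle_pearson(ds$takes[[i]]$angles[, c1],
                                             ds$takes[[i]]$angles[, c2])
      tot <- tot + s / length(idx)
    }
    tot / length(acts)
  }
  G <- function(f, r1, r2) {
    by_role <- function(f, role) {
      fu <- toupper(f)
      if (f == "thumb") {
        switch(role, CMC = "THUMB_CMC_FLEXION", MCP = "THUMB_MCP",
               IP = "THUMB_IP")
      } else {
        switch(role, MCP = paste0(fu, "_MCP_FLEXION"),
               PIP = paste0(fu, "_PIP"), DIP = paste0(fu, "_DIP"))
      }
    }
    1 - abs(avg_r(by_role(f, r1), by_role(f, r2)))
  }
  D <- function(f, a) {
    idx <- which(ds$activity == a)
    best <- -Inf
    for (f2 in setdiff(fingers, f)) {
      tot <- 0
      for (j in 1:4) {
        s <- 0
        for (i in idx) {
          s <- s + oracle_pearson(ds$takes[[i]]$angles[, col_ord(f, j)],
                                  ds$takes[[i]]$angles[, col_ord(f2, j)])
        }
        tot <- tot + s / length(idx)
      }
      best <- max(best, abs(tot / 4))
    }
    best
  }
  H <- function(f) 1 - min(vapply(acts, function(a) D(f, a), numeric(1)))
  I <- c()
  for (f in fingers) {
    h <- H(f)
    if (f == "thumb") {
      I[paste0(f, "_distal")] <- h
      I[paste0(f, "_proximal")] <- G(f, "IP", "MCP") * h
      I[paste0(f, "_metacarpal")] <- G(f, "IP", "CMC") * G(f, "MCP", "CMC") * h
    } else {
      I[paste0(f, "_distal")] <- h
      I[paste0(f, "_middle")] <- G(f, "DIP", "PIP") * h
      I[paste0(f, "_proximal")] <- G(f, "PIP", "MCP") * G(f, "DIP", "MCP") * h
    }
  }
  list(H = vapply(fingers, H, numeric(1)),
       D = sapply(acts, function(a) vapply(fingers, function(f) D(f, a),
                                           numeric(1))),
       I = I)
}

# Small random motion dataset with smooth per-joint series (random Fourier
# series), labeled with activities and sessions.
random_motion_dataset <- function(model, n_activities = 3, n_sessions = 2,
                                  n_frames = 30) {
  dofs <- dof_names(model)
  takes <- list()
  for (a in seq_len(n_activities)) {
    for (s in seq_len(n_sessions)) {
      t <- seq(0, 1, length.out = n_frames)
      ang <- sapply(dofs, function(d) {
        a1 <- stats::rnorm(1, 0, 10); a2 <- stats::rnorm(1, 0, 5)
        ph <- stats::runif(2, 0, 2 * pi)
        a1 * sin(2 * pi * t + ph[1]) + a2 * sin(4 * pi * t + ph[2])
      })
      takes[[length(takes) + 1]] <- joint_angle_motion(
        seq_len(n_frames) / 30, ang,
        activity = paste0("act", a), session = paste0("s", s))
    }
  }
  motion_dataset(takes)
}

# --- weighted F1 brute force via full confusion matrix -------------------

oracle_weighted_f1 <- function(truth, pred) {
  classes <- sort(unique(truth))
  cm <- table(factor(truth, levels = classes),
              factor(pred, levels = unique(c(classes, pred))))
  f1 <- numeric(length(classes))
  for (k in seq_along(classes)) {
    tp <- cm[k, classes[k]]
    fp <- sum(cm[, classes[k]]) - tp
    fn <- sum(cm[k, ]) - tp
    f1[k] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  w <- as.numeric(table(factor(truth, levels = classes)))
  sum(f1 * w) / sum(w)
}

# --- window count enumeration oracle -------------------------------------

oracle_window_count <- function(n_samples, rate, window_s, overlap) {
  w <- as.integer(round(window_s * rate))
  stride <- max(1L, as.integer(round(w * (1 - overlap))))
  count <- 0L
  start <- 1L
  while (start + w - 1L <= n_samples) {
    count <- count + 1L
    start <- start + stride
  }
  count
}

# a short in-limits test gesture used in several files
test_gesture_motion <- function(model, n_frames = 40) {
  tpl <- gesture_template("testwave", list(
    list(time = 0, angles = c()),
    list(time = 0.5, angles = c(INDEX_MCP_FLEXION = 50, INDEX_PIP = 70,
                                INDEX_DIP = 40, MIDDLE_MCP_FLEXION = 35,
                                THUMB_CMC_FLEXION = 30, THUMB_IP = 25)),
    list(time = 1, angles = c())
  ), angle_jitter_sd = 0, duration_sd = 0)
  generate_take(tpl, model, rate = 20, duration = n_frames / 20,
                jitter = FALSE)
}
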
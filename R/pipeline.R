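# Classification pipeline: sensor streams to sliding windows, leakage-safe
# splits, normalization, training-time augmentation, weighted-F1 evaluation
# and the per-candidate-set design report.

#' Simulate multi-sensor streams for a set of takes
#'
#' Runs the IMU simulation for every take and sensor site and stacks the
#' modalities into one channel matrix per take. Channels are named
#' `site|modality|axis` (e.g. `index_distal|accel|x`).
#'
#' @param takes List of `joint_angle_motion` objects.
#' @param model A `hand_model`, or a list of models (one per take, as
#'   produced by hand-size augmentation).
#' @param sites Character vector of sensor site names.
#' @param params An [imu_error_params()].
#' @param noisy Apply the sensor error model.
#' @return A list of streams, each with `times`, `channels` (n x C matrix),
#'   `activity`, `session`, `take_id` and `source_take_id`.
#' @export
simulate_sensor_streams <- function(takes, model, sites,
                                    params = imu_error_params(),
                                    noisy = TRUE) {
  models <- if (inherits(model, "hand_model")) {
    rep(list(model), length(takes))
  } else model
  lapply(seq_along(takes), function(i) {
    take <- takes[[i]]
    trajs <- sensor_site_trajectories(models[[i]], take, sites)
    per_site <- lapply(sites, function(s) {
      traj <- trajs[[s]]
      kin <- resample_trajectory(traj$times, traj$p, traj$q,
                                 params$sample_rate)
      r <- ideal_readings(kin, params)
      if (noisy) r <- apply_error_model(r, params)
      ch <- cbind(r$accel, r$gyro, r$mag)
      colnames(ch) <- paste0(s, "|", rep(c("accel", "gyro", "mag"), each = 3),
                             "|", rep(c("x", "y", "z"), 3))
      list(times = r$times, ch = ch)
    })
    channels <- do.call(cbind, lapply(per_site, `[[`, "ch"))
    src <- take_id(take)  # the source take for augmented motions
    own <- if (is.null(take$meta$source_take)) src else
      paste0(src, "#", take$meta$kind, i)
    list(times = per_site[[1]]$times, channels = channels,
         activity = take$activity, session = take$session,
         take_id = own, source_take_id = src)
  })
}

#' Segment sensor streams into labeled sliding windows
#'
#' Windows of `window_s` seconds slide with stride
#' `window * (1 - overlap)`; only windows wholly inside a stream are kept.
#' Each window is labeled with the activity present throughout most of the
#' window (majority labeling).
#'
#' @param streams Output of [simulate_sensor_streams()]. A stream may carry
#'   a per-sample `labels` vector; otherwise its single `activity` is used.
#' @param window_s Window length in seconds (default 0.5).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.8).
#' @return A list of class `windowed_dataset` with `windows` (list of
#'   C x samples matrices), `labels`, `take_ids`, `source_take_ids`,
#'   `channel_names`, `window_samples` and `rate`.
#' @export
sliding_windows <- function(streams, window_s = 0.5, overlap = 0.8) {
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  rate <- 1 / stats::median(diff(streams[[1]]$times))
  w <- as.integer(round(window_s * rate))
  stride <- max(1L, as.integer(round(w * (1 - overlap))))
  windows <- list(); labels <- character(0)
  take_ids <- character(0); source_ids <- character(0)
  for (st in streams) {
    n <- nrow(st$channels)
    if (n < w) {
      warning("stream shorter than one window; skipped")
      next
    }
    starts <- seq(1L, n - w + 1L, by = stride)
    per_sample <- if (!is.null(st$labels)) st$labels else rep(st$activity, n)
    for (s0 in starts) {
      idx <- s0:(s0 + w - 1L)
      windows[[length(windows) + 1L]] <- t(st$channels[idx, , drop = FALSE])
      tab <- table(per_sample[idx])
      labels <- c(labels, names(tab)[which.max(tab)])
      take_ids <- c(take_ids, st$take_id)
      source_ids <- c(source_ids, st$source_take_id)
    }
  }
  structure(list(windows = windows, labels = labels, take_ids = take_ids,
                 source_take_ids = source_ids,
                 channel_names = rownames(windows[[1]]),
                 window_samples = w, stride = stride, rate = rate,
                 window_s = window_s, overlap = overlap),
            class = "windowed_dataset")
}

#' Expected number of sliding windows for a stream
#'
#' @param n_samples Stream length in samples.
#' @param rate Sample rate (Hz).
#' @param window_s Window length (s).
#' @param overlap Fractional overlap.
#' @return Integer window count.
#' @export
window_count <- function(n_samples, rate, window_s = 0.5, overlap = 0.8) {
  w <- as.integer(round(window_s * rate))
  stride <- max(1L, as.integer(round(w * (1 - overlap))))
  if (n_samples < w) return(0L)
  as.integer((n_samples - w) %/% stride) + 1L
}

#' Leakage-safe train/validation/test split of takes
#'
#' Splitting happens at the take level, stratified by activity, on the
#' *source* takes only; every augmented take then inherits the split of its
#' source take, so no augmented variant of a test gesture can reach the
#' training set.
#'
#' @param take_ids Character vector of take identifiers.
#' @param activities Activity label per take.
#' @param source_ids Source-take identifier per take (equal to `take_ids`
#'   for original takes).
#' @param proportions Train/validation/test proportions summing to 1.
#' @param seed Optional integer seed for the shuffle.
#' @return Named character vector mapping take id to
#'   `"train"`/`"val"`/`"test"`.
#' @export
split_takes <- function(take_ids, activities, source_ids = take_ids,
                        proportions = c(0.6, 0.2, 0.2), seed = NULL) {
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  is_source <- take_ids == source_ids
  src <- unique(take_ids[is_source])
  src_act <- activities[match(src, take_ids)]
  assign <- character(0)
  for (a in unique(src_act)) {
    ids <- sample(src[src_act == a])
    n <- length(ids)
    n_train <- round(proportions[1] * n)
    n_val <- round(proportions[2] * n)
    if (n - n_train - n_val < 1 || n_val < 1 || n_train < 1) {
      stop("fewer takes than splits for activity '", a, "'")
    }
    sp <- c(rep("train", n_train), rep("val", n_val),
            rep("test", n - n_train - n_val))
    assign[ids] <- sp
  }
  out <- assign[source_ids]
  names(out) <- take_ids
  if (anyNA(out)) stop("some takes reference unknown source takes")
  out
}

#' Normalize windows to zero mean and unit variance using training data only
#'
#' Per-channel statistics are computed on the training split and applied to
#' every split, so no information leaks from validation or test data.
#' Channels with zero training variance are mean-centered only.
#'
#' @param wds A `windowed_dataset`.
#' @param split Named split assignment from [split_takes()].
#' @return The normalized `windowed_dataset` (statistics kept in
#'   `$norm_stats`).
#' @export
normalize_windows <- function(wds, split) {
  train_idx <- which(split[wds$take_ids] == "train")
  if (!length(train_idx)) stop("training split is empty")
  train_mat <- do.call(cbind, wds$windows[train_idx])
  mu <- rowMeans(train_mat)
  sdv <- apply(train_mat, 1, stats::sd)
  sdv[sdv == 0] <- 1
  wds$windows <- lapply(wds$windows, function(w) (w - mu) / sdv)
  wds$norm_stats <- list(mean = mu, sd = sdv)
  wds
}

#' Training-time augmentation of a window batch
#'
#' Optionally applies one uniformly random 3D rotation per window, jointly
#' to every sensor's accelerometer/gyroscope/magnetometer vector triplet
#' (emulating unknown sensor mounting orientation), then element-wise
#' multiplicative Gaussian noise with mean 1 and standard deviation
#' `noise_sd`.
#'
#' @param windows List of C x samples window matrices with
#'   `site|modality|axis` row names.
#' @param rotation Apply the random rotation.
#' @param noise_sd Standard deviation of the multiplicative noise
#'   (default 0.2; 0 disables).
#' @return The augmented window list.
#' @export
train_time_augment <- function(windows, rotation = TRUE, noise_sd = 0.2) {
  ch <- rownames(windows[[1]])
  triplets <- NULL
  if (rotation) {
    key <- sub("\\|[xyz]$", "", ch)
    triplets <- split(seq_along(ch), key)
    triplets <- triplets[vapply(triplets, length, integer(1)) == 3]
  }
  lapply(windows, function(w) {
    if (rotation) {
      R <- random_rotation()
      for (idx in triplets) w[idx, ] <- R %*% w[idx, , drop = FALSE]
    }
    if (noise_sd > 0) {
      w <- w * matrix(stats::rnorm(length(w), 1, noise_sd), nrow(w), ncol(w))
    }
    w
  })
}

#' Per-class and support-weighted F1 score
#'
#' Per class, `F1 = 2 TP / (2 TP + FP + FN)`; the weighted score averages
#' class F1 values with weights proportional to class support in the truth.
#' Classes absent from the truth are excluded with a warning.
#'
#' @param truth,pred Character vectors of true and predicted labels.
#' @return List with `per_class` (named F1 vector), `support` and
#'   `weighted_f1`.
#' @export
f1_scores <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  classes <- sort(unique(truth))
  extra <- setdiff(unique(pred), classes)
  if (length(extra)) {
    warning("predicted class(es) absent from truth excluded: ",
            paste(extra, collapse = ", "))
  }
  per_class <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  support <- as.numeric(table(factor(truth, levels = classes)))
  list(per_class = per_class, support = support,
       weighted_f1 = sum(per_class * support / sum(support)))
}

#' Summary-feature representation of windows
#'
#' Five order-free features per channel: mean, standard deviation, minimum,
#' maximum and the root-mean-square of the first difference (a bandwidth
#' proxy).
#'
#' @param windows List of C x samples window matrices.
#' @param channels Optional channel-name subset.
#' @return Numeric feature matrix, one row per window.
#' @export
window_features <- function(windows, channels = NULL) {
  feat <- t(vapply(windows, function(w) {
    if (!is.null(channels)) w <- w[channels, , drop = FALSE]
    as.numeric(apply(w, 1, function(x) {
      c(mean(x), stats::sd(x), min(x), max(x), sqrt(mean(diff(x)^2)))
    }))
  }, numeric(5 * (if (is.null(channels)) nrow(windows[[1]]) else length(channels)))))
  feat
}

#' Random-forest window classifier (fit/predict contract)
#'
#' The reference classifier for design evaluation: summary features per
#' channel feeding a random forest. Any object with the same `fit(x, y)` /
#' `predict(model, x)` contract on window lists can be substituted.
#'
#' @param num_trees Number of trees.
#' @param channels Optional channel subset the classifier sees.
#' @return A list of class `window_classifier` with `fit` and `predict`.
#' @export
classifier_ranger <- function(num_trees = 200, channels = NULL) {
  structure(list(
    fit = function(windows, labels) {
      x <- window_features(windows, channels)
      df <- as.data.frame(x)
      df$.label <- factor(labels)
      ranger::ranger(.label ~ ., data = df, num.trees = num_trees,
                     num.threads = 1)
    },
    predict = function(model, windows) {
      x <- as.data.frame(window_features(windows, channels))
      as.character(stats::predict(model, x)$predictions)
    },
    channels = channels
  ), class = "window_classifier")
}

#' Train on the training split and evaluate a classifier on the test split
#'
#' The validation weighted F1 is reported alongside for model selection by
#' callers that compare several fitted candidates.
#'
#' @param clf A classifier honouring the `fit`/`predict` contract.
#' @param wds A (normalized) `windowed_dataset`.
#' @param split Split assignment from [split_takes()].
#' @return List with `test` and `val` F1 summaries (see [f1_scores()]) and
#'   the fitted model.
#' @export
evaluate_classifier <- function(clf, wds, split) {
  sp <- split[wds$take_ids]
  tr <- which(sp == "train"); va <- which(sp == "val"); te <- which(sp == "test")
  if (!length(te)) stop("test split is empty")
  fitted <- clf$fit(wds$windows[tr], wds$labels[tr])
  val <- if (length(va)) {
    f1_scores(wds$labels[va], clf$predict(fitted, wds$windows[va]))
  } else NULL
  test <- f1_scores(wds$labels[te], clf$predict(fitted, wds$windows[te]))
  list(test = test, val = val, model = fitted)
}

#' Design report over candidate sensor sets
#'
#' Trains one classifier per candidate set (and optionally per worst set)
#' on the channel subset belonging to that set's sites and tabulates the
#' weighted test F1 together with hardware-independent cost proxies
#' (channel and feature counts).
#'
#' @param wds A normalized `windowed_dataset` containing all channels.
#' @param split Split assignment.
#' @param sets Output of [candidate_sets()] (or a list of site-name
#'   vectors under `$best`).
#' @param classifier_factory Function of a channel subset returning a
#'   fit/predict classifier; defaults to [classifier_ranger()].
#' @param include_worst Also evaluate the complementary worst sets.
#' @param seed Optional seed fixed before each training run, making the
#'   report deterministic.
#' @return A data frame of class `design_report`: one row per evaluated
#'   set with `config`, `n_sensors`, `sites`, `weighted_f1`, `val_f1`,
#'   `n_channels`, `n_features`.
#' @export
design_report <- function(wds, split, sets,
                          classifier_factory = function(ch)
                            classifier_ranger(channels = ch),
                          include_worst = TRUE, seed = NULL) {
  eval_set <- function(sites, config, i) {
    ch <- wds$channel_names[sub("\\|.*$", "", wds$channel_names) %in% sites]
    if (!is.null(seed)) set.seed(seed + i)
    clf <- classifier_factory(ch)
    res <- evaluate_classifier(clf, wds, split)
    data.frame(config = config, n_sensors = length(sites),
               sites = paste(sites, collapse = "+"),
               weighted_f1 = res$test$weighted_f1,
               val_f1 = if (is.null(res$val)) NA_real_ else res$val$weighted_f1,
               n_channels = length(ch), n_features = 5 * length(ch),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_along(sets$best)) {
    rows[[length(rows) + 1]] <- eval_set(sets$best[[i]], "best", i)
  }
  if (include_worst && !is.null(sets$worst)) {
    for (i in seq_along(sets$worst)) {
      rows[[length(rows) + 1]] <- eval_set(sets$worst[[i]], "worst", 100 + i)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("design_report", class(out))
  out
}

#' Write a design report as JSON plus a Markdown table
#'
#' @param report A `design_report`.
#' @param path Output JSON path; a `.md` table is written alongside.
#' @return `path`, invisibly.
#' @export
write_design_report <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, digits = NA,
                       pretty = TRUE)
  md <- c("| config | sensors | weighted F1 | channels |",
          "|---|---|---|---|",
          sprintf("| %s | %d | %.3f | %d |", report$config,
                  report$n_sensors, report$weighted_f1, report$n_channels))
  writeLines(md, sub("\\.json$", ".md", path))
  invisible(path)
}
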
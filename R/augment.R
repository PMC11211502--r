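# Dataset augmentation: hand-size resampling and key-pose time warping.

#' Anthropometric hand-size distribution
#'
#' Hand length (wrist to middle fingertip) is modeled as a normal
#' distribution with mean 19.3 cm and standard deviation 1.25 cm; the
#' index:ring finger length ratio as a normal with mean 1.0 and standard
#' deviation 0.05. Draws are truncated to +/- 4 standard deviations to
#' exclude non-physical hands.
#'
#' @param length_mean,length_sd Hand length parameters in meters.
#' @param ratio_mean,ratio_sd Index:ring ratio parameters (dimensionless).
#' @return A list of class `hand_dimension_distribution`.
#' @export
hand_dimension_distribution <- function(length_mean = 0.193,
                                        length_sd = 0.0125,
                                        ratio_mean = 1.0,
                                        ratio_sd = 0.05) {
  stopifnot(length_sd > 0, ratio_sd > 0)
  structure(list(length_mean = length_mean, length_sd = length_sd,
                 ratio_mean = ratio_mean, ratio_sd = ratio_sd),
            class = "hand_dimension_distribution")
}

.rnorm_trunc4 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- abs(x - mean) > 4 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > 4 * sd
  }
  x
}

#' Sample hand dimensions for augmentation
#'
#' @param dist A [hand_dimension_distribution()].
#' @param n Number of draws.
#' @return A data frame with columns `hand_length` (m) and
#'   `index_ring_ratio`.
#' @export
sample_hand_dimensions <- function(dist = hand_dimension_distribution(),
                                   n = 1) {
  data.frame(
    hand_length = .rnorm_trunc4(n, dist$length_mean, dist$length_sd),
    index_ring_ratio = .rnorm_trunc4(n, dist$ratio_mean, dist$ratio_sd)
  )
}

#' Hand-size augmentation
#'
#' Small changes in hand geometry do not change the gesture class, and the
#' joint-angle representation is size-free: each variant pairs the
#' *unchanged* joint-angle motion with a resized hand model, so the
#' variation appears only downstream, in the simulated sensor trajectories.
#'
#' @param motion A `joint_angle_motion`.
#' @param base_model The `hand_model` to resize.
#' @param dist A [hand_dimension_distribution()].
#' @param n_variants Number of variants to generate.
#' @return A list of variants, each a list with `motion` (identical angles,
#'   provenance in `$meta`), `model`, `hand_length` and `index_ring_ratio`.
#' @export
hand_size_augment <- function(motion, base_model,
                              dist = hand_dimension_distribution(),
                              n_variants = 1) {
  if (n_variants <= 0) return(list())
  dims <- sample_hand_dimensions(dist, n_variants)
  lapply(seq_len(n_variants), function(i) {
    scaled <- scale_model(base_model, dims$hand_length[i],
                          dims$index_ring_ratio[i])
    m <- motion
    m$meta <- list(kind = "hand_size",
                   source_take = take_id(motion),
                   hand_length = dims$hand_length[i],
                   index_ring_ratio = dims$index_ring_ratio[i])
    list(motion = m, model = scaled, hand_length = dims$hand_length[i],
         index_ring_ratio = dims$index_ring_ratio[i])
  })
}

#' Identifier of a take (activity/session pair)
#' @param motion A `joint_angle_motion`.
#' @return A character scalar.
#' @export
take_id <- function(motion) {
  if (!is.null(motion$meta$source_take)) return(motion$meta$source_take)
  paste(motion$activity, motion$session, sep = "/")
}

#' Variance-trace profile of a motion
#'
#' For every sliding analysis window the covariance matrix of the windowed
#' joint-angle channels is eigendecomposed, the eigenvectors are scaled by
#' the square roots of their eigenvalues to form `Q`, and
#' `D = sqrt(Tr(Q Q^T))` — the square root of the total windowed variance —
#' is recorded. `D` summarises how much the motion as a whole is changing
#' around each frame; its prominent local extrema mark the key poses.
#'
#' @param motion A `joint_angle_motion`.
#' @param window_length Analysis window length in frames (`>= 2`).
#' @param columns Channels to analyse; defaults to all non-wrist angle
#'   columns.
#' @return A list of class `variance_profile` with `D`, `D_norm` (normalized
#'   to `[0, 1]` over the take), `frame_index` (window centers) and
#'   `window_length`.
#' @export
variance_trace <- function(motion, window_length = 5, columns = NULL) {
  if (window_length < 2) stop("window_length must be at least 2 frames")
  n <- length(motion$times)
  if (window_length > n) stop("window longer than the take")
  if (is.null(columns)) {
    columns <- grep("^WRIST_T", colnames(motion$angles), value = TRUE,
                    invert = TRUE)
  }
  A_full <- motion$angles[, columns, drop = FALSE]
  n_win <- n - window_length + 1
  D <- numeric(n_win)
  for (i in seq_len(n_win)) {
    A <- A_full[i:(i + window_length - 1), , drop = FALSE]
    C <- stats::cov(A)
    ev <- eigen(C, symmetric = TRUE)
    Q <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow = length(ev$values))
    D[i] <- sqrt(sum(Q^2))
  }
  rng <- range(D)
  D_norm <- if (diff(rng) < 1e-12) rep(0, n_win) else (D - rng[1]) / diff(rng)
  structure(list(D = D, D_norm = D_norm,
                 frame_index = seq_len(n_win) + (window_length - 1) %/% 2,
                 window_length = window_length, n_frames = n),
            class = "variance_profile")
}

#' Time-warp configuration
#'
#' @param noise_bound Bound of the multiplicative time-adjustment noise;
#'   each inter-key-pose duration is multiplied by `1 + u` with
#'   `u ~ Uniform(-noise_bound, noise_bound)`. Default 0.4.
#' @param prominence_threshold Minimum prominence of a key-pose extremum, as
#'   a fraction of the normalized variance-trace range.
#' @param butterworth_order Order of the low-pass filter applied per warped
#'   segment to suppress resampling end effects.
#' @param butterworth_cutoff Cutoff as a fraction of the Nyquist frequency.
#' @return A list of class `warp_config`.
#' @export
warp_config <- function(noise_bound = 0.4, prominence_threshold = 0.1,
                        butterworth_order = 4, butterworth_cutoff = 0.3) {
  if (noise_bound < 0 || noise_bound >= 1) {
    stop("noise_bound must be in [0, 1)")
  }
  structure(list(noise_bound = noise_bound,
                 prominence_threshold = prominence_threshold,
                 butterworth_order = butterworth_order,
                 butterworth_cutoff = butterworth_cutoff),
            class = "warp_config")
}

# Prominence of local extrema: for each candidate peak the bases are the
# minima between the peak and the nearest higher peak (or the series edge)
# on either side; prominence = peak height minus the higher base.
.prominent_peaks <- function(x, min_prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  peaks <- which(vapply(2:(n - 1), function(i) {
    x[i] > x[i - 1] && x[i] >= x[i + 1]
  }, logical(1))) + 1L
  keep <- logical(length(peaks))
  for (k in seq_along(peaks)) {
    i <- peaks[k]
    left <- x[1:i]
    higher_l <- which(left > x[i])
    lbase <- min(left[(if (length(higher_l)) max(higher_l) else 1):i])
    right <- x[i:n]
    higher_r <- which(right > x[i])
    rbase <- min(right[1:(if (length(higher_r)) min(higher_r) else length(right))])
    prom <- x[i] - max(lbase, rbase)
    keep[k] <- prom >= min_prominence
  }
  peaks[keep]
}

#' Extract key-pose frame indices from a variance profile
#'
#' Key poses are prominence-qualified local minima and maxima of the
#' normalized variance trace; the first and last frame of the take are
#' always included.
#'
#' @param profile A `variance_profile` from [variance_trace()].
#' @param cfg A [warp_config()].
#' @return Strictly increasing integer frame indices.
#' @export
extract_key_poses <- function(profile, cfg = warp_config()) {
  d <- profile$D_norm
  if (length(d) < 3) {
    return(unique(c(1L, as.integer(profile$n_frames))))
  }
  maxima <- .prominent_peaks(d, cfg$prominence_threshold)
  minima <- .prominent_peaks(-d, cfg$prominence_threshold)
  as.integer(sort(unique(c(1L, profile$frame_index[sort(c(maxima, minima))],
                           profile$n_frames))))
}

#' Fourier-method resampling of a uniformly sampled signal
#'
#' Resamples `x` to `n_out` samples through its discrete Fourier transform
#' (spectrum truncation or zero padding), the same mechanism as
#' `scipy.signal.resample`.
#'
#' @param x Numeric vector.
#' @param n_out Target number of samples (`>= 2`).
#' @return Numeric vector of length `n_out`.
#' @export
resample_fourier <- function(x, n_out) {
  n <- length(x)
  if (n_out < 2) stop("n_out must be at least 2")
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(real = numeric(n_out), imaginary = numeric(n_out))
  m <- min(n, n_out)
  half <- m %/% 2
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half >= 1) Y[(n_out - half + 1):n_out] <- X[(n - half + 1):n]
  if (m %% 2 == 0) {
    if (n_out > n) {
      # upsampling: split the Nyquist bin symmetrically
      Y[half + 1] <- X[half + 1] / 2
      Y[n_out - half + 1] <- X[half + 1] / 2
    } else {
      # downsampling: fold the two bins that alias onto the new Nyquist
      Y[half + 1] <- X[half + 1] + X[n - half + 1]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Draw multiplicative time-adjustment noise
#'
#' @param n Number of draws.
#' @param bound Noise bound; draws are `Uniform(-bound, bound)`.
#' @return Numeric vector of length `n`.
#' @export
draw_warp_noise <- function(n, bound = 0.4) {
  stats::runif(n, -bound, bound)
}

# Warp one channel segment to m_new samples: detrend through the endpoints,
# Fourier-resample the residual, restore the trend on the new grid, low-pass,
# and re-pin the endpoints.
.warp_segment_channel <- function(x, m_new, cfg) {
  m <- length(x)
  t_old <- seq(0, 1, length.out = m)
  t_new <- seq(0, 1, length.out = m_new)
  # work on the endpoint-detrended residual: it vanishes at both ends, so
  # both the Fourier periodic extension and the filter see no edge jump
  r <- resample_fourier(x - (x[1] + (x[m] - x[1]) * t_old), m_new)
  if (m_new > 3 * (cfg$butterworth_order + 1)) {
    bf <- signal::butter(cfg$butterworth_order, cfg$butterworth_cutoff)
    # odd-reflection padding suppresses filtfilt edge transients
    p <- min(3L * (cfg$butterworth_order + 1L), m_new - 1L)
    padded <- c(-rev(r[2:(p + 1)]), r, -rev(r[(m_new - p):(m_new - 1)]))
    filtered <- as.numeric(signal::filtfilt(bf, padded))
    r <- filtered[(p + 1):(p + m_new)]
  }
  # re-pin the endpoints so segments join without instantaneous jumps and
  # key-pose angles are preserved
  r <- r - r[1] - (r[m_new] - r[1]) * t_new
  r + x[1] + (x[m] - x[1]) * t_new
}

#' Key-pose time-warp augmentation of a motion
#'
#' Each inter-key-pose duration is multiplied by `1 + u` with bounded
#' uniform noise `u`, the motion between poses is resampled by the Fourier
#' method, low-pass filtered to suppress end effects, and the segments are
#' rejoined with aligned endpoints, so the warped take is faster or slower
#' between poses but passes through the same key poses.
#'
#' @param motion A `joint_angle_motion` (uniformly sampled).
#' @param key_frames Key-pose frame indices (from [extract_key_poses()]);
#'   at least 2.
#' @param cfg A [warp_config()].
#' @param u Optional fixed noise vector (one value per inter-key-pose
#'   segment), e.g. to replay a previous warp; drawn uniformly when `NULL`.
#' @return A warped `joint_angle_motion`; the drawn noise vector and source
#'   take are recorded in `$meta`.
#' @export
time_warp <- function(motion, key_frames, cfg = warp_config(), u = NULL) {
  key_frames <- sort(unique(as.integer(key_frames)))
  if (length(key_frames) < 2) stop("at least 2 key frames are required")
  n <- length(motion$times)
  if (key_frames[1] != 1 || key_frames[length(key_frames)] != n) {
    key_frames <- sort(unique(c(1L, key_frames, n)))
  }
  dt <- stats::median(diff(motion$times))
  n_seg <- length(key_frames) - 1
  fixed_u <- u
  if (!is.null(fixed_u) && length(fixed_u) != n_seg) {
    stop("u must have one value per inter-key-pose segment")
  }
  u <- numeric(n_seg)
  segs <- vector("list", n_seg)
  for (s in seq_len(n_seg)) {
    idx <- key_frames[s]:key_frames[s + 1]
    m <- length(idx)
    repeat {
      u[s] <- if (!is.null(fixed_u)) fixed_u[s] else
        if (cfg$noise_bound == 0) 0 else draw_warp_noise(1, cfg$noise_bound)
      m_new <- as.integer(round((m - 1) * (1 + u[s]))) + 1L
      if (m_new >= 2) break
      if (!is.null(fixed_u)) stop("fixed u yields a segment shorter than 2 samples")
    }
    seg <- matrix(NA_real_, m_new, ncol(motion$angles),
                  dimnames = list(NULL, colnames(motion$angles)))
    for (j in seq_len(ncol(motion$angles))) {
      seg[, j] <- .warp_segment_channel(motion$angles[idx, j], m_new, cfg)
    }
    segs[[s]] <- seg
  }
  # join segments, dropping the duplicated key-pose sample at each boundary
  joined <- segs[[1]]
  if (n_seg > 1) {
    for (s in 2:n_seg) joined <- rbind(joined, segs[[s]][-1, , drop = FALSE])
  }
  out <- joint_angle_motion(
    times = motion$times[1] + dt * (seq_len(nrow(joined)) - 1),
    angles = joined, activity = motion$activity, session = motion$session
  )
  out$meta <- list(kind = "gesture_style", source_take = take_id(motion),
                   u = u, key_frames = key_frames)
  out
}
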
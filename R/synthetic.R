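# Synthetic-study generation: scenes with moving luminance blobs and circular
# head ROIs, gaze driven by a known linear combination of predictors,
# affective ratings with a target inter-rater consistency, and stimulus-locked
# cardiac / electrodermal responses.

#' Scene specification
#'
#' Geometry and content of a synthetic video: moving Gaussian luminance blobs
#' and circular head-like regions (rendered discs whose tracks are recorded
#' as ROI annotations). Defaults emulate 20 s clips at 1280 x 720 / 30 fps;
#' reduced sizes keep the 32 x 18 grid exact whenever `width_px` is a
#' multiple of 32 and `height_px` a multiple of 18.
#'
#' @param width_px,height_px frame size in pixels.
#' @param n_frames number of frames.
#' @param fps frame rate in Hz.
#' @param n_blobs number of moving luminance blobs.
#' @param n_heads number of circular social ROIs.
#' @param head_radius_px head radius in pixels (constant within a video).
#' @param motion_speed_px_per_frame trajectory speed.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(width_px = 1280, height_px = 720, n_frames = 600,
                       fps = 30, n_blobs = 3, n_heads = 2,
                       head_radius_px = 0.055 * width_px,
                       motion_speed_px_per_frame = 0.004 * width_px) {
  stopifnot_scalar(width_px, "width_px", integer = TRUE)
  stopifnot_scalar(height_px, "height_px", integer = TRUE)
  stopifnot_scalar(n_frames, "n_frames", integer = TRUE)
  stopifnot_scalar(fps, "fps")
  if (n_blobs < 0 || n_heads < 0) stop("blob/head counts must be >= 0")
  if (head_radius_px <= 0) stop("'head_radius_px' must be positive")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 n_frames = as.integer(n_frames), fps = fps,
                 n_blobs = as.integer(n_blobs), n_heads = as.integer(n_heads),
                 head_radius_px = head_radius_px,
                 motion_speed_px_per_frame = motion_speed_px_per_frame),
            class = "scene_spec")
}

## straight trajectory with reflecting boundaries on [lim_lo, lim_hi]
reflect_path <- function(p0, v, n, lim_lo, lim_hi) {
  span <- lim_hi - lim_lo
  if (span <= 0) return(rep((lim_lo + lim_hi) / 2, n))
  raw <- p0 + v * (0:(n - 1)) - lim_lo
  m <- raw %% (2 * span)
  lim_lo + ifelse(m > span, 2 * span - m, m)
}

#' Generate a synthetic scene
#'
#' Renders `n_frames` RGB frames on a mid-grey background: `n_blobs`
#' tinted Gaussian luminance blobs and `n_heads` skin-toned discs, all moving
#' on straight trajectories with reflecting boundaries (never clipped at the
#' frame edge). Head tracks are returned as circular-ROI annotations, one row
#' per head per frame.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed; output is a pure function of `(spec, seed)`.
#' @return List with `frames` (array `h x w x 3 x n_frames`, values in
#'   `[0, 1]`) and `roi` (data.frame `frame` (0-based), `cx_px`, `cy_px`,
#'   `r_px`; empty when `n_heads = 0`).
#' @export
make_scene <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$width_px; h <- spec$height_px; n <- spec$n_frames
  with_seed(seed, {
    frames <- array(0.5, c(h, w, 3, n))
    xs <- 0:(w - 1); ys <- 0:(h - 1)
    track <- function(margin) {
      ang <- stats::runif(1, 0, 2 * pi)
      list(x = reflect_path(stats::runif(1, margin, w - 1 - margin),
                            spec$motion_speed_px_per_frame * cos(ang), n,
                            margin, w - 1 - margin),
           y = reflect_path(stats::runif(1, margin, h - 1 - margin),
                            spec$motion_speed_px_per_frame * sin(ang), n,
                            margin, h - 1 - margin))
    }
    if (spec$n_blobs > 0) {
      sig <- 0.04 * w
      for (b in seq_len(spec$n_blobs)) {
        tr <- track(2 * sig)
        tint <- stats::runif(3, 0.3, 1)
        amp <- stats::runif(1, 0.3, 0.5)
        for (t in seq_len(n)) {
          g <- amp * exp(-outer((ys - tr$y[t])^2, (xs - tr$x[t])^2, "+") /
                           (2 * sig^2))
          for (c in 1:3) frames[, , c, t] <- frames[, , c, t] + tint[c] * g
        }
      }
    }
    roi <- NULL
    if (spec$n_heads > 0) {
      r <- spec$head_radius_px
      skin <- c(0.87, 0.72, 0.53)
      for (k in seq_len(spec$n_heads)) {
        tr <- track(r)
        roi <- rbind(roi, data.frame(frame = 0:(n - 1), cx_px = tr$x,
                                     cy_px = tr$y, r_px = r))
        for (t in seq_len(n)) {
          disc <- outer((ys - tr$y[t])^2, (xs - tr$x[t])^2, "+") <= r^2
          for (c in 1:3)
            frames[, , c, t] <- ifelse(disc, skin[c], frames[, , c, t])
        }
      }
      roi <- roi[order(roi$frame), , drop = FALSE]
      rownames(roi) <- NULL
    } else {
      roi <- data.frame(frame = integer(0), cx_px = numeric(0),
                        cy_px = numeric(0), r_px = numeric(0))
    }
    frames[frames > 1] <- 1
    frames[frames < 0] <- 0
    list(frames = frames, roi = roi)
  })
}

#' Ground-truth generating parameters
#'
#' Standardized linear-predictor weights and random-intercept spreads used by
#' the gaze generator. Defaults mirror the magnitudes typically reported for
#' naturalistic dynamic scenes (moderate central bias, similarly strong
#' saliency and social-ROI effects, a small negative saliency x ROI
#' interaction) with moderate participant and video heterogeneity.
#'
#' @param beta_centrality,beta_saliency,beta_roi,beta_interaction linear
#'   weights on the z-standardized grid predictors (`beta_interaction`
#'   multiplies the saliency x ROI product).
#' @param participant_sd,video_sd random-intercept standard deviations
#'   (>= 0). Note that intercepts are constant across cells within a frame
#'   and cancel in the generative softmax, so they do not move cell choices;
#'   they are retained for contract completeness.
#' @param beta_participant_sd SD of stable per-participant offsets added to
#'   the centrality/saliency/ROI weights by [make_study()]; this is what
#'   creates the stable interindividual differences the consistency
#'   analysis measures (default 0.15).
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(beta_centrality = 0.3, beta_saliency = 0.5,
                         beta_roi = 0.5, beta_interaction = -0.1,
                         participant_sd = 0.2, video_sd = 0.2,
                         beta_participant_sd = 0.15) {
  if (participant_sd < 0 || video_sd < 0 || beta_participant_sd < 0)
    stop("heterogeneity standard deviations must be >= 0")
  structure(list(beta_centrality = beta_centrality,
                 beta_saliency = beta_saliency, beta_roi = beta_roi,
                 beta_interaction = beta_interaction,
                 participant_sd = participant_sd, video_sd = video_sd,
                 beta_participant_sd = beta_participant_sd),
            class = "ground_truth")
}

#' Draw fixated grid cells from a softmax over cell utilities
#'
#' Cells are selected with probability proportional to `exp(eta)`; this is
#' the generative conditional-multinomial link of the synthetic gaze model
#' (the estimation side uses case-control probit, so generated and estimated
#' weights agree in sign and order, not numerically).
#'
#' @param eta numeric vector of cell utilities.
#' @param n number of draws.
#' @param seed integer seed.
#' @return Integer vector of 0-based cell indices.
#' @export
draw_fixated_cells <- function(eta, n, seed = 1L) {
  p <- exp(eta - max(eta))
  p <- p / sum(p)
  with_seed(seed, sample.int(length(eta), n, replace = TRUE, prob = p)) - 1L
}

## Linear cell utilities of the generative gaze model: z-standardize the grid
## predictors within the video (zero-variance predictors dropped with a
## warning) and combine them with the ground-truth weights. Returns an
## n_frames x n_cells matrix. Intercepts are constant within a frame and
## cancel in the softmax, so they are not included here.
cell_utilities <- function(cells, truth, n_frames, n_cells) {
  zstd <- function(x, name) {
    s <- stats::sd(as.vector(x))
    if (!is.finite(s) || s == 0) {
      warning(sprintf("zero-variance predictor '%s' dropped from the gaze model",
                      name))
      return(NULL)
    }
    (x - mean(as.vector(x))) / s
  }
  cen <- zstd(matrix(as.vector(cells$centrality), n_frames, n_cells,
                     byrow = TRUE), "centrality")
  sal <- zstd(cells$saliency, "saliency")
  roi <- zstd(cells$roi, "roi")
  eta <- matrix(0, n_frames, n_cells)
  if (!is.null(cen)) eta <- eta + truth$beta_centrality * cen
  if (!is.null(sal)) eta <- eta + truth$beta_saliency * sal
  if (!is.null(roi)) eta <- eta + truth$beta_roi * roi
  if (!is.null(sal) && !is.null(roi))
    eta <- eta + truth$beta_interaction * sal * roi
  eta
}

#' Simulate one trial's gaze stream
#'
#' Per video frame one grid cell is drawn with probability proportional to
#' `exp(eta)`, where `eta` combines the ground-truth weights with the cell's
#' grid predictors (z-standardized within the video across frames and cells;
#' zero-variance predictors are dropped with a warning) and the trial's
#' participant and video intercepts. Gaze samples within the frame interval
#' sit at the fixated cell's centre plus isotropic Gaussian jitter. A
#' pre-stimulus fixation-cross segment (centre + jitter) is emitted for
#' drift-correction; a per-trial drift offset shifts the entire stream, and
#' the baseline can be contaminated with displaced outlier samples and/or a
#' blink run.
#'
#' @param cells list with `centrality` (length `n_cells`), `saliency`,
#'   `roi` (matrices `n_frames x n_cells`) for this video.
#' @param truth a [ground_truth()].
#' @param participant,video identifiers copied into the output.
#' @param grid a [grid_spec()] matching the cell tables.
#' @param n_frames,fps video timing.
#' @param sampling_rate gaze sampling rate in Hz (>= fps; default 250).
#' @param participant_intercept,video_intercept random-intercept values.
#' @param jitter_sd_px gaze jitter SD in pixels.
#' @param drift_sd_px SD of the per-trial drift offset.
#' @param pre_ms length of the pre-stimulus segment.
#' @param contaminate_outliers,contaminate_blink logical: contaminate this
#'   trial's baseline with displaced samples / a blink run.
#' @param contam_frac fraction of baseline samples affected (default 0.1).
#' @param seed integer seed.
#' @return data.frame `participant`, `video`, `t_ms`, `x_px`, `y_px`,
#'   `valid`; attribute `fixated_cells` records the generating cell per
#'   frame.
#' @export
simulate_gaze <- function(cells, truth, participant, video, grid,
                          n_frames, fps = 30, sampling_rate = 250,
                          participant_intercept = 0, video_intercept = 0,
                          jitter_sd_px = 5, drift_sd_px = 5, pre_ms = 1000,
                          contaminate_outliers = FALSE,
                          contaminate_blink = FALSE, contam_frac = 0.1,
                          seed = 1L) {
  if (sampling_rate < fps) stop("'sampling_rate' must be >= fps")
  n_cells <- grid$n_cells
  eta0 <- participant_intercept + video_intercept
  U <- cell_utilities(cells, truth, n_frames, n_cells) + eta0
  with_seed(seed, {
    period_ms <- 1000 / sampling_rate
    fix_cells <- integer(n_frames)
    for (t in seq_len(n_frames)) {
      p <- exp(U[t, ] - max(U[t, ]))
      fix_cells[t] <- sample.int(n_cells, 1L, prob = p) - 1L
    }
    t_ms <- seq(-pre_ms, n_frames / fps * 1000 - period_ms / 2, by = period_ms)
    pre <- t_ms < 0
    frame <- pmin(floor(pmax(t_ms, 0) / 1000 * fps), n_frames - 1L)
    cellk <- fix_cells[frame + 1L]
    cx <- (cellk %% grid$n_cols + 0.5) * grid$cell_px
    cy <- (cellk %/% grid$n_cols + 0.5) * grid$cell_px
    x <- ifelse(pre, grid$width_px / 2, cx) + stats::rnorm(length(t_ms), 0, jitter_sd_px)
    y <- ifelse(pre, grid$height_px / 2, cy) + stats::rnorm(length(t_ms), 0, jitter_sd_px)
    drift <- stats::rnorm(2, 0, drift_sd_px)
    x <- x + drift[1]
    y <- y + drift[2]
    valid <- rep(TRUE, length(t_ms))
    pre_idx <- which(pre)
    if (contaminate_outliers && length(pre_idx) > 0) {
      bad <- sample(pre_idx, max(1L, round(contam_frac * length(pre_idx))))
      mag <- 0.15 * grid$width_px
      x[bad] <- x[bad] + sample(c(-1, 1), length(bad), TRUE) *
        stats::runif(length(bad), mag, 2 * mag)
      y[bad] <- y[bad] + sample(c(-1, 1), length(bad), TRUE) *
        stats::runif(length(bad), mag, 2 * mag)
    }
    if (contaminate_blink && length(pre_idx) > 0) {
      len <- max(1L, round(contam_frac * length(pre_idx)))
      s0 <- sample(seq_len(length(pre_idx) - len + 1L), 1L)
      valid[pre_idx[s0:(s0 + len - 1L)]] <- FALSE
    }
    out <- data.frame(participant = participant, video = video, t_ms = t_ms,
                      x_px = x, y_px = y, valid = valid)
    attr(out, "fixated_cells") <- fix_cells
    out
  })
}

#' Simulate affective ratings with a target inter-rater consistency
#'
#' `rating = round(clamp(video_mean + rater_bias + noise, 1, 9))` with
#' `rater_bias ~ N(0, rater_bias_sd)` per participant and i.i.d. noise.
#' With the default video-mean spread, the pilot-calibrated default
#' `rater_noise_sd = 1.15` yields an ICC near 0.65 (valence-like) at 32
#' raters x 90 videos; larger noise degrades consistency towards 0.
#'
#' @param n_participants,n_videos table dimensions.
#' @param video_means per-video mean ratings in `[1, 9]` (default an even
#'   spread over `[2, 8]`).
#' @param rater_bias_sd SD of the per-participant shift (default 0.5).
#' @param rater_noise_sd SD of the per-rating noise.
#' @param seed integer seed.
#' @return data.frame `participant`, `video`, `rating`.
#' @export
simulate_ratings <- function(n_participants, n_videos,
                             video_means = seq(2, 8, length.out = n_videos),
                             rater_bias_sd = 0.5, rater_noise_sd = 1.15,
                             seed = 1L) {
  if (any(video_means < 1 | video_means > 9))
    stop("'video_means' must lie in [1, 9]")
  with_seed(seed, {
    bias <- stats::rnorm(n_participants, 0, rater_bias_sd)
    out <- expand.grid(video = seq_len(n_videos),
                       participant = seq_len(n_participants))
    raw <- video_means[out$video] + bias[out$participant] +
      stats::rnorm(nrow(out), 0, rater_noise_sd)
    out$rating <- as.integer(round(pmin(pmax(raw, 1), 9)))
    out[c("participant", "video", "rating")]
  })
}

## peak-normalized skin-conductance response shape
scr_shape <- function(u, rise = 0.75, decay = 2) {
  r <- ifelse(u > 0, (1 - exp(-u / rise)) * exp(-u / decay), 0)
  peak_u <- rise * log(1 + decay / rise)
  r / ((1 - exp(-peak_u / rise)) * exp(-peak_u / decay))
}

#' Simulate trial-locked cardiac and electrodermal responses
#'
#' Heart rate follows `bpm(t) = hr_baseline_bpm - deceleration_bpm` during
#' the programmed dip window after stimulus onset and the baseline rate
#' elsewhere; R-peak times are obtained by stepping `t += 60 / bpm(t)`. The
#' EDA trace is a tonic level plus a stimulus-locked, exponentially decaying
#' response scaled by `eda_amp`. Times are relative to stimulus onset.
#'
#' @param n_trials number of trials (one pair of traces each).
#' @param hr_baseline_bpm baseline heart rate (> 0).
#' @param deceleration_bpm dip depth in bpm.
#' @param dip_start_s,dip_len_s dip window (default seconds 2-7 of
#'   stimulation).
#' @param eda_amp response amplitude in microsiemens.
#' @param eda_tonic_uS tonic level.
#' @param eda_latency_s response latency.
#' @param trial_dur_s stimulation length (default 20 s).
#' @param eda_rate EDA sampling rate in Hz.
#' @param seed integer seed (reserved; the default traces are deterministic).
#' @return List with `r_peaks` (data.frame `trial`, `t_s`) and `eda`
#'   (data.frame `trial`, `t_s`, `uS`).
#' @export
simulate_physio <- function(n_trials = 1, hr_baseline_bpm = 70,
                            deceleration_bpm = 5, dip_start_s = 2,
                            dip_len_s = 5, eda_amp = 0.3, eda_tonic_uS = 5,
                            eda_latency_s = 1, trial_dur_s = 20,
                            eda_rate = 50, seed = 1L) {
  stopifnot_scalar(hr_baseline_bpm, "hr_baseline_bpm")
  bpm_at <- function(t) {
    hr_baseline_bpm - deceleration_bpm *
      (t >= dip_start_s & t < dip_start_s + dip_len_s)
  }
  rp <- list(); ed <- list()
  for (tr in seq_len(n_trials)) {
    t <- -5
    times <- numeric(0)
    while (t < trial_dur_s + 2) {
      times <- c(times, t)
      t <- t + 60 / bpm_at(t)
    }
    rp[[tr]] <- data.frame(trial = tr, t_s = times)
    ts <- seq(-1, trial_dur_s, by = 1 / eda_rate)
    ed[[tr]] <- data.frame(trial = tr, t_s = ts,
                           uS = eda_tonic_uS +
                             eda_amp * scr_shape(ts - eda_latency_s))
  }
  list(r_peaks = do.call(rbind, rp), eda = do.call(rbind, ed))
}

#' Synthetic ECG trace from R-peak times
#'
#' Template beats (Gaussian R spike with small P and S lobes) placed at the
#' given peak times, plus baseline wander and white noise, for exercising
#' [detect_r_peaks()] against ground truth.
#'
#' @param r_times R-peak times in seconds.
#' @param rate sampling rate in Hz.
#' @param duration_s trace length (default covers the peaks plus 1 s).
#' @param amp R amplitude.
#' @param noise_sd white-noise SD.
#' @param seed integer seed.
#' @return Numeric trace of length `duration_s * rate`.
#' @export
synthesize_ecg <- function(r_times, rate = 500,
                           duration_s = max(r_times) + 1, amp = 1,
                           noise_sd = 0.01, seed = 1L) {
  n <- round(duration_s * rate)
  t <- (0:(n - 1)) / rate
  x <- 0.05 * sin(2 * pi * 0.25 * t)
  for (tp in r_times) {
    x <- x + amp * exp(-(t - tp)^2 / (2 * 0.012^2)) -
      0.25 * amp * exp(-(t - tp - 0.035)^2 / (2 * 0.015^2)) +
      0.1 * amp * exp(-(t - tp + 0.18)^2 / (2 * 0.04^2))
  }
  if (noise_sd > 0) x <- x + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  x
}
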
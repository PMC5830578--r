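# Gaze preprocessing: recursive baseline outlier removal, drift correction,
# onset exclusion and frame alignment.

#' Recursive outlier removal
#'
#' Repeatedly removes the current minimum and maximum of a distribution,
#' compares each removed value to the mean +/- 3 SD of the remaining values,
#' and re-enters the values that fall within that band. The recursion ends
#' when both the removed minimum and maximum meet the re-entry criterion.
#' The SD is the sample SD (n-1 denominator); with SD = 0 only values equal
#' to the mean re-enter.
#'
#' @param values numeric vector of coordinates (non-finite values are ignored).
#' @param n_sd re-entry band half-width in standard deviations (default 3).
#' @return Numeric vector of retained values (a sub-multiset of the input,
#'   original order not preserved), with attributes `n_removed` and
#'   `degenerate` (TRUE when fewer than 3 finite values were supplied, in
#'   which case all are retained).
#' @export
recursive_outlier_trim <- function(values, n_sd = 3) {
  x <- values[is.finite(values)]
  if (length(x) < 3L) {
    return(structure(x, n_removed = 0L, degenerate = TRUE))
  }
  n_in <- length(x)
  x <- sort(x)
  repeat {
    if (length(x) < 3L) break
    lo <- x[1L]
    hi <- x[length(x)]
    rest <- x[-c(1L, length(x))]
    m <- mean(rest)
    s <- stats::sd(rest)
    if (is.na(s)) s <- Inf  # single remaining value: no evidence to reject
    lo_ok <- abs(lo - m) <= n_sd * s
    hi_ok <- abs(hi - m) <= n_sd * s
    x <- rest
    if (lo_ok) x <- c(lo, x)
    if (hi_ok) x <- c(x, hi)
    if (lo_ok && hi_ok) break
  }
  structure(x, n_removed = n_in - length(x), degenerate = FALSE)
}

#' Baseline gaze position from the pre-stimulus window
#'
#' Estimates the mean valid gaze position in the last `window_ms` before
#' stimulus onset, after recursive outlier removal per axis. The baseline is
#' flagged invalid when the window contains any blink/invalid sample or when
#' the outlier recursion discarded part of either axis; such baselines are
#' replaced downstream by the participant's mean valid baseline.
#'
#' @param trial data.frame with columns `t_ms`, `x_px`, `y_px`, `valid`
#'   (t_ms relative to stimulus onset; the pre-stimulus segment has t_ms < 0).
#' @param window_ms length of the pre-onset window in ms (default 300).
#' @return List with `bx_px`, `by_px`, `valid`, `n_used` (per-axis retained
#'   sample counts) and `n_window`.
#' @export
compute_baseline <- function(trial, window_ms = 300) {
  w <- trial[trial$t_ms >= -window_ms & trial$t_ms < 0, , drop = FALSE]
  if (nrow(w) == 0L)
    return(list(bx_px = NA_real_, by_px = NA_real_, valid = FALSE,
                n_used = c(x = 0L, y = 0L), n_window = 0L))
  any_blink <- any(!w$valid)
  ok <- w[as.logical(w$valid), , drop = FALSE]
  if (nrow(ok) == 0L)
    return(list(bx_px = NA_real_, by_px = NA_real_, valid = FALSE,
                n_used = c(x = 0L, y = 0L), n_window = nrow(w)))
  tx <- recursive_outlier_trim(ok$x_px)
  ty <- recursive_outlier_trim(ok$y_px)
  discarded <- attr(tx, "n_removed") > 0L || attr(ty, "n_removed") > 0L
  list(bx_px = mean(tx), by_px = mean(ty),
       valid = !any_blink && !discarded,
       n_used = c(x = length(tx), y = length(ty)),
       n_window = nrow(w))
}

#' Drift-correct all trials of one participant
#'
#' Computes per-trial baselines, replaces invalid baselines by the mean of the
#' participant's valid baselines (per axis), subtracts the drift offset
#' (baseline minus fixation-cross position, taken as the screen/video centre)
#' from every gaze sample, and applies the stimulus-onset exclusion (samples
#' with `t_ms < onset_exclude_ms` are dropped, pre-stimulus segment included).
#'
#' @param trials data.frame of raw gaze samples with columns `participant`,
#'   `video`, `t_ms`, `x_px`, `y_px`, `valid` for a single participant.
#' @param width_px,height_px video dimensions in pixels (the fixation cross is
#'   assumed at the centre `(width_px/2, height_px/2)`).
#' @param window_ms baseline window, see [compute_baseline()].
#' @param onset_exclude_ms initial stimulus period excluded (default 150 ms;
#'   the boundary is half-open, samples at exactly this time are kept).
#' @return data.frame of corrected samples (columns as input), with attribute
#'   `baselines`: one row per video with the baseline used, its validity, and
#'   whether it was imputed. If no trial has a valid baseline the data are
#'   returned uncorrected (onset exclusion still applied) with attribute
#'   `uncorrected = TRUE`.
#' @export
correct_trials <- function(trials, width_px, height_px, window_ms = 300,
                           onset_exclude_ms = 150) {
  if (length(unique(trials$participant)) > 1L)
    stop("correct_trials() expects the trials of a single participant")
  videos <- unique(trials$video)
  bl <- lapply(videos, function(v)
    compute_baseline(trials[trials$video == v, , drop = FALSE], window_ms))
  bx <- vapply(bl, `[[`, numeric(1), "bx_px")
  by <- vapply(bl, `[[`, numeric(1), "by_px")
  ok <- vapply(bl, `[[`, logical(1), "valid")
  imputed <- !ok
  uncorrected <- FALSE
  if (!any(ok)) {
    uncorrected <- TRUE
    bx[] <- width_px / 2
    by[] <- height_px / 2
    imputed[] <- FALSE
  } else {
    bx[!ok] <- mean(bx[ok], na.rm = TRUE)
    by[!ok] <- mean(by[ok], na.rm = TRUE)
  }
  cx <- width_px / 2
  cy <- height_px / 2
  out <- trials[trials$t_ms >= onset_exclude_ms, , drop = FALSE]
  idx <- match(out$video, videos)
  out$x_px <- out$x_px - (bx[idx] - cx)
  out$y_px <- out$y_px - (by[idx] - cy)
  rownames(out) <- NULL
  attr(out, "baselines") <- data.frame(video = videos, bx_px = bx, by_px = by,
                                       valid = ok, imputed = imputed)
  attr(out, "uncorrected") <- uncorrected
  out
}

#' Collapse gaze samples to one point per video frame
#'
#' Frame `k` (0-based) covers the half-open interval `[k/fps, (k+1)/fps)`
#' seconds after stimulus onset. The per-frame gaze point is the mean of the
#' valid, in-bounds samples falling in that interval; frames without any such
#' sample are marked missing.
#'
#' @param trial corrected gaze samples of one trial (columns `t_ms`, `x_px`,
#'   `y_px`, `valid`).
#' @param n_frames number of video frames.
#' @param fps frame rate (default 30).
#' @param width_px,height_px frame bounds used for the in-bounds check.
#' @return data.frame with columns `frame` (0-based), `x_px`, `y_px`,
#'   `missing`.
#' @export
align_gaze_to_frames <- function(trial, n_frames, fps = 30,
                                 width_px, height_px) {
  s <- trial[as.logical(trial$valid) &
               trial$x_px >= 0 & trial$x_px < width_px &
               trial$y_px >= 0 & trial$y_px < height_px &
               trial$t_ms >= 0, , drop = FALSE]
  frame <- floor(s$t_ms / 1000 * fps)
  keep <- frame >= 0 & frame < n_frames
  s <- s[keep, , drop = FALSE]
  frame <- frame[keep]
  x <- tapply(s$x_px, factor(frame, levels = 0:(n_frames - 1L)), mean)
  y <- tapply(s$y_px, factor(frame, levels = 0:(n_frames - 1L)), mean)
  data.frame(frame = 0:(n_frames - 1L),
             x_px = as.numeric(x), y_px = as.numeric(y),
             missing = is.na(as.numeric(x)))
}
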
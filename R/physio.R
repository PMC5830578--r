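# Autonomic trial summaries: R-peak detection, second-by-second heart rate
# with fractional-overlap weighting, and baseline-corrected HR / EDA means.

#' Detect R-peaks in an ECG trace
#'
#' Automated QRS detection: band-pass filtering (5-35 Hz Butterworth,
#' zero-phase), squared derivative, moving-average smoothing, an adaptive
#' threshold relative to the signal's own amplitude distribution (so the
#' result is invariant to trace scaling), and a 250 ms refractory period.
#' Peak times are refined to the local maximum of the band-passed signal.
#'
#' @param ecg numeric trace (arbitrary units).
#' @param rate sampling rate in Hz.
#' @param refractory_s minimum peak spacing in seconds (default 0.25).
#' @return Numeric vector of peak times in seconds (empty, with a warning,
#'   when nothing resembling a QRS complex is found).
#' @export
detect_r_peaks <- function(ecg, rate, refractory_s = 0.25) {
  if (length(ecg) < 2 * rate) stop("trace must cover at least 2 s")
  if (stats::sd(ecg) == 0) {
    warning("flat trace: no R-peaks detected")
    return(numeric(0))
  }
  bf <- signal::butter(3, c(5, 35) / (rate / 2), type = "pass")
  filt <- as.numeric(signal::filtfilt(bf, ecg))
  d <- c(0, diff(filt)) * rate
  sq <- d^2
  wlen <- max(3L, round(0.12 * rate))
  smooth <- as.numeric(stats::filter(sq, rep(1 / wlen, wlen), sides = 2))
  smooth[is.na(smooth)] <- 0
  thr <- 0.2 * stats::quantile(smooth, 0.99)
  if (thr <= 0) {
    warning("no QRS-like energy above threshold")
    return(numeric(0))
  }
  above <- smooth > thr
  refr <- round(refractory_s * rate)
  peaks <- integer(0)
  i <- 1L
  n <- length(smooth)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      seg <- i:j
      peaks <- c(peaks, seg[which.max(smooth[seg])])
      i <- j + refr
    }
    i <- i + 1L
  }
  ## refine to the local max of |band-passed| signal near the energy peak
  half <- round(0.05 * rate)
  refined <- vapply(peaks, function(p) {
    seg <- max(1L, p - half):min(n, p + half)
    seg[which.max(filt[seg])]
  }, integer(1))
  refined <- sort(unique(refined))
  if (length(refined) > 1L) {
    keep <- c(TRUE, diff(refined) >= refr)
    refined <- refined[keep]
  }
  (refined - 1) / rate
}

#' Second-by-second heart rate from R-peak times
#'
#' The instantaneous rate of interval `i` is `60 / (t[i+1] - t[i])` bpm; the
#' value for each one-second bin is the mean of the instantaneous rates of
#' all intervals overlapping the bin, weighted by the fraction of the bin
#' each interval covers. Seconds not covered by any interval are `NA`.
#'
#' @param r_times R-peak times in seconds (>= 2 peaks).
#' @param start,end window bounds in seconds; bins are `[start, start+1)`,
#'   ..., up to `end`.
#' @return Numeric vector of bpm values, one per second, named by bin start
#'   time.
#' @export
hr_per_second <- function(r_times, start, end) {
  r_times <- sort(r_times)
  if (length(r_times) < 2L) stop("need at least 2 R-peaks")
  if (end <= start) stop("'end' must exceed 'start'")
  ivl_a <- r_times[-length(r_times)]
  ivl_b <- r_times[-1]
  rate <- 60 / (ivl_b - ivl_a)
  secs <- seq(start, end - 1)
  out <- vapply(secs, function(s) {
    ov <- pmin(ivl_b, s + 1) - pmax(ivl_a, s)
    w <- pmax(ov, 0)
    if (sum(w) <= 0) return(NA_real_)
    sum(w * rate) / sum(w)
  }, numeric(1))
  names(out) <- secs
  out
}

#' Baseline-corrected trial summaries of heart rate and EDA
#'
#' HR: the value of the last pre-stimulus second (the baseline second) is
#' subtracted from every stimulation second; the per-second deltas and their
#' mean are returned. EDA: the value at trial start is subtracted from all
#' samples within the trial and the corrected trace is averaged.
#'
#' @param hr second-by-second bpm values from [hr_per_second()], covering the
#'   baseline second followed by the stimulation seconds (first element =
#'   baseline).
#' @param eda optional data.frame with columns `t_s`, `uS`.
#' @param trial_start,trial_end EDA trial bounds in seconds.
#' @return List with `hr_delta` (per stimulation second), `hr_mean_delta`,
#'   `eda_mean_delta` (NA when no EDA supplied).
#' @export
trial_autonomic_summary <- function(hr, eda = NULL, trial_start = NA,
                                    trial_end = NA) {
  if (is.na(hr[1])) stop("baseline second not covered; trial excluded")
  base <- hr[1]
  delta <- hr[-1] - base
  eda_mean <- NA_real_
  if (!is.null(eda)) {
    sel <- eda$t_s >= trial_start & eda$t_s < trial_end
    tr <- eda[sel, , drop = FALSE]
    if (nrow(tr) > 0L) eda_mean <- mean(tr$uS - tr$uS[1])
  }
  list(hr_delta = delta, hr_mean_delta = mean(delta, na.rm = TRUE),
       eda_mean_delta = eda_mean)
}
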
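#' Extract the ROI-mean intensity signal from single-channel IR video
#'
#' Respiratory airflow modulates pixel intensities in the nose area of
#' (non-radiometric) infrared video; this returns one ROI-mean intensity per
#' frame.
#'
#' @param video a single-channel [frame_sequence()].
#' @param roi a [roi()] (fixed) or a [tracking_result()] covering the video.
#' @return An object of class `intensity_signal` with `values`,
#'   `sampling_rate` and `duration_s`.
#' @export
extract_intensity_signal <- function(video, roi) {
  if (n_channels(video) != 1)
    stop("3-channel input: use the RGB heart-rate pipeline (extract_green_signal) instead")
  n <- length(video$frames)
  rois <- if (inherits(roi, "roi")) rep(list(roi), n)
          else if (inherits(roi, "tracking_result")) roi$rois
          else stop("'roi' must be a roi or tracking_result")
  if (length(rois) != n) stop("roi trajectory does not cover the video")
  vals <- rep(NA_real_, n)
  for (i in seq_len(n))
    if (!is.null(rois[[i]])) vals[i] <- mean(roi_pixels(video$frames[[i]], rois[[i]]))
  if (anyNA(vals)) {
    lost <- is.na(vals)
    if (mean(lost) > 0.5) stop("more than 50% of frames have lost tracking")
    idx <- seq_len(n)
    vals <- stats::approx(idx[!lost], vals[!lost], xout = idx, rule = 2)$y
  }
  structure(list(values = vals, sampling_rate = video$frame_rate,
                 duration_s = n / video$frame_rate),
            class = "intensity_signal")
}

#' @export
print.intensity_signal <- function(x, ...) {
  cat(sprintf("<intensity_signal> %d samples at %g fps (%.1f s)\n",
              length(x$values), x$sampling_rate, x$duration_s))
  invisible(x)
}

# minimum-spacing peak picking: local maxima, greedy by height, then a
# prominence filter relative to the processed signal's spread
count_peaks <- function(x, min_dist_samples, min_prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand)
    if (!length(kept) || min(abs(kept - p)) >= min_dist_samples)
      kept <- c(kept, p)
  kept <- sort(kept)
  # prominence: drop to the deepest valley towards the neighbouring peaks
  ok <- vapply(seq_along(kept), function(i) {
    lo <- if (i == 1) 1 else kept[i - 1]
    hi <- if (i == length(kept)) n else kept[i + 1]
    prom <- min(x[kept[i]] - min(x[lo:kept[i]]), x[kept[i]] - min(x[kept[i]:hi]))
    prom >= min_prominence
  }, logical(1))
  kept[ok]
}

#' Count respiration cycles in an intensity signal
#'
#' The signal is detrended by subtracting a 5 s moving median, low-pass
#' filtered (zero-phase second-order Butterworth at `max_rr_bpm`), and
#' breathing cycles are counted as prominent peaks (prominence at least half
#' the processed signal's inter-quartile range) spaced at least
#' `60 / max_rr_bpm` seconds apart.
#'
#' @param signal an [extract_intensity_signal()] result.
#' @param min_rr_bpm,max_rr_bpm plausible respiration band in breaths per
#'   minute (defaults 5 and 120); `max_rr_bpm` must be below Nyquist.
#' @return An object of class `rr_estimate`: `breaths_per_min`
#'   (`n_cycles * 60 / window_s`), `n_cycles`, `window_s`.
#' @export
count_breaths <- function(signal, min_rr_bpm = 5, max_rr_bpm = 120) {
  fs <- signal$sampling_rate
  if (signal$duration_s < 10) stop("signal too short: need at least 10 s")
  if (!(min_rr_bpm > 0 && min_rr_bpm < max_rr_bpm && max_rr_bpm / 60 < fs / 2))
    stop("respiration band empty or above Nyquist")
  x <- signal$values
  n <- length(x)
  k <- round(5 * fs)
  if (k %% 2 == 0) k <- k + 1
  k <- min(k, if (n %% 2 == 1) n else n - 1)
  # reflect-pad so the moving-median detrend has no end-of-series bias
  pad <- min(k, n - 1)
  xe <- c(2 * x[1] - rev(x[2:(pad + 1)]), x, 2 * x[n] - rev(x[(n - pad):(n - 1)]))
  x <- x - stats::runmed(xe, k)[(pad + 1):(pad + n)]
  bf <- signal::butter(2, (max_rr_bpm / 60) / (fs / 2), type = "low")
  x <- zero_phase(bf, x, pad = min(round(3 * fs), length(x) - 1))
  peaks <- count_peaks(x, min_dist_samples = ceiling(fs * 60 / max_rr_bpm),
                       min_prominence = 0.5 * stats::IQR(x))
  n_cycles <- length(peaks)
  structure(list(breaths_per_min = n_cycles * 60 / signal$duration_s,
                 n_cycles = n_cycles, window_s = signal$duration_s),
            class = "rr_estimate")
}

#' @export
print.rr_estimate <- function(x, ...) {
  cat(sprintf("<rr_estimate> %.1f breaths/min (%d cycles over %.1f s)\n",
              x$breaths_per_min, x$n_cycles, x$window_s))
  invisible(x)
}
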
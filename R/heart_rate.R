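#' Default heart-rate passband, in beats per minute
#'
#' 45--240 BPM (0.75--4 Hz) brackets published bovine heart-rate ranges with
#' margin.
#' @export
HR_BAND_BPM <- c(45, 240)

#' Construct a luminosity signal
#'
#' @param values mean green-channel (or IR) intensity per frame.
#' @param sampling_rate frames per second.
#' @param roi_label which area the signal came from.
#' @param interpolated optional logical vector flagging frames whose value
#'   was filled in across a tracking gap.
#' @return An object of class `luminosity_signal`.
#' @export
luminosity_signal <- function(values, sampling_rate, roi_label = "eye_area",
                              interpolated = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("signal needs at least 2 samples")
  if (!all(is.finite(values))) stop("non-finite signal values")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (is.null(interpolated)) interpolated <- rep(FALSE, length(values))
  structure(list(values = values, sampling_rate = sampling_rate,
                 roi_label = roi_label, interpolated = interpolated),
            class = "luminosity_signal")
}

#' @export
print.luminosity_signal <- function(x, ...) {
  cat(sprintf("<luminosity_signal> %d samples at %g fps (%s), %d interpolated\n",
              length(x$values), x$sampling_rate, x$roi_label,
              sum(x$interpolated)))
  invisible(x)
}

#' Extract the ROI-mean green-channel signal from a tracked video
#'
#' For every frame with a usable ROI the mean of the green channel over the
#' (masked) ROI is taken; frames where tracking was lost are filled by linear
#' interpolation between neighbours and flagged in the result.
#'
#' @param video a 3-channel [frame_sequence()].
#' @param tracking a [tracking_result()] (or from [tracking_from_rois()])
#'   covering the video's frames.
#' @return A [luminosity_signal()].
#' @export
extract_green_signal <- function(video, tracking) {
  if (n_channels(video) != 3)
    stop("grayscale input: the photoplethysmography pipeline needs RGB video")
  n <- length(video$frames)
  if (length(tracking$rois) != n) stop("tracking does not cover the video")
  vals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r <- tracking$rois[[i]]
    if (!is.null(r)) vals[i] <- mean(roi_pixels(video$frames[[i]][, , 2], r))
  }
  lost <- is.na(vals)
  if (mean(lost) > 0.5) stop("more than 50% of frames have lost tracking")
  if (any(lost)) {
    idx <- seq_len(n)
    vals <- stats::approx(idx[!lost], vals[!lost], xout = idx, rule = 2)$y
  }
  lab <- NULL
  for (r in tracking$rois) if (!is.null(r)) { lab <- r$label; break }
  luminosity_signal(vals, video$frame_rate, lab, interpolated = lost)
}

design_bandpass <- function(band_bpm, sampling_rate, order) {
  nyq_bpm <- 60 * sampling_rate / 2
  if (!(band_bpm[1] > 0 && band_bpm[1] < band_bpm[2] && band_bpm[2] < nyq_bpm))
    stop("passband must satisfy 0 < low < high < Nyquist (", nyq_bpm, " BPM)")
  signal::butter(order, band_bpm / nyq_bpm, type = "pass")
}

# zero-phase filtering with reflective padding to suppress edge transients
zero_phase <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  xe <- c(2 * x[1] - rev(x[2:(pad + 1)]), x, 2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- signal::filtfilt(bf, xe)
  y[(pad + 1):(pad + n)]
}

#' Band-pass filter a luminosity signal (zero-phase Butterworth)
#'
#' The signal is mean-detrended, then a Butterworth band-pass of the stated
#' order is applied forward and backward (zero phase), which squares the
#' magnitude response. Output length equals input length.
#'
#' @param signal a [luminosity_signal()].
#' @param band_bpm `(low, high)` passband in beats per minute; must lie
#'   strictly inside (0, Nyquist).
#' @param order filter order (default 2, i.e. a second-order Butterworth).
#' @return A [luminosity_signal()] of the filtered values.
#' @export
bandpass_filter <- function(signal, band_bpm = HR_BAND_BPM, order = 2) {
  fs <- signal$sampling_rate
  bf <- design_bandpass(band_bpm, fs, order)
  low_hz <- band_bpm[1] / 60
  warmup <- ceiling(3 * order * fs / low_hz)
  x <- signal$values
  if (length(x) <= 2 * order + 2)
    stop("signal shorter than the filter warm-up (", warmup, " samples)")
  y <- zero_phase(bf, x - mean(x), pad = min(warmup, length(x) - 1))
  luminosity_signal(y, fs, signal$roi_label, signal$interpolated)
}

#' Heart-rate series from a luminosity signal (windowed FFT peak analysis)
#'
#' The signal is band-pass filtered (zero-phase Butterworth of order 2),
#' then analysed in Hann-tapered windows stepped every `hop_s` seconds
#' (0.5 s, the reporting cadence). Each window is zero-padded so the FFT bin
#' spacing is at most 0.5 BPM and the dominant in-band spectral peak,
#' refined by parabolic interpolation, gives `hr_bpm = 60 * peak frequency`.
#' A window whose peak-to-median spectral ratio is below 2, or which overlaps
#' an interpolated tracking gap longer than one second, is flagged low
#' confidence.
#'
#' @param signal a [luminosity_signal()].
#' @param window_s FFT window length in seconds (default 10).
#' @param hop_s seconds between estimates (default exactly 0.5).
#' @param band_bpm `(low, high)` passband in BPM (default 45--240).
#' @return An object of class `hr_series`: `estimates` data.frame
#'   (`time_s`, `hr_bpm`, `confident`), plus `hop_s`, `window_s`, `band_bpm`.
#' @export
estimate_hr_series <- function(signal, window_s = 10, hop_s = 0.5,
                               band_bpm = HR_BAND_BPM) {
  fs <- signal$sampling_rate
  dur <- length(signal$values) / fs
  if (dur < window_s) stop("signal duration shorter than the analysis window")
  filt <- bandpass_filter(signal, band_bpm, order = 2)
  x <- filt$values
  wlen <- round(window_s * fs)
  nfft <- 2^ceiling(log2(max(wlen, fs * 60 / 0.5)))  # bin spacing <= 0.5 BPM
  freqs_bpm <- 60 * (0:(nfft / 2)) * fs / nfft
  inband <- which(freqs_bpm >= band_bpm[1] & freqs_bpm <= band_bpm[2])
  if (length(inband) == 0) stop("empty band after Nyquist clipping")
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(wlen - 1)) / (wlen - 1))
  n_est <- floor((dur - window_s) / hop_s) + 1
  max_gap <- ceiling(fs)  # interpolated runs beyond 1 s disqualify a window
  times <- hr <- conf <- numeric(0)
  for (k in seq_len(n_est) - 1) {
    start <- round(k * hop_s * fs) + 1
    if (start + wlen - 1 > length(x)) break
    seg_interp <- signal$interpolated[start:(start + wlen - 1)]
    runs <- rle(seg_interp)
    long_gap <- any(runs$values & runs$lengths > max_gap)
    w <- x[start:(start + wlen - 1)] * hann
    spec <- abs(stats::fft(c(w, rep(0, nfft - wlen)))[1:(nfft / 2 + 1)])
    sb <- spec[inband]
    pk <- which.max(sb)
    # parabolic refinement of the peak bin
    f_bpm <- freqs_bpm[inband[pk]]
    if (pk > 1 && pk < length(sb)) {
      a <- sb[pk - 1]; b <- sb[pk]; cc <- sb[pk + 1]
      denom <- a - 2 * b + cc
      if (denom < 0) {
        delta <- 0.5 * (a - cc) / denom
        f_bpm <- f_bpm + delta * 60 * fs / nfft
      }
    }
    f_bpm <- min(max(f_bpm, band_bpm[1]), band_bpm[2])
    times <- c(times, k * hop_s + window_s / 2)
    hr <- c(hr, f_bpm)
    conf <- c(conf, !long_gap && (max(sb) / (stats::median(sb) + 1e-300)) >= 2)
  }
  structure(list(estimates = data.frame(time_s = times, hr_bpm = hr,
                                        confident = as.logical(conf)),
                 hop_s = hop_s, window_s = window_s, band_bpm = band_bpm),
            class = "hr_series")
}

#' @export
print.hr_series <- function(x, ...) {
  est <- x$estimates
  cat(sprintf("<hr_series> %d estimates every %g s, median %.1f BPM (band %g-%g)\n",
              nrow(est), x$hop_s, stats::median(est$hr_bpm), x$band_bpm[1],
              x$band_bpm[2]))
  invisible(x)
}
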
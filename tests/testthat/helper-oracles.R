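# Independent brute-force oracles used to check the package's computations.

# Pearson r by direct evaluation of the product-moment formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) * sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# OLS slope/intercept from the normal equations
oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# masked-pixel statistics by an explicit double loop
oracle_roi_stats <- function(frame, rect, mask = NULL) {
  vals <- c()
  for (i in (rect[1] + 1):rect[3]) for (j in (rect[2] + 1):rect[4]) {
    inside <- if (is.null(mask)) TRUE else mask[i - rect[1], j - rect[2]]
    if (inside) vals <- c(vals, frame[i, j])
  }
  list(mean = mean(vals), max = max(vals), min = min(vals),
       sd = if (length(vals) > 1) sd(vals) else 0, n = length(vals))
}

# amplitude of a sinusoid at known frequency (single-bin DFT projection)
oracle_amplitude <- function(x, f_hz, fs) {
  t <- (seq_along(x) - 1) / fs
  x <- x - mean(x)
  2 * Mod(mean(x * exp(-2i * pi * f_hz * t)))
}

# closed-form amplitude ratio of the zero-phase digital Butterworth bandpass:
# |H|^2 where H is the bilinear-transform (prewarped) analog prototype
oracle_butter2_zerophase <- function(f_bpm, band_bpm, fs, order = 2) {
  warp <- function(f) tan(pi * (f / 60) / fs)
  w <- warp(f_bpm)
  w1 <- warp(band_bpm[1]); w2 <- warp(band_bpm[2])
  1 / (1 + ((w^2 - w1 * w2) / ((w2 - w1) * w))^(2 * order))
}

# a checkerboard test frame: k x k cells of side `cell`, top-left corner at
# (off, off) 1-based, values lo/hi on a lo background
make_checkerboard <- function(size = 48, cell = 6, k = 5, off = 9,
                              lo = 60, hi = 200) {
  cb <- matrix(lo, size, size)
  for (i in 0:(k - 1)) for (j in 0:(k - 1))
    if ((i + j) %% 2 == 0)
      cb[off + i * cell + (1:cell), off + j * cell + (1:cell)] <- hi
  cb
}

# interior lattice crossings of that checkerboard, 0-based sub-pixel coords
checkerboard_crossings <- function(cell = 6, k = 5, off = 9) {
  g <- off + cell * (1:(k - 1)) - 0.5
  as.matrix(expand.grid(row = g, col = g))
}

# per-frame IoU of a tracking result against a truth trajectory
iou_trace <- function(result, truth_rois) {
  mapply(function(a, b) if (is.null(a)) 0 else roi_iou(a, b),
         result$rois, truth_rois)
}

snr_to_sd <- function(amplitude, snr_db) sqrt(amplitude^2 / 2 / 10^(snr_db / 10))
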
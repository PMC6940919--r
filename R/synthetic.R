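# Seeded synthetic fixtures with known ground truth. Texture is a field of
# Gaussian blobs (rendered analytically, so sub-pixel motion is exact and
# gradients are smooth for the tracker); noise is Gaussian; every generator
# is a pure function of (params, seed).

# render amps[k] * exp(-d^2 / (2 sigma^2)) blobs onto a H x W canvas,
# each evaluated on a local window of +/- 4 sigma
render_blobs <- function(H, W, centers, amps, sigma) {
  img <- matrix(0, H, W)
  rad <- ceiling(4 * sigma)
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1]; c0 <- centers[k, 2]
    ri <- max(1, floor(r0 + 1 - rad)):min(H, ceiling(r0 + 1 + rad))
    ci <- max(1, floor(c0 + 1 - rad)):min(W, ceiling(c0 + 1 + rad))
    if (!length(ri) || !length(ci)) next
    dr2 <- ((ri - 1) - r0)^2
    dc2 <- ((ci - 1) - c0)^2
    img[ri, ci] <- img[ri, ci] + amps[k] * exp(-outer(dr2, dc2, "+") / (2 * sigma^2))
  }
  img
}

patch_rect <- function(center, half) {
  c(floor(center[1] - half), floor(center[2] - half),
    floor(center[1] - half) + 2 * half, floor(center[2] - half) + 2 * half)
}

ground_truth <- function(kind, schedule, seed, params) {
  structure(list(kind = kind, schedule = schedule, seed = seed,
                 params = params), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> kind=%s seed=%d\n", x$kind, x$seed))
  invisible(x)
}

# write media + ground-truth manifest next to it
write_manifest <- function(truth, out_dir) {
  gt <- truth
  gt$params <- gt$params[!vapply(gt$params, is.list, logical(1))]
  jsonlite::write_json(unclass(gt), file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Synthetic photoplethysmography (PPG) video with a known heart rate
#'
#' A textured face patch on a flat background; the green channel inside the
#' patch is modulated sinusoidally at `hr_bpm / 60` Hz with amplitude 5
#' intensity units over a baseline of 100. The patch wanders on a circular
#' path at `motion_px_per_frame` pixels per frame; Gaussian pixel noise is
#' added to all channels.
#'
#' @param hr_bpm embedded heart rate (below Nyquist, i.e. `< 30 * frame_rate`).
#' @param duration_s clip length in seconds (at least 10).
#' @param frame_rate frames per second (default 29, the RGB camera rate).
#' @param motion_px_per_frame speed of the rigid patch motion (default 0).
#' @param noise_sd Gaussian pixel noise SD in intensity units (default 0).
#' @param seed RNG seed; the output is a pure function of (params, seed).
#' @param frame_size frame height/width in pixels.
#' @param patch_half half the patch side (patch is `2*patch_half` squared).
#' @param out_dir optional directory: frames and a ground-truth JSON manifest
#'   are written there.
#' @return List with `video` ([frame_sequence()]), `roi` (the frame-1 patch
#'   box), `truth` (`ground_truth` carrying the schedule and per-frame true
#'   ROI trajectory).
#' @export
make_ppg_video <- function(hr_bpm, duration_s, frame_rate = 29,
                           motion_px_per_frame = 0, noise_sd = 0, seed = 1,
                           frame_size = 64, patch_half = 18, out_dir = NULL) {
  if (!(hr_bpm > 0 && hr_bpm < 30 * frame_rate))
    stop("hr_bpm must be inside (0, 30 * frame_rate): above Nyquist")
  if (duration_s < 10) stop("duration_s must be at least 10")
  n <- round(duration_s * frame_rate)
  f_hz <- hr_bpm / 60
  withr::with_seed(seed, {
    n_blobs <- 40
    rel <- cbind(stats::runif(n_blobs, -patch_half + 3, patch_half - 3),
                 stats::runif(n_blobs, -patch_half + 3, patch_half - 3))
    amps <- stats::runif(n_blobs, 15, 40) * sample(c(-1, 1), n_blobs, TRUE)
    mid <- (frame_size - 1) / 2
    radius <- min(8, mid - patch_half - 4)
    if (radius < 0) stop("frame too small for the patch")
    omega <- if (radius > 0) motion_px_per_frame / radius else 0
    tvec <- (seq_len(n) - 1) / frame_rate
    ang <- omega * (seq_len(n) - 1)
    centers <- cbind(mid + radius * sin(ang), mid + radius * cos(ang))
    frames <- vector("list", n)
    truth_rois <- vector("list", n)
    for (i in seq_len(n)) {
      ctr <- centers[i, ]
      tex <- render_blobs(frame_size, frame_size,
                          cbind(rel[, 1] + ctr[1], rel[, 2] + ctr[2]), amps, 2)
      rect <- patch_rect(ctr, patch_half)
      box <- matrix(FALSE, frame_size, frame_size)
      box[(rect[1] + 1):rect[3], (rect[2] + 1):rect[4]] <- TRUE
      red <- matrix(60, frame_size, frame_size)
      green <- red
      blue <- red
      red[box] <- 90 + tex[box]
      blue[box] <- 80 + tex[box]
      green[box] <- 100 + 0.8 * tex[box] + 5 * sin(2 * pi * f_hz * tvec[i])
      fr <- array(0, c(frame_size, frame_size, 3))
      fr[, , 1] <- red; fr[, , 2] <- green; fr[, , 3] <- blue
      if (noise_sd > 0)
        fr <- fr + array(stats::rnorm(length(fr), 0, noise_sd), dim(fr))
      frames[[i]] <- fr
      truth_rois[[i]] <- roi(rect, label = "face")
    }
  })
  video <- frame_sequence(frames, frame_rate, source_id = "synthetic_ppg")
  truth <- ground_truth("hr", hr_bpm, seed,
                        list(duration_s = duration_s, frame_rate = frame_rate,
                             motion_px_per_frame = motion_px_per_frame,
                             noise_sd = noise_sd, amplitude = 5, baseline = 100,
                             roi_trajectory = truth_rois))
  if (!is.null(out_dir)) {
    write_frame_sequence(video, out_dir)
    write_manifest(truth, out_dir)
  }
  list(video = video, roi = truth_rois[[1]], truth = truth)
}

#' Synthetic nostril video with a known respiration rate
#'
#' Single-channel video: a nose patch whose intensity cycles sinusoidally at
#' `rr_bpm / 60` Hz with amplitude 10 over baseline 100, on a background of
#' 80, plus optional Gaussian noise.
#'
#' @param rr_bpm embedded breaths per minute (`rr_bpm / 60` below Nyquist).
#' @param duration_s clip length (default 60 s, a typical crush recording).
#' @param frame_rate frames per second (29, or e.g. 8.7 for a phone-mounted
#'   IR camera).
#' @param noise_sd Gaussian pixel noise SD.
#' @param seed RNG seed.
#' @param frame_size frame side in pixels.
#' @param out_dir optional output directory for frames + manifest.
#' @return List with `video`, `roi` (nose patch box) and `truth`.
#' @export
make_breath_video <- function(rr_bpm, duration_s = 60, frame_rate = 29,
                              noise_sd = 0, seed = 1, frame_size = 32,
                              out_dir = NULL) {
  f_hz <- rr_bpm / 60
  if (!(f_hz > 0 && f_hz < frame_rate / 2)) stop("rr_bpm above Nyquist")
  n <- round(duration_s * frame_rate)
  half <- 6
  mid <- (frame_size - 1) / 2
  rect <- patch_rect(c(mid, mid), half)
  rows <- (rect[1] + 1):rect[3]; cols <- (rect[2] + 1):rect[4]
  tvec <- (seq_len(n) - 1) / frame_rate
  withr::with_seed(seed, {
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      fr <- matrix(80, frame_size, frame_size)
      fr[rows, cols] <- 100 + 10 * sin(2 * pi * f_hz * tvec[i])
      if (noise_sd > 0)
        fr <- fr + matrix(stats::rnorm(length(fr), 0, noise_sd), frame_size)
      frames[[i]] <- fr
    }
  })
  video <- frame_sequence(frames, frame_rate, source_id = "synthetic_breath")
  truth <- ground_truth("rr", rr_bpm, seed,
                        list(duration_s = duration_s, frame_rate = frame_rate,
                             noise_sd = noise_sd, amplitude = 10, baseline = 100))
  if (!is.null(out_dir)) {
    write_frame_sequence(video, out_dir)
    write_manifest(truth, out_dir)
  }
  list(video = video, roi = roi(rect, label = "nose"), truth = truth)
}

#' Synthetic radiometric sequence with paired logger ground truth
#'
#' Emulates the invasive-vs-remote temperature comparison: an intravaginal
#' logger records the core trajectory exactly every 60 s, while the thermal
#' camera sees, at 1 frame per second, eye-area pixels at core minus
#' `offset_C` and ear-base pixels at core minus `ear_offset_C`, both with
#' additive Gaussian noise, on an ambient background.
#'
#' @param core_trajectory data.frame `(time_s, temp_C)` covering
#'   `[0, duration_s]`.
#' @param offset_C eye-area surface offset below core (default 1.1 degC).
#' @param noise_sd_C per-pixel Gaussian noise SD in degC.
#' @param duration_s sequence length in seconds.
#' @param seed RNG seed.
#' @param ear_offset_C ear-base offset below core (default 3.1 degC, more
#'   peripheral than the eye).
#' @param frame_size raster side in pixels.
#' @param out_dir optional output directory (float TIFF + JSON + manifest).
#' @return List with `thermal` ([radiometric_sequence()]), `rois` (named
#'   list: eye_area, ear_base), `logger` (data.frame `time_s`, `temp_C`) and
#'   `truth`.
#' @export
make_thermal_sequence <- function(core_trajectory, offset_C = 1.1,
                                  noise_sd_C = 0.1, duration_s = 360, seed = 1,
                                  ear_offset_C = 3.1, frame_size = 32,
                                  out_dir = NULL) {
  tt <- as.numeric(core_trajectory$time_s)
  cc <- as.numeric(core_trajectory$temp_C)
  if (min(tt) > 0 || max(tt) < duration_s)
    stop("trajectory gap: core_trajectory must cover [0, duration_s]")
  times <- seq(0, duration_s, by = 1)
  core <- stats::approx(tt, cc, xout = times)$y
  eye <- roi(c(6, 6, 14, 14), label = "eye_area")
  ear <- roi(c(18, 18, 26, 26), label = "ear_base")
  withr::with_seed(seed, {
    frames <- lapply(seq_along(times), function(i) {
      fr <- matrix(25, frame_size, frame_size)
      fr[(eye$rect[1] + 1):eye$rect[3], (eye$rect[2] + 1):eye$rect[4]] <-
        core[i] - offset_C
      fr[(ear$rect[1] + 1):ear$rect[3], (ear$rect[2] + 1):ear$rect[4]] <-
        core[i] - ear_offset_C
      if (noise_sd_C > 0)
        fr <- fr + matrix(stats::rnorm(length(fr), 0, noise_sd_C), frame_size)
      fr
    })
  })
  logger_t <- seq(0, duration_s, by = 60)
  logger <- data.frame(time_s = logger_t,
                       temp_C = stats::approx(tt, cc, xout = logger_t)$y)
  thermal <- radiometric_sequence(frames, frame_rate = 1)
  truth <- ground_truth("temperature", list(offset_C = offset_C,
                                            ear_offset_C = ear_offset_C), seed,
                        list(duration_s = duration_s, noise_sd_C = noise_sd_C))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_radiometric_pair(thermal, file.path(out_dir, "thermal.tiff"),
                           file.path(out_dir, "thermal.json"))
    write_roi_spec(list(eye_area = eye, ear_base = ear),
                   c(frame_size, frame_size), file.path(out_dir, "rois.json"))
    utils::write.csv(logger, file.path(out_dir, "logger.csv"), row.names = FALSE)
    write_manifest(truth, out_dir)
  }
  list(thermal = thermal, rois = list(eye_area = eye, ear_base = ear),
       logger = logger, truth = truth)
}

#' Synthetic tracking sequence with a commanded motion schedule
#'
#' A densely textured patch follows a commanded per-frame translation on a
#' flat background; the true patch ROI is recorded for every frame. The
#' frame is sized automatically so the motion keeps the patch inside.
#'
#' @param motion `(n-1) x 2` matrix of per-frame `(drow, dcol)` steps (or a
#'   list of length-2 vectors); row i moves the patch between frames i and
#'   i+1.
#' @param texture_density blobs per patch pixel (default 0.03).
#' @param duration_frames number of frames.
#' @param seed RNG seed.
#' @param patch_half half the patch side.
#' @param noise_sd Gaussian pixel noise SD.
#' @param out_dir optional output directory for frames + manifest.
#' @return List with `video` (grayscale [frame_sequence()]), `truth_rois`
#'   (per-frame true [roi()]s) and `truth`.
#' @export
make_tracking_sequence <- function(motion, texture_density = 0.03,
                                   duration_frames = 100, seed = 1,
                                   patch_half = 18, noise_sd = 0,
                                   out_dir = NULL) {
  n <- duration_frames
  if (is.list(motion)) motion <- do.call(rbind, motion)
  if (is.null(motion)) motion <- matrix(0, n - 1, 2)
  if (nrow(motion) != n - 1) stop("motion must have duration_frames - 1 rows")
  disp <- rbind(c(0, 0), apply(motion, 2, cumsum))
  margin <- patch_half + 8
  r_span <- range(disp[, 1]); c_span <- range(disp[, 2])
  H <- ceiling(diff(r_span)) + 2 * margin
  W <- ceiling(diff(c_span)) + 2 * margin
  start <- c(margin - r_span[1], margin - c_span[1])
  n_blobs <- max(8, round(texture_density * (2 * patch_half)^2))
  withr::with_seed(seed, {
    rel <- cbind(stats::runif(n_blobs, -patch_half + 2, patch_half - 2),
                 stats::runif(n_blobs, -patch_half + 2, patch_half - 2))
    amps <- stats::runif(n_blobs, 25, 60) * sample(c(-1, 1), n_blobs, TRUE)
    frames <- vector("list", n)
    truth_rois <- vector("list", n)
    for (i in seq_len(n)) {
      ctr <- start + disp[i, ]
      rect <- patch_rect(ctr, patch_half)
      if (rect[1] < 0 || rect[2] < 0 || rect[3] > H || rect[4] > W)
        stop("patch exits frame")
      fr <- matrix(60, H, W)
      tex <- render_blobs(H, W, cbind(rel[, 1] + ctr[1], rel[, 2] + ctr[2]),
                          amps, 2)
      box <- matrix(FALSE, H, W)
      box[(rect[1] + 1):rect[3], (rect[2] + 1):rect[4]] <- TRUE
      fr[box] <- 110 + tex[box]
      if (noise_sd > 0)
        fr <- fr + matrix(stats::rnorm(length(fr), 0, noise_sd), H)
      frames[[i]] <- fr
      truth_rois[[i]] <- roi(rect, label = "face")
    }
  })
  video <- frame_sequence(frames, 29, source_id = "synthetic_tracking")
  truth <- ground_truth("tracking", list(motion = motion), seed,
                        list(duration_frames = n, patch_half = patch_half,
                             texture_density = texture_density,
                             noise_sd = noise_sd))
  if (!is.null(out_dir)) {
    write_frame_sequence(video, out_dir)
    write_manifest(truth, out_dir)
  }
  list(video = video, truth_rois = truth_rois, truth = truth)
}

#' Synthetic paired invasive/remote series with a target correlation
#'
#' Bivariate Gaussian draws with the requested means, SDs and correlation.
#'
#' @param rho target correlation, strictly inside (-1, 1).
#' @param n number of pairs (at least 3).
#' @param means `(invasive, remote)` means.
#' @param sds `(invasive, remote)` SDs.
#' @param seed RNG seed.
#' @param quantity label for the pairs (default `"temperature_C"`).
#' @return A [paired_measurements()] with attribute `truth`.
#' @export
make_paired_series <- function(rho, n, means = c(38.6, 37.5),
                               sds = c(0.4, 0.4), seed = 1,
                               quantity = "temperature_C") {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (n < 3) stop("need n >= 3")
  withr::with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
  })
  inv <- means[1] + sds[1] * z1
  rem <- means[2] + sds[2] * (rho * z1 + sqrt(1 - rho^2) * z2)
  pm <- paired_measurements(
    data.frame(animal_id = "A1", period = "crush1",
               minute_index = seq_len(n) - 1L, invasive = inv, remote = rem),
    quantity = quantity)
  attr(pm, "truth") <- ground_truth("paired", rho, seed,
                                    list(n = n, means = means, sds = sds))
  pm
}
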
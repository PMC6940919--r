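#' Default ROI refresh ratio threshold
#'
#' A new ROI is only created when the ratio of surviving tracked points to
#' the previous point count is strictly higher than this value.
#' @export
REFRESH_RATIO <- 0.70

#' Propagate feature points between two frames (pyramidal KLT)
#'
#' A Kanade-Lucas-Tomasi sparse optical-flow step: each point's local window
#' in `prev_frame` is registered against `next_frame` by iterative
#' Lucas-Kanade refinement over an image pyramid. Points failing the
#' forward-backward consistency check (re-tracking the result back to the
#' first frame must land within `fb_err` pixels of the start) or leaving the
#' frame are dropped; survivors keep their order.
#'
#' @param prev_frame,next_frame rasters of identical shape (RGB averaged to
#'   gray).
#' @param points a [feature_point_set()] with at least one point.
#' @param levels pyramid levels (default 3).
#' @param win_half half window size; the window is `2*win_half+1` squared
#'   (default 15, i.e. 31x31), clamped at coarse levels.
#' @param max_iter,eps Lucas-Kanade iteration cap and convergence threshold
#'   in pixels.
#' @param fb_err forward-backward rejection radius in pixels (default 2).
#' @return A [feature_point_set()] of survivors at their new sub-pixel
#'   positions.
#' @export
propagate_points <- function(prev_frame, next_frame, points, levels = 3,
                             win_half = 15, max_iter = 20, eps = 0.01,
                             fb_err = 2) {
  prev_frame <- as_gray(prev_frame)
  next_frame <- as_gray(next_frame)
  if (!all(dim(prev_frame) == dim(next_frame))) stop("frame shapes differ")
  if (nrow(points$points) == 0) stop("no points to propagate")
  res <- .klt_propagate_cpp(prev_frame, next_frame, points$points,
                            levels, win_half, max_iter, eps, fb_err)
  feature_point_set(res$points[res$status, , drop = FALSE], points$detector,
                    points$frame_index + 1L)
}

#' Construct a tracking state
#'
#' @param roi current [roi()].
#' @param points current [feature_point_set()].
#' @param refresh_ratio_threshold survivors/previous ratio above which the
#'   ROI is rebuilt (default [REFRESH_RATIO], exactly 0.70).
#' @param lost whether tracking has been declared lost.
#' @param consecutive_failures count of consecutive refresh rejections.
#' @return An object of class `track_state`.
#' @export
track_state <- function(roi, points, refresh_ratio_threshold = REFRESH_RATIO,
                        lost = FALSE, consecutive_failures = 0L) {
  if (lost && nrow(points$points) > 0) stop("a lost state carries no points")
  structure(list(roi = roi, points = points,
                 refresh_ratio_threshold = refresh_ratio_threshold,
                 lost = lost,
                 consecutive_failures = as.integer(consecutive_failures)),
            class = "track_state")
}

# padded bounding rectangle of a point matrix, clipped to the frame
points_bbox_roi <- function(pts, frame_dim, label, pad_frac = 0.05) {
  r0 <- min(pts[, 1]); r1 <- max(pts[, 1])
  c0 <- min(pts[, 2]); c1 <- max(pts[, 2])
  diag_ <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
  pad <- pad_frac * diag_
  rect <- c(max(0, floor(r0 - pad)), max(0, floor(c0 - pad)),
            min(frame_dim[1], ceiling(r1 + pad) + 1),
            min(frame_dim[2], ceiling(c1 + pad) + 1))
  if (rect[3] <= rect[1]) rect[3] <- min(frame_dim[1], rect[1] + 1)
  if (rect[4] <= rect[2]) rect[4] <- min(frame_dim[2], rect[2] + 1)
  h <- rect[3] - rect[1]; w <- rect[4] - rect[2]
  # binary segmentation: pixels outside the reconstructed region are masked out
  roi(rect, mask = matrix(TRUE, h, w), label = label)
}

#' Refresh or retain the ROI from freshly tracked points (ratio gate)
#'
#' A new ROI -- the padded bounding rectangle of the surviving points, with a
#' binary mask excluding every pixel outside that region -- is only created
#' when the ratio of tracked survivors to the previous point count is
#' strictly higher than the state's threshold (default 0.70). Otherwise the
#' previous ROI is retained and the failure counter is incremented.
#'
#' @param state a [track_state()] that is not lost.
#' @param tracked the [feature_point_set()] returned by [propagate_points()].
#' @param frame_dim `(H, W)` of the frame, used to clip the new rectangle.
#' @return The updated `track_state`, with attribute `"refreshed"` (logical).
#' @export
reconstruct_roi <- function(state, tracked, frame_dim = NULL) {
  if (state$lost) stop("state is lost")
  n_prev <- nrow(state$points$points)
  n_new <- nrow(tracked$points)
  if (n_new == 0 && n_prev == 0) {
    out <- track_state(state$roi, tracked, state$refresh_ratio_threshold,
                       lost = TRUE,
                       consecutive_failures = state$consecutive_failures + 1L)
    attr(out, "refreshed") <- FALSE
    return(out)
  }
  ratio <- if (n_prev > 0) n_new / n_prev else 0
  if (ratio > state$refresh_ratio_threshold) {
    if (is.null(frame_dim))
      frame_dim <- c(max(state$roi$rect[3], ceiling(max(tracked$points[, 1])) + 1),
                     max(state$roi$rect[4], ceiling(max(tracked$points[, 2])) + 1))
    new_roi <- points_bbox_roi(tracked$points, frame_dim, state$roi$label)
    out <- track_state(new_roi, tracked, state$refresh_ratio_threshold,
                       lost = FALSE, consecutive_failures = 0L)
    attr(out, "refreshed") <- TRUE
  } else {
    out <- track_state(state$roi, tracked, state$refresh_ratio_threshold,
                       lost = FALSE,
                       consecutive_failures = state$consecutive_failures + 1L)
    attr(out, "refreshed") <- FALSE
  }
  out
}

#' Tracking accuracy as a percentage
#'
#' The share of frames in which the desired area was correctly tracked over
#' the total frames processed, reported to one decimal place.
#'
#' @param n_correct number of correctly tracked frames.
#' @param n_total total frames processed (positive).
#' @return `100 * n_correct / n_total`, rounded to one decimal.
#' @export
tracking_accuracy <- function(n_correct, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_correct < 0 || n_correct > n_total) stop("need 0 <= n_correct <= n_total")
  round(100 * n_correct / n_total, 1)
}

#' Track an ROI through a frame sequence
#'
#' Detects characteristic points inside the initial ROI (choosing the best
#' detector automatically unless one is named), propagates them frame to
#' frame with the pyramidal KLT tracker, and refreshes the ROI under the
#' ratio gate of [reconstruct_roi()]. When a refresh is rejected the chosen
#' detector is re-run inside the retained ROI; after `max_failures`
#' consecutive rejections the target is declared lost.
#'
#' A frame counts as correctly tracked either against ground truth (when
#' `truth_rois` is supplied: IoU of the tracked and true rectangles at least
#' `iou_threshold`) or, in field mode, when the state is not lost and the
#' latest refresh-or-retain succeeded with at least one surviving point.
#'
#' @param video a [frame_sequence()].
#' @param initial_roi [roi()] valid on frame 1.
#' @param detector optional detector name; default: automatic selection.
#' @param refresh_ratio_threshold ratio gate (default 0.70).
#' @param max_failures consecutive refresh rejections before declaring lost.
#' @param truth_rois optional list of true [roi()]s (one per frame) enabling
#'   IoU-based correctness accounting.
#' @param iou_threshold IoU cut-off for truth-mode correctness (default 0.5).
#' @return An object of class `tracking_result`: `per_frame` data.frame
#'   (`frame_index`, `n_points_in`, `n_points_tracked`, `refreshed`,
#'   `correctly_tracked`, `has_roi`), `rois` (list of per-frame [roi()] or
#'   NULL after loss), `detector`, and `accuracy_percent`.
#' @export
track_sequence <- function(video, initial_roi, detector = NULL,
                           refresh_ratio_threshold = REFRESH_RATIO,
                           max_failures = 15, truth_rois = NULL,
                           iou_threshold = 0.5) {
  frames <- lapply(video$frames, as_gray)
  n <- length(frames)
  fd <- dim(frames[[1]])
  if (!roi_in_frame(initial_roi, fd)) stop("initial_roi outside frame bounds")
  if (is.null(detector)) {
    sel <- select_detector(frames[[1]], initial_roi)  # errors on failure
    detector <- sel$detector
    pts <- sel$points
  } else {
    pts <- detect_features(frames[[1]], initial_roi, detector)
    if (nrow(pts$points) == 0)
      stop("detection failure on frame 0 with detector '", detector, "'")
  }
  state <- track_state(initial_roi, pts, refresh_ratio_threshold)
  rois <- vector("list", n)
  rois[[1]] <- initial_roi
  rec <- data.frame(frame_index = seq_len(n) - 1L, n_points_in = 0L,
                    n_points_tracked = 0L, refreshed = FALSE,
                    correctly_tracked = FALSE, has_roi = FALSE)
  correct <- function(i, refreshed, n_tracked, lost) {
    if (!is.null(truth_rois)) {
      !lost && !is.null(rois[[i]]) &&
        roi_iou(rois[[i]], truth_rois[[i]]) >= iou_threshold
    } else {
      !lost && (refreshed || n_tracked >= 1)
    }
  }
  rec$n_points_in[1] <- rec$n_points_tracked[1] <- nrow(pts$points)
  rec$has_roi[1] <- TRUE
  rec$correctly_tracked[1] <- correct(1, FALSE, nrow(pts$points), FALSE)

  for (i in 2:n) {
    if (state$lost) {
      rois[i] <- list(NULL)
      next  # record stays: no roi, not correct
    }
    n_in <- nrow(state$points$points)
    tracked <- if (n_in > 0)
      propagate_points(frames[[i - 1]], frames[[i]], state$points)
    else feature_point_set(matrix(numeric(0), 0, 2), detector, i - 1L)
    state <- reconstruct_roi(state, tracked, fd)
    refreshed <- attr(state, "refreshed")
    n_tr <- nrow(tracked$points)
    if (!refreshed && !state$lost) {
      redetected <- tryCatch(detect_features(frames[[i]], state$roi, detector),
                             error = function(e) NULL)
      if (!is.null(redetected) && nrow(redetected$points) > 0) {
        state$points <- redetected
      }
      if (state$consecutive_failures >= max_failures ||
          nrow(state$points$points) == 0) {
        state <- track_state(state$roi,
                             feature_point_set(matrix(numeric(0), 0, 2),
                                               detector, i - 1L),
                             state$refresh_ratio_threshold, lost = TRUE,
                             consecutive_failures = state$consecutive_failures)
      }
    }
    rois[i] <- if (state$lost) list(NULL) else list(state$roi)
    rec$n_points_in[i] <- n_in
    rec$n_points_tracked[i] <- n_tr
    rec$refreshed[i] <- refreshed
    rec$has_roi[i] <- !state$lost
    rec$correctly_tracked[i] <- correct(i, refreshed, n_tr, state$lost)
  }
  structure(list(per_frame = rec, rois = rois, detector = detector,
                 accuracy_percent = tracking_accuracy(sum(rec$correctly_tracked), n)),
            class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf("<tracking_result> %d frames, detector %s, accuracy %.1f%%\n",
              nrow(x$per_frame), x$detector, x$accuracy_percent))
  invisible(x)
}

#' Build a tracking result from a known ROI trajectory
#'
#' Utility for driving the signal-extraction stages with a fixed or
#' externally known ROI per frame (e.g. generator ground truth or a static
#' crop), bypassing the KLT tracker.
#'
#' @param rois a single [roi()] (replicated) or a list of per-frame ROIs
#'   (NULL entries mark lost frames).
#' @param n_frames number of frames covered.
#' @return A `tracking_result`.
#' @export
tracking_from_rois <- function(rois, n_frames) {
  if (inherits(rois, "roi")) rois <- rep(list(rois), n_frames)
  if (length(rois) != n_frames) stop("need one roi per frame")
  has <- !vapply(rois, is.null, logical(1))
  rec <- data.frame(frame_index = seq_len(n_frames) - 1L, n_points_in = 0L,
                    n_points_tracked = 0L, refreshed = FALSE,
                    correctly_tracked = has, has_roi = has)
  structure(list(per_frame = rec, rois = rois, detector = "none",
                 accuracy_percent = tracking_accuracy(sum(has), n_frames)),
            class = "tracking_result")
}
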
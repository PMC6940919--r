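test_that("propagation over identical frames keeps all points in place", {
  fx <- make_tracking_sequence(matrix(0, 1, 2), duration_frames = 2, seed = 5)
  pts <- detect_features(fx$video$frames[[1]], fx$truth_rois[[1]], "min_eigenvalue")
  tr <- propagate_points(fx$video$frames[[1]], fx$video$frames[[2]], pts)
  expect_identical(nrow(tr$points), nrow(pts$points))
  expect_lt(max(abs(tr$points - pts$points)), 0.1)
})

test_that("propagation recovers a commanded rigid shift to sub-pixel accuracy", {
  fx <- make_tracking_sequence(matrix(c(0, 2), 1, 2), duration_frames = 2, seed = 5)
  pts <- detect_features(fx$video$frames[[1]], fx$truth_rois[[1]], "min_eigenvalue")
  tr <- propagate_points(fx$video$frames[[1]], fx$video$frames[[2]], pts)
  expect_gt(nrow(tr$points), 0)
  disp <- colMeans(tr$points) - colMeans(pts$points[seq_len(nrow(pts$points)) %in%
    seq_len(nrow(pts$points)), , drop = FALSE])
  # survivors keep order, so compare like with like when all survive
  if (nrow(tr$points) == nrow(pts$points))
    disp <- colMeans(tr$points - pts$points)
  expect_lt(abs(disp[1] - 0), 0.25)
  expect_lt(abs(disp[2] - 2), 0.25)
  expect_error(propagate_points(matrix(0, 4, 4), matrix(0, 5, 5), pts),
               "shapes differ")
})

test_that("points whose region leaves the frame are dropped, survivors stay in bounds", {
  # patch starts near the right edge and is pushed out of frame
  fx <- make_tracking_sequence(matrix(c(0, 30), 1, 2, byrow = TRUE),
                               duration_frames = 2, seed = 9, patch_half = 12)
  f1 <- fx$video$frames[[1]]
  # crop the second frame's columns so the patch content is truly gone
  f2 <- f1 * 0 + 60
  pts <- detect_features(f1, fx$truth_rois[[1]], "min_eigenvalue")
  tr <- propagate_points(f1, f2, pts)
  expect_lt(nrow(tr$points), nrow(pts$points))
  if (nrow(tr$points)) {
    expect_true(all(tr$points[, 1] >= 0 & tr$points[, 1] <= nrow(f1) - 1))
    expect_true(all(tr$points[, 2] >= 0 & tr$points[, 2] <= ncol(f1) - 1))
  }
})

test_that("the ratio gate refreshes iff survivors/previous exceeds 0.70", {
  mkpts <- function(n) feature_point_set(
    cbind(10 + seq_len(n), 10 + seq_len(n)), "min_eigenvalue")
  for (k in 0:10) {
    st <- track_state(roi(c(5, 5, 30, 30), label = "eye_area"), mkpts(10))
    out <- reconstruct_roi(st, mkpts(k), frame_dim = c(64, 64))
    expect_identical(attr(out, "refreshed"), k / 10 > 0.70,
                     info = paste("k =", k))
    if (k / 10 > 0.70) {
      expect_identical(out$consecutive_failures, 0L)
      expect_false(is.null(out$roi$mask))  # outside pixels masked
    } else {
      expect_equal(out$roi$rect, st$roi$rect)  # previous roi retained
      expect_identical(out$consecutive_failures, 1L)
    }
  }
  # boundary: exactly 0.70 must NOT refresh
  st <- track_state(roi(c(5, 5, 30, 30), label = "eye_area"), mkpts(10))
  out <- reconstruct_roi(st, mkpts(7), frame_dim = c(64, 64))
  expect_false(attr(out, "refreshed"))
})

test_that("a refreshed ROI is the padded bounding box of the survivors", {
  pts <- feature_point_set(rbind(c(10, 12), c(20, 30), c(15, 18)), "fast")
  st <- track_state(roi(c(0, 0, 40, 40), label = "face"), pts)
  out <- reconstruct_roi(st, pts, frame_dim = c(64, 64))
  expect_true(attr(out, "refreshed"))
  r <- out$roi$rect
  expect_lte(r[1], 10); expect_lte(r[2], 12)
  expect_gte(r[3], 21); expect_gte(r[4], 31)
  # padding is 5% of the bbox diagonal, so the box stays tight
  expect_gte(r[1], 10 - 3); expect_gte(r[2], 12 - 3)
  expect_lte(r[3], 21 + 3); expect_lte(r[4], 31 + 3)
})

test_that("losing every point on a lost-input state declares the track lost", {
  empty <- feature_point_set(matrix(numeric(0), 0, 2), "fast")
  st <- track_state(roi(c(5, 5, 30, 30), label = "eye_area"), empty)
  out <- reconstruct_roi(st, empty, frame_dim = c(64, 64))
  expect_true(out$lost)
  expect_error(reconstruct_roi(out, empty), "lost")
})

test_that("tracking accuracy reproduces printed frame-count ratios", {
  expect_identical(tracking_accuracy(124207, 134966), 92.0)
  expect_identical(tracking_accuracy(124526, 134966), 92.3)
  expect_identical(tracking_accuracy(118813, 125715), 94.5)
  expect_identical(tracking_accuracy(0, 1000), 0)
  expect_error(tracking_accuracy(5, 0), "positive")
  expect_error(tracking_accuracy(7, 5), "n_correct")
})

test_that("a static textured sequence tracks with 100% accuracy, deterministically", {
  fx <- make_tracking_sequence(matrix(0, 59, 2), duration_frames = 60, seed = 7)
  res <- track_sequence(fx$video, fx$truth_rois[[1]])
  expect_identical(res$accuracy_percent, 100)
  expect_identical(nrow(res$per_frame), 60L)
  res2 <- track_sequence(fx$video, fx$truth_rois[[1]])
  expect_identical(res$per_frame, res2$per_frame)
  expect_identical(res$rois, res2$rois)
})

test_that("a drifting target is followed with high IoU against ground truth", {
  fx <- make_tracking_sequence(matrix(1, 79, 2), duration_frames = 80, seed = 13)
  res <- track_sequence(fx$video, fx$truth_rois[[1]], truth_rois = fx$truth_rois)
  iou <- iou_trace(res, fx$truth_rois)
  expect_gte(mean(iou >= 0.5), 0.95)
  # recovered ROI centroid displacement matches the commanded 1 px/frame drift
  ctr <- t(vapply(res$rois, function(r) c((r$rect[1] + r$rect[3]) / 2,
                                          (r$rect[2] + r$rect[4]) / 2),
                  numeric(2)))
  step <- diff(ctr)
  expect_lt(max(abs(step - 1)), 0.5 + 1)  # integer rects quantize the centroid
  expect_lt(abs(mean(step) - 1), 0.1)
})

test_that("a target that vanishes mid-sequence is marked not correctly tracked", {
  fx <- make_tracking_sequence(matrix(0, 39, 2), duration_frames = 40, seed = 15)
  frames <- fx$video$frames
  for (i in 21:40) frames[[i]] <- frames[[i]] * 0 + 60  # target gone
  vid <- frame_sequence(frames, 29)
  res <- track_sequence(vid, fx$truth_rois[[1]], detector = "min_eigenvalue",
                        max_failures = 5)
  expect_lt(res$accuracy_percent, 100)
  expect_true(any(!res$per_frame$has_roi))
  after_loss <- which(!res$per_frame$has_roi)
  expect_true(all(!res$per_frame$correctly_tracked[after_loss]))
  expect_true(all(after_loss > 20))
})
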
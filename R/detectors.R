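#' Feature detector vocabulary, in tie-break priority order
#' @export
DETECTORS <- c("min_eigenvalue", "surf", "brisk", "fast", "harris", "hog")

as_gray <- function(frame) {
  if (length(dim(frame)) == 3) (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
  else frame
}

crop_rect <- function(frame, rect) {
  frame[(rect[1] + 1):rect[3], (rect[2] + 1):rect[4], drop = FALSE]
}

gauss_blur <- function(x, sigma) {
  # EBImage's gblur needs the raster to be larger than the brush
  radius <- min(2 * ceiling(3 * sigma) + 1, 2 * (min(dim(x)) %/% 2) - 1)
  if (radius < 3) return(x)
  EBImage::gblur(x, sigma = sigma, radius = radius)
}

SOBEL_R <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 8
SOBEL_C <- t(SOBEL_R)

conv2 <- function(x, k) EBImage::filter2(x, k, boundary = "replicate")

# local maxima (8-neighbourhood, strict against at least one side) of a
# response matrix; returns a 2-column matrix of 1-based (row, col) indices
local_maxima <- function(resp) {
  nr <- nrow(resp); nc <- ncol(resp)
  if (nr < 3 || nc < 3) return(matrix(numeric(0), 0, 2))
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- resp
  ok <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    # ties broken toward the earlier pixel in column-major order
    if (dr > 0 || (dr == 0 && dc > 0)) ok <- ok & (resp >= nb)
    else ok <- ok & (resp > nb)
  }
  which(ok, arr.ind = TRUE)
}

# greedy strongest-first selection with a minimum pairwise distance
select_spaced <- function(pts, score, min_dist = 3, max_points = 80) {
  if (nrow(pts) == 0) return(pts)
  ord <- order(score, decreasing = TRUE)
  pts <- pts[ord, , drop = FALSE]
  keep <- logical(nrow(pts))
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(pts))) {
    if (nrow(kept) >= max_points) break
    if (nrow(kept) == 0 ||
        min((kept[, 1] - pts[i, 1])^2 + (kept[, 2] - pts[i, 2])^2) >= min_dist^2) {
      keep[i] <- TRUE
      kept <- rbind(kept, pts[i, ])
    }
  }
  pts[keep, , drop = FALSE]
}

intensity_scale <- function(x) max(abs(x)) + 1

# corner response detectors share the structure-tensor machinery
structure_tensor_response <- function(crop, kind) {
  g <- gauss_blur(crop, 1)
  gx <- conv2(g, SOBEL_C)  # d/dcol
  gy <- conv2(g, SOBEL_R)  # d/drow
  sxx <- gauss_blur(gx * gx, 1.5)
  syy <- gauss_blur(gy * gy, 1.5)
  sxy <- gauss_blur(gx * gy, 1.5)
  tr <- sxx + syy
  det <- sxx * syy - sxy * sxy
  if (kind == "harris") det - 0.04 * tr^2
  else (tr - sqrt(pmax(tr^2 - 4 * det, 0))) / 2  # smaller eigenvalue
}

detect_response_peaks <- function(resp, crop, rel_thresh = 0.01) {
  floor_ <- (1e-6 * intensity_scale(crop))^2
  m <- max(resp)
  if (!is.finite(m) || m <= floor_) return(list(pts = matrix(numeric(0), 0, 2),
                                                score = numeric(0)))
  idx <- local_maxima(resp)
  if (nrow(idx) == 0) return(list(pts = matrix(numeric(0), 0, 2), score = numeric(0)))
  sc <- resp[idx]
  keep <- sc > max(rel_thresh * m, floor_)
  list(pts = idx[keep, , drop = FALSE], score = sc[keep])
}

# FAST-9/16 segment test on a crop; returns (pts, score)
fast_detect <- function(crop, threshold = NULL) {
  nr <- nrow(crop); nc <- ncol(crop)
  empty <- list(pts = matrix(numeric(0), 0, 2), score = numeric(0))
  if (nr < 8 || nc < 8) return(empty)
  rng <- diff(range(crop))
  if (is.null(threshold)) threshold <- 0.08 * rng
  if (rng <= 1e-6 * intensity_scale(crop)) return(empty)
  offs <- rbind(c(-3, 0), c(-3, 1), c(-2, 2), c(-1, 3), c(0, 3), c(1, 3),
                c(2, 2), c(3, 1), c(3, 0), c(3, -1), c(2, -2), c(1, -3),
                c(0, -3), c(-1, -3), c(-2, -2), c(-3, -1))
  ri <- 4:(nr - 3); ci <- 4:(nc - 3)
  ctr <- crop[ri, ci]
  npix <- length(ctr)
  bright <- dark <- matrix(FALSE, npix, 16)
  absdev <- matrix(0, npix, 16)
  for (k in 1:16) {
    sh <- crop[ri + offs[k, 1], ci + offs[k, 2]]
    d <- as.vector(sh - ctr)
    bright[, k] <- d > threshold
    dark[, k] <- d < -threshold
    absdev[, k] <- pmax(abs(d) - threshold, 0)
  }
  run9 <- function(m) {
    m2 <- cbind(m, m[, 1:8])
    hit <- rep(FALSE, nrow(m))
    for (s in 1:16) {
      all9 <- m2[, s]
      for (j in 1:8) all9 <- all9 & m2[, s + j]
      hit <- hit | all9
    }
    hit
  }
  corner <- run9(bright) | run9(dark)
  if (!any(corner)) return(empty)
  score <- rep(0, npix)
  score[corner] <- rowSums(absdev[corner, , drop = FALSE])
  smat <- matrix(0, nr, nc)
  smat[ri, ci] <- matrix(score, length(ri), length(ci))
  idx <- local_maxima(smat)
  keep <- smat[idx] > 0
  list(pts = idx[keep, , drop = FALSE], score = smat[idx][keep])
}

block_mean_2 <- function(x) {
  nr <- nrow(x) %/% 2; nc <- ncol(x) %/% 2
  if (nr < 1 || nc < 1) return(NULL)
  x <- x[1:(2 * nr), 1:(2 * nc), drop = FALSE]
  (x[seq(1, 2 * nr, 2), seq(1, 2 * nc, 2)] + x[seq(2, 2 * nr, 2), seq(1, 2 * nc, 2)] +
   x[seq(1, 2 * nr, 2), seq(2, 2 * nc, 2)] + x[seq(2, 2 * nr, 2), seq(2, 2 * nc, 2)]) / 4
}

# determinant-of-Hessian blob/corner points (SURF-style interest operator)
surf_detect <- function(crop) {
  pts <- matrix(numeric(0), 0, 2); score <- numeric(0)
  floor_ <- (1e-6 * intensity_scale(crop))^2
  for (sigma in c(2, 3.5)) {
    g <- gauss_blur(crop, sigma)
    nr <- nrow(g); nc <- ncol(g)
    if (nr < 5 || nc < 5) next
    lrr <- g * 0; lcc <- g * 0; lrc <- g * 0
    i <- 2:(nr - 1); j <- 2:(nc - 1)
    lrr[i, j] <- g[i + 1, j] - 2 * g[i, j] + g[i - 1, j]
    lcc[i, j] <- g[i, j + 1] - 2 * g[i, j] + g[i, j - 1]
    lrc[i, j] <- (g[i + 1, j + 1] - g[i + 1, j - 1] - g[i - 1, j + 1] + g[i - 1, j - 1]) / 4
    doh <- sigma^4 * (lrr * lcc - 0.81 * lrc^2)
    pk <- detect_response_peaks(doh, crop, rel_thresh = 0.02)
    pts <- rbind(pts, pk$pts); score <- c(score, pk$score)
  }
  list(pts = pts, score = score)
}

# FAST over a two-level scale pyramid (BRISK-style scale-space corners)
brisk_detect <- function(crop) {
  p1 <- fast_detect(crop)
  res <- list(pts = p1$pts, score = p1$score)
  half <- block_mean_2(crop)
  if (!is.null(half) && min(dim(half)) >= 8) {
    p2 <- fast_detect(half)
    if (nrow(p2$pts)) {
      up <- p2$pts * 2 - 0.5  # centre of the 2x2 block at full resolution
      keepnew <- rep(TRUE, nrow(up))
      if (nrow(res$pts)) {
        for (i in seq_len(nrow(up)))
          keepnew[i] <- min((res$pts[, 1] - up[i, 1])^2 +
                            (res$pts[, 2] - up[i, 2])^2) > 4
      }
      res$pts <- rbind(res$pts, up[keepnew, , drop = FALSE])
      res$score <- c(res$score, p2$score[keepnew])
    }
  }
  res
}

# local maxima of gradient-magnitude energy on a cell grid (HOG-style)
hog_detect <- function(crop, cell = 8) {
  nr <- nrow(crop); nc <- ncol(crop)
  empty <- list(pts = matrix(numeric(0), 0, 2), score = numeric(0))
  ncr <- nr %/% cell; ncc <- nc %/% cell
  if (ncr < 1 || ncc < 1) return(empty)
  g <- gauss_blur(crop, 1)
  gx <- conv2(g, SOBEL_C); gy <- conv2(g, SOBEL_R)
  m2 <- gx^2 + gy^2
  energy <- matrix(0, ncr, ncc)
  for (a in 1:ncr) for (b in 1:ncc)
    energy[a, b] <- sum(m2[((a - 1) * cell + 1):(a * cell),
                           ((b - 1) * cell + 1):(b * cell)])
  floor_ <- (1e-6 * intensity_scale(crop))^2 * cell^2
  if (max(energy) <= floor_) return(empty)
  if (ncr < 3 || ncc < 3) {
    idx <- which(energy == max(energy), arr.ind = TRUE)[1, , drop = FALSE]
  } else {
    idx <- local_maxima(energy)
    keep <- energy[idx] > max(0.05 * max(energy), floor_)
    idx <- idx[keep, , drop = FALSE]
  }
  if (nrow(idx) == 0) return(empty)
  pts <- matrix(0, nrow(idx), 2)
  for (i in seq_len(nrow(idx))) {
    rows <- ((idx[i, 1] - 1) * cell + 1):(idx[i, 1] * cell)
    cols <- ((idx[i, 2] - 1) * cell + 1):(idx[i, 2] * cell)
    w <- m2[rows, cols]
    tot <- sum(w)
    pts[i, 1] <- sum(outer(rows, rep(1, length(cols))) * w) / tot
    pts[i, 2] <- sum(outer(rep(1, length(rows)), cols) * w) / tot
  }
  list(pts = pts, score = energy[idx])
}

#' Construct a feature point set
#'
#' @param points numeric matrix with columns (row, col), 0-based sub-pixel
#'   frame coordinates; may have zero rows as a detection-failure sentinel.
#' @param detector one of [DETECTORS].
#' @param frame_index integer frame index the points belong to.
#' @return An object of class `feature_point_set`.
#' @export
feature_point_set <- function(points, detector, frame_index = 0L) {
  points <- matrix(as.numeric(points), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  if (!detector %in% DETECTORS) stop("unknown detector '", detector, "'")
  structure(list(points = points, detector = detector,
                 frame_index = as.integer(frame_index)),
            class = "feature_point_set")
}

#' @export
print.feature_point_set <- function(x, ...) {
  cat(sprintf("<feature_point_set> %d points, detector %s, frame %d\n",
              nrow(x$points), x$detector, x$frame_index))
  invisible(x)
}

#' Detect characteristic points inside an ROI
#'
#' Runs one of six interest-point operators on the ROI crop of a grayscale
#' frame: `min_eigenvalue` (Shi-Tomasi smaller structure-tensor eigenvalue),
#' `surf` (determinant-of-Hessian blobs at two scales), `brisk` (FAST over a
#' scale pyramid), `fast` (FAST-9/16 segment test), `harris` (corner/edge
#' response) and `hog` (local maxima of gradient-magnitude energy on a cell
#' grid). Returned points lie inside the ROI (mask-respecting), in 0-based
#' frame coordinates, strongest first, spaced at least 3 px apart.
#'
#' @param frame 2-D numeric raster (RGB arrays are averaged to gray).
#' @param roi a [roi()] within the frame.
#' @param detector one of [DETECTORS].
#' @param frame_index frame index recorded in the result.
#' @param max_points cap on the number of points returned.
#' @return A [feature_point_set()]; empty when no feature exceeds threshold
#'   (e.g. on uniform-intensity frames).
#' @export
detect_features <- function(frame, roi, detector = "min_eigenvalue",
                            frame_index = 0L, max_points = 80) {
  if (!detector %in% DETECTORS) stop("unknown detector '", detector, "'")
  frame <- as_gray(frame)
  if (!roi_in_frame(roi, dim(frame))) stop("roi outside frame bounds")
  crop <- crop_rect(frame, roi$rect)
  res <- switch(detector,
    min_eigenvalue = detect_response_peaks(
      structure_tensor_response(crop, "mineig"), crop),
    harris = detect_response_peaks(structure_tensor_response(crop, "harris"), crop),
    fast = fast_detect(crop),
    brisk = brisk_detect(crop),
    surf = surf_detect(crop),
    hog = hog_detect(crop))
  pts <- res$pts
  if (nrow(pts)) {
    # exclude the crop border where responses are boundary artefacts
    inner <- pts[, 1] >= 3 & pts[, 1] <= nrow(crop) - 2 &
             pts[, 2] >= 3 & pts[, 2] <= ncol(crop) - 2
    pts <- pts[inner, , drop = FALSE]
    sc <- res$score[inner]
    if (!is.null(roi$mask) && nrow(pts)) {
      mi <- pmin(pmax(round(pts[, 1]), 1), nrow(roi$mask))
      mj <- pmin(pmax(round(pts[, 2]), 1), ncol(roi$mask))
      keep <- roi$mask[cbind(mi, mj)]
      pts <- pts[keep, , drop = FALSE]
      sc <- sc[keep]
    }
    pts <- select_spaced(pts, sc, min_dist = 3, max_points = max_points)
  }
  if (nrow(pts)) {
    # crop-local 1-based -> frame 0-based
    pts[, 1] <- pts[, 1] - 1 + roi$rect[1]
    pts[, 2] <- pts[, 2] - 1 + roi$rect[2]
  }
  feature_point_set(pts, detector, frame_index)
}

#' Automatically choose the detector that best represents the ROI
#'
#' All six detectors are run inside the ROI and scored by the number of valid
#' points they return; ties are broken by the fixed priority order of
#' [DETECTORS]. Deterministic given its inputs.
#'
#' @inheritParams detect_features
#' @return A list with `detector` (the winning name) and `points` (its
#'   [feature_point_set()]).
#' @export
select_detector <- function(frame, roi, frame_index = 0L, max_points = 80) {
  best <- NULL
  for (d in DETECTORS) {
    fs <- tryCatch(detect_features(frame, roi, d, frame_index, max_points),
                   error = function(e) NULL)
    if (is.null(fs)) next
    if (is.null(best) || nrow(fs$points) > nrow(best$points)) best <- fs
  }
  if (is.null(best) || nrow(best$points) == 0)
    stop("detection failure: no detector found features inside the ROI")
  list(detector = best$detector, points = best)
}
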
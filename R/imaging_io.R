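#' Region-of-interest labels used throughout the pipeline
#'
#' The five anatomical areas the pipeline extracts signals from: eye area,
#' forehead and face (heart rate), eye area and ear base (temperature), and
#' nose (respiration).
#' @export
ROI_LABELS <- c("eye_area", "forehead", "face", "ear_base", "nose")

#' Default thermal-camera emissivity
#'
#' Mammalian skin emissivity assumed by the radiometric camera when a
#' metadata file does not override it.
#' @export
DEFAULT_EMISSIVITY <- 0.985

# ---- FrameSequence ---------------------------------------------------------

#' Construct a frame sequence
#'
#' An ordered set of equally shaped pixel rasters with timing information.
#' Frames are numeric matrices (grayscale) or `H x W x 3` arrays with
#' channels ordered red, green, blue. Intensities are conventionally on the
#' 0--255 scale but any finite numeric scale is accepted.
#'
#' @param frames list of matrices or 3-channel arrays, all the same size.
#' @param frame_rate frames per second (positive).
#' @param timestamps seconds from sequence start, one per frame; defaults to
#'   `(seq_along(frames) - 1) / frame_rate`.
#' @param source_id free-text provenance label.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate, timestamps = NULL, source_id = "") {
  if (!is.list(frames) || length(frames) == 0L)
    stop("'frames' must be a non-empty list of rasters")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("'frame_rate' must be a positive scalar")
  d1 <- dim(frames[[1]])
  for (f in frames) {
    d <- dim(f)
    if (length(d) != length(d1) || any(d != d1))
      stop("all frames must share identical dimensions")
  }
  if (is.null(timestamps)) timestamps <- (seq_along(frames) - 1) / frame_rate
  if (length(timestamps) != length(frames))
    stop("one timestamp per frame required")
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(frames = frames, frame_rate = frame_rate,
                 timestamps = timestamps, source_id = source_id),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames, %s, %.6g fps, %.2f s%s\n",
              length(x$frames),
              if (length(d) == 3) sprintf("%dx%dx3", d[1], d[2])
              else sprintf("%dx%d", d[1], d[2]),
              x$frame_rate, utils::tail(x$timestamps, 1),
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' Number of colour channels in a frame sequence
#' @param video a `frame_sequence`.
#' @return 1 for grayscale, 3 for RGB.
#' @export
n_channels <- function(video) {
  if (length(dim(video$frames[[1]])) == 3) 3L else 1L
}

#' Read a frame sequence from a directory of numbered image files
#'
#' Frames are read in lexicographic order of their file names (zero-padded
#' numbering recommended). PNG and TIFF files are supported; pixel values are
#' rescaled to the 0--255 convention. Timestamps are synthesized as
#' `index / frame_rate`.
#'
#' @param path directory containing the frames.
#' @param frame_rate_override frames per second; defaults to 29 (the RGB
#'   camera rate) when not given.
#' @return A [frame_sequence()].
#' @export
read_frame_sequence <- function(path, frame_rate_override = NULL) {
  if (!dir.exists(path)) stop("unreadable path: ", path)
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("zero decodable frames in ", path)
  frames <- lapply(files, function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
           else tiff::readTIFF(f)
    d <- dim(img)
    if (length(d) == 3 && d[3] >= 3) img <- img[, , 1:3, drop = FALSE]
    else if (length(d) == 3 && d[3] == 1) img <- img[, , 1]
    img * 255
  })
  rate <- if (is.null(frame_rate_override)) 29 else frame_rate_override
  if (rate <= 0) stop("'frame_rate_override' must be positive")
  fs <- tryCatch(frame_sequence(frames, rate, source_id = path),
                 error = function(e) stop("inconsistent frame shapes in ", path))
  fs
}

#' Write a frame sequence as a stack of numbered PNG files
#'
#' Intensities are clipped to \[0, 255\] and quantized to 8 bits; the
#' write/read round trip is exact for integer-valued frames on that scale.
#'
#' @param video a `frame_sequence`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_frame_sequence <- function(video, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- length(video$frames)
  fmt <- paste0("frame_%0", max(4, nchar(n)), "d.png")
  for (i in seq_len(n)) {
    img <- pmin(pmax(video$frames[[i]], 0), 255) / 255
    png::writePNG(img, file.path(path, sprintf(fmt, i)))
  }
  invisible(path)
}

# ---- RadiometricSequence ---------------------------------------------------

#' Construct a radiometric (calibrated temperature) sequence
#'
#' @param frames list of matrices holding surface temperature in degrees
#'   Celsius per pixel.
#' @param frame_rate frames per second (thermal cameras here record at 1 fps).
#' @param emissivity assumed surface emissivity in (0, 1]; defaults to
#'   [DEFAULT_EMISSIVITY].
#' @param timestamps seconds from start; defaults to `index / frame_rate`.
#' @return An object of class `radiometric_sequence`.
#' @export
radiometric_sequence <- function(frames, frame_rate = 1,
                                 emissivity = DEFAULT_EMISSIVITY,
                                 timestamps = NULL) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("'frames' must be a non-empty list of temperature rasters")
  d1 <- dim(frames[[1]])
  for (f in frames) {
    if (!all(dim(f) == d1)) stop("raster dimensions differ across frames")
    if (!all(is.finite(f))) stop("non-finite temperatures")
  }
  if (emissivity <= 0 || emissivity > 1) stop("emissivity must be in (0, 1]")
  if (is.null(timestamps)) timestamps <- (seq_along(frames) - 1) / frame_rate
  structure(list(frames = frames, frame_rate = frame_rate,
                 emissivity = emissivity, timestamps = timestamps),
            class = "radiometric_sequence")
}

#' @export
print.radiometric_sequence <- function(x, ...) {
  rng <- range(unlist(lapply(x$frames, range)))
  cat(sprintf(
    "<radiometric_sequence> %d frames %dx%d, %.6g fps, emissivity %.3f, %.1f-%.1f degC\n",
    length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
    x$frame_rate, x$emissivity, rng[1], rng[2]))
  invisible(x)
}

#' Write a radiometric sequence as float TIFF plus JSON sidecar
#'
#' Temperatures are stored as 32-bit floats in a multi-page TIFF, normalised
#' to \[0, 1\] with the scale and offset recorded in the JSON sidecar along
#' with emissivity, frame rate and timestamps.
#'
#' @param seq a `radiometric_sequence`.
#' @param raster_path output `.tiff` path.
#' @param metadata_path output `.json` path.
#' @return `raster_path`, invisibly.
#' @export
write_radiometric_pair <- function(seq, raster_path, metadata_path) {
  vals <- unlist(lapply(seq$frames, range))
  lo <- min(vals); hi <- max(vals)
  scale <- if (hi > lo) hi - lo else 1
  planes <- lapply(seq$frames, function(f) (f - lo) / scale)
  tiff::writeTIFF(planes, raster_path, bits.per.sample = 32L)
  meta <- list(offset_C = lo, scale_C = scale, emissivity = seq$emissivity,
               frame_rate = seq$frame_rate, timestamps = seq$timestamps)
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA)
  invisible(raster_path)
}

#' Read a radiometric raster/metadata pair
#'
#' @param raster_path multi-page float TIFF of normalised temperatures.
#' @param metadata_path JSON sidecar with `offset_C`, `scale_C` and optional
#'   `emissivity`, `frame_rate`, `timestamps`. When emissivity is absent it
#'   defaults to [DEFAULT_EMISSIVITY] (0.985).
#' @return A [radiometric_sequence()].
#' @export
read_radiometric_pair <- function(raster_path, metadata_path) {
  if (!file.exists(metadata_path)) stop("missing metadata file: ", metadata_path)
  if (!file.exists(raster_path)) stop("missing raster file: ", raster_path)
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  planes <- tiff::readTIFF(raster_path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  off <- if (!is.null(meta$offset_C)) meta$offset_C else 0
  sc <- if (!is.null(meta$scale_C)) meta$scale_C else 1
  frames <- lapply(planes, function(p) p * sc + off)
  d1 <- dim(frames[[1]])
  for (f in frames) if (!all(dim(f) == d1)) stop("shape mismatch between planes")
  if (!all(vapply(frames, function(f) all(is.finite(f)), logical(1))))
    stop("non-finite temperatures")
  radiometric_sequence(
    frames,
    frame_rate = if (!is.null(meta$frame_rate)) meta$frame_rate else 1,
    emissivity = if (!is.null(meta$emissivity)) meta$emissivity else DEFAULT_EMISSIVITY,
    timestamps = if (!is.null(meta$timestamps)) meta$timestamps else NULL)
}

# ---- Roi -------------------------------------------------------------------

#' Construct a region of interest
#'
#' Rectangles use 0-based, half-open `(row0, col0, row1, col1)` coordinates:
#' rows `row0 .. row1 - 1` and columns `col0 .. col1 - 1` are inside.
#'
#' @param rect integer-ish vector `(row0, col0, row1, col1)`.
#' @param mask optional logical matrix of the rectangle's shape selecting the
#'   pixels that belong to the region; must select at least one pixel.
#' @param label one of [ROI_LABELS].
#' @return An object of class `roi`.
#' @export
roi <- function(rect, mask = NULL, label = "eye_area") {
  rect <- as.numeric(rect)
  if (length(rect) != 4L) stop("'rect' must be (row0, col0, row1, col1)")
  if (rect[3] <= rect[1] || rect[4] <= rect[2]) stop("empty rectangle")
  if (!label %in% ROI_LABELS)
    stop("unknown label '", label, "'; must be one of ",
         paste(ROI_LABELS, collapse = ", "))
  h <- rect[3] - rect[1]; w <- rect[4] - rect[2]
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    storage.mode(mask) <- "logical"
    if (nrow(mask) != h || ncol(mask) != w)
      stop("mask shape must equal rect shape")
    if (!any(mask)) stop("mask selects no pixels")
  }
  structure(list(rect = rect, mask = mask, label = label), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %s rows [%g,%g) cols [%g,%g)%s\n", x$label,
              x$rect[1], x$rect[3], x$rect[2], x$rect[4],
              if (is.null(x$mask)) "" else sprintf(", mask (%d px)", sum(x$mask))))
  invisible(x)
}

roi_in_frame <- function(r, frame_dim) {
  r$rect[1] >= 0 && r$rect[2] >= 0 &&
    r$rect[3] <= frame_dim[1] && r$rect[4] <= frame_dim[2]
}

# pixels of `frame` (matrix) selected by the roi, as a vector
roi_pixels <- function(frame, r) {
  if (!roi_in_frame(r, dim(frame)[1:2])) stop("roi outside frame bounds")
  sub <- frame[(r$rect[1] + 1):r$rect[3], (r$rect[2] + 1):r$rect[4], drop = FALSE]
  if (is.null(r$mask)) as.vector(sub) else sub[r$mask]
}

#' Intersection-over-union of two ROI rectangles
#'
#' @param a,b `roi` objects (masks ignored; rectangles only).
#' @return IoU in \[0, 1\].
#' @export
roi_iou <- function(a, b) {
  ra <- a$rect; rb <- b$rect
  ih <- max(0, min(ra[3], rb[3]) - max(ra[1], rb[1]))
  iw <- max(0, min(ra[4], rb[4]) - max(ra[2], rb[2]))
  inter <- ih * iw
  areas <- (ra[3] - ra[1]) * (ra[4] - ra[2]) + (rb[3] - rb[1]) * (rb[4] - rb[2])
  if (inter == 0) return(0)
  inter / (areas - inter)
}

#' Read an ROI specification file
#'
#' The spec is JSON: `{"frame_size": [H, W], "rois": {"eye_area":
#' {"rect": [r0, c0, r1, c1], "mask_rle": [...]}, ...}}`. `mask_rle` is an
#' optional run-length encoding (alternating FALSE/TRUE run lengths, column-
#' major over the rectangle) of the binary mask.
#'
#' @param path JSON file path.
#' @return Named list mapping label to [roi()].
#' @export
read_roi_spec <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(spec$frame_size) || length(spec$frame_size) != 2)
    stop("ROI spec must declare frame_size [H, W]")
  fd <- as.numeric(spec$frame_size)
  out <- list()
  for (lab in names(spec$rois)) {
    if (!lab %in% ROI_LABELS) stop("unknown label '", lab, "' in ROI spec")
    entry <- spec$rois[[lab]]
    rect <- as.numeric(entry$rect)
    mask <- NULL
    if (!is.null(entry$mask_rle)) {
      h <- rect[3] - rect[1]; w <- rect[4] - rect[2]
      runs <- as.integer(entry$mask_rle)
      vals <- rep(rep(c(FALSE, TRUE), length.out = length(runs)), runs)
      if (length(vals) != h * w) stop("mask run-length does not match rect shape")
      mask <- matrix(vals, nrow = h, ncol = w)
    }
    r <- roi(rect, mask, lab)
    if (!roi_in_frame(r, fd))
      stop("roi '", lab, "' exceeds declared frame size")
    out[[lab]] <- r
  }
  out
}

#' Write an ROI specification file
#'
#' Inverse of [read_roi_spec()].
#'
#' @param rois named list of [roi()] objects (names are the labels).
#' @param frame_size `(H, W)` the rectangles must fit in.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_roi_spec <- function(rois, frame_size, path) {
  enc <- lapply(rois, function(r) {
    e <- list(rect = r$rect)
    if (!is.null(r$mask)) {
      v <- as.vector(r$mask)
      rl <- rle(v)
      runs <- rl$lengths
      if (rl$values[1]) runs <- c(0L, runs)  # encoding starts with a FALSE run
      e$mask_rle <- as.integer(runs)
    }
    e
  })
  jsonlite::write_json(list(frame_size = as.integer(frame_size), rois = enc),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- MeasurementTable ------------------------------------------------------

MEASUREMENT_COLS <- c("animal_id", "handling_period", "minute_index", "method",
                      "quantity", "value", "camera_position",
                      "camera_distance_m", "analysed_area")
HANDLING_PERIODS <- c("crush1", "milking", "crush2")
QUANTITIES <- c("temperature_C", "hr_bpm", "rr_bpm")

#' Construct a measurement table
#'
#' Long-format table of invasive and remote readings keyed by animal,
#' handling period, minute, method, quantity and camera stratifiers.
#'
#' @param df data.frame with columns `animal_id`, `handling_period`
#'   (crush1/milking/crush2), `minute_index`, `method` (invasive/remote),
#'   `quantity` (temperature_C/hr_bpm/rr_bpm), `value`, `camera_position`,
#'   `camera_distance_m`, `analysed_area`.
#' @return The validated data.frame with class `measurement_table`.
#' @export
measurement_table <- function(df) {
  miss <- setdiff(MEASUREMENT_COLS, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[MEASUREMENT_COLS]
  if (nrow(df)) {
    if (!all(df$handling_period %in% HANDLING_PERIODS)) stop("bad handling_period")
    if (!all(df$method %in% c("invasive", "remote"))) stop("bad method")
    if (!all(df$quantity %in% QUANTITIES)) stop("bad quantity")
    if (!all(is.finite(df$value))) stop("non-finite values")
    key <- do.call(paste, c(df[setdiff(MEASUREMENT_COLS, "value")], sep = "\r"))
    if (anyDuplicated(key)) stop("duplicate measurement keys")
  }
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Write a measurement table to CSV
#'
#' Fixed column order (animal_id, handling_period, minute_index, method,
#' quantity, value, camera_position, camera_distance_m, analysed_area),
#' UTF-8, header row, "." decimal separator. Validates before writing.
#'
#' @param table a [measurement_table()] (or coercible data.frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(table, path) {
  table <- measurement_table(table)  # re-validate; errors before any write
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a measurement table from CSV
#'
#' @param path CSV written by [write_measurement_table()].
#' @return A [measurement_table()].
#' @export
read_measurement_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  measurement_table(df)
}
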
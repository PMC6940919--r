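#' Temperature statistics of an ROI in one radiometric frame
#'
#' Computes mean, maximum, minimum and sample standard deviation of the
#' temperatures over exactly the pixels the ROI selects (mask-respecting).
#'
#' @param frame a 2-D raster of temperatures in degrees Celsius.
#' @param roi a [roi()] within the frame, selecting at least one pixel.
#' @param frame_index frame index recorded in the summary.
#' @return A list of class `roi_temperature_summary` with fields
#'   `frame_index`, `label`, `mean_C`, `max_C`, `min_C`, `sd_C`, `n_pixels`.
#' @export
extract_roi_temperature <- function(frame, roi, frame_index = 0L) {
  px <- roi_pixels(frame, roi)
  if (length(px) < 1) stop("roi selects no pixels")
  if (!all(is.finite(px))) stop("non-finite temperatures inside the roi")
  structure(list(frame_index = as.integer(frame_index), label = roi$label,
                 mean_C = mean(px), max_C = max(px), min_C = min(px),
                 sd_C = if (length(px) > 1) stats::sd(px) else 0,
                 n_pixels = length(px)),
            class = "roi_temperature_summary")
}

#' @export
print.roi_temperature_summary <- function(x, ...) {
  cat(sprintf("<roi_temperature_summary> frame %d %s: mean %.2f, max %.2f, min %.2f, sd %.3f degC (%d px)\n",
              x$frame_index, x$label, x$mean_C, x$max_C, x$min_C, x$sd_C,
              x$n_pixels))
  invisible(x)
}

#' Build a temperature series from a radiometric sequence and an ROI
#'
#' One [extract_roi_temperature()] summary per frame. The statistic that
#' represents each frame downstream defaults to the maximum for the eye area
#' (the convention in ocular thermography) and the mean for other, more
#' diffuse regions.
#'
#' @param seq a [radiometric_sequence()].
#' @param roi a [roi()] (fixed across frames) or list of per-frame ROIs.
#' @param statistic `"mean"` or `"max"`; default depends on the ROI label as
#'   described above.
#' @return An object of class `temperature_series`: `entries` data.frame with
#'   the per-frame statistics, `statistic_used`, `sampling_rate`.
#' @export
temperature_series <- function(seq, roi, statistic = NULL) {
  rois <- if (inherits(roi, "roi")) rep(list(roi), length(seq$frames)) else roi
  if (is.null(statistic))
    statistic <- if (rois[[1]]$label == "eye_area") "max" else "mean"
  statistic <- match.arg(statistic, c("mean", "max"))
  rows <- lapply(seq_along(seq$frames), function(i) {
    s <- extract_roi_temperature(seq$frames[[i]], rois[[i]], i - 1L)
    data.frame(frame_index = s$frame_index, label = s$label, mean_C = s$mean_C,
               max_C = s$max_C, min_C = s$min_C, sd_C = s$sd_C,
               n_pixels = s$n_pixels)
  })
  structure(list(entries = do.call(rbind, rows), statistic_used = statistic,
                 sampling_rate = seq$frame_rate),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("<temperature_series> %d entries at %g fps, statistic %s\n",
              nrow(x$entries), x$sampling_rate, x$statistic_used))
  invisible(x)
}

#' Aggregate a temperature series per minute or per handling period
#'
#' The per-frame statistic (`statistic_used` of the series) is averaged
#' within each group. Minute boundaries are `[60k, 60(k+1))` seconds from
#' series start; handling periods are given as explicit time bounds.
#'
#' @param series a [temperature_series()].
#' @param by `"minute"` or `"period"`.
#' @param period_bounds for `by = "period"`: data.frame or list of
#'   `(start_s, end_s, period)` rows, half-open `[start_s, end_s)`, that
#'   together cover every entry.
#' @return data.frame with columns `group` and `value_C` (groups with no
#'   entries are omitted).
#' @export
summarize_temperature_series <- function(series, by = c("minute", "period"),
                                         period_bounds = NULL) {
  by <- match.arg(by)
  ent <- series$entries
  if (nrow(ent) == 0) stop("empty series")
  val <- if (series$statistic_used == "max") ent$max_C else ent$mean_C
  t_s <- ent$frame_index / series$sampling_rate
  if (by == "minute") {
    grp <- floor(t_s / 60)
    agg <- tapply(val, grp, mean)
    return(data.frame(group = as.numeric(names(agg)), value_C = as.numeric(agg)))
  }
  if (is.null(period_bounds)) stop("period_bounds required for by = 'period'")
  pb <- as.data.frame(do.call(rbind, lapply(seq_len(NROW(period_bounds)), function(i) {
    row <- if (is.data.frame(period_bounds)) period_bounds[i, ] else period_bounds[[i]]
    data.frame(start_s = as.numeric(row[[1]]), end_s = as.numeric(row[[2]]),
               period = as.character(row[[3]]))
  })))
  grp <- rep(NA_character_, length(t_s))
  for (i in seq_len(nrow(pb)))
    grp[t_s >= pb$start_s[i] & t_s < pb$end_s[i]] <- pb$period[i]
  if (anyNA(grp)) stop("entry outside all period bounds")
  agg <- tapply(val, grp, mean)
  out <- data.frame(group = names(agg), value_C = as.numeric(agg))
  out[order(match(out$group, pb$period)), , drop = FALSE]
}
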
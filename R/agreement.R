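#' Construct paired invasive/remote measurements
#'
#' @param df data.frame with columns `animal_id`, `period`, `minute_index`,
#'   `invasive`, `remote`.
#' @param quantity one of `"temperature_C"`, `"hr_bpm"`, `"rr_bpm"`.
#' @param stratifiers optional named list recording camera, position,
#'   distance and analysed area.
#' @return The data.frame with class `paired_measurements` and attributes
#'   `quantity`, `stratifiers`.
#' @export
paired_measurements <- function(df, quantity = "temperature_C",
                                stratifiers = list()) {
  need <- c("animal_id", "period", "minute_index", "invasive", "remote")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (!all(is.finite(df$invasive)) || !all(is.finite(df$remote)))
    stop("non-finite paired values")
  structure(df, class = c("paired_measurements", "data.frame"),
            quantity = quantity, stratifiers = stratifiers)
}

#' Anderson-Darling normality check
#'
#' @param values numeric vector, n >= 8, non-constant.
#' @param alpha significance level for the normality verdict (default 0.05).
#' @return List with `statistic`, `p_value` and `normal`
#'   (`p_value > alpha`).
#' @export
check_normality <- function(values, alpha = 0.05) {
  if (length(values) < 8) stop("normality check needs n >= 8")
  if (stats::sd(values) == 0) stop("zero variance")
  t <- nortest::ad.test(values)
  list(statistic = unname(t$statistic), p_value = t$p.value,
       normal = t$p.value > alpha)
}

#' Pearson product-moment correlation with two-sided p-value
#'
#' @param x,y equal-length numeric vectors (n >= 3) with positive variance.
#' @return List with `r` and `p_value` (t-transform, n - 2 df).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Ordinary least-squares fit of y on x
#'
#' Used with `y` = invasive (reference) and `x` = remote, asking whether the
#' remote measurement predicts the invasive one.
#'
#' @param x predictor (remote); `y` response (invasive).
#' @param y response values.
#' @return List with `slope`, `intercept`, `r`, `p_value` (the correlation's
#'   two-sided p).
#' @export
linear_fit <- function(x, y) {
  pr <- pearson_r(x, y)  # shares the preconditions
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]), r = pr$r,
       p_value = pr$p_value)
}

#' Bias between methods: mean and SD of invasive - remote
#'
#' @param pairs a [paired_measurements()] (n >= 2).
#' @return List with `mean_diff` and `sd_diff` (sample SD, n - 1).
#' @export
mean_difference <- function(pairs) {
  d <- pairs$invasive - pairs$remote
  if (length(d) < 2) stop("need at least 2 pairs")
  list(mean_diff = mean(d), sd_diff = stats::sd(d))
}

#' Exclude animals whose reference series is too variable
#'
#' An animal is excluded when the sample SD of its reference heart-rate
#' series is strictly greater than the threshold (default 20 bpm).
#'
#' @param reference_series named list of per-animal numeric vectors (each
#'   n >= 2).
#' @param threshold SD cut-off in bpm.
#' @return List with `retained` and `excluded` id vectors (a partition of
#'   the input names).
#' @export
exclude_by_sd <- function(reference_series, threshold = 20) {
  if (is.null(names(reference_series)) || any(!nzchar(names(reference_series))))
    stop("series must be named by animal id")
  sds <- vapply(reference_series, function(s) {
    if (length(s) < 2) stop("each series needs n >= 2")
    stats::sd(s)
  }, numeric(1))
  list(retained = names(sds)[sds <= threshold],
       excluded = names(sds)[sds > threshold])
}

#' Aggregate paired measurements into analysis cells
#'
#' Invasive and remote values are first averaged independently within
#' `(animal, period)` cells (`by = "period"`) or `(animal, period, minute)`
#' cells (`by = "minute"`), then returned pooled across animals
#' (`level = "group"`, one `paired_measurements`) or split per animal
#' (`level = "per_animal"`, a list partitioning the input's animals).
#'
#' @param pairs a [paired_measurements()].
#' @param level `"group"` or `"per_animal"`.
#' @param by `"minute"` or `"period"`.
#' @return A list of [paired_measurements()] (length 1 for `level =
#'   "group"`).
#' @export
aggregate_pairs <- function(pairs, level = c("group", "per_animal"),
                            by = c("minute", "period")) {
  level <- match.arg(level)
  by <- match.arg(by)
  if (nrow(pairs) == 0) stop("empty pairs")
  keys <- if (by == "period") list(animal_id = pairs$animal_id,
                                   period = pairs$period)
          else list(animal_id = pairs$animal_id, period = pairs$period,
                    minute_index = pairs$minute_index)
  agg <- stats::aggregate(cbind(invasive, remote) ~ ., cbind(as.data.frame(keys),
                          invasive = pairs$invasive, remote = pairs$remote),
                          FUN = mean)
  if (!"minute_index" %in% names(agg)) agg$minute_index <- 0L
  mk <- function(d) paired_measurements(d, attr(pairs, "quantity"),
                                        attr(pairs, "stratifiers"))
  if (level == "group") return(list(mk(agg)))
  lapply(split(agg, agg$animal_id), mk)
}

#' Agreement report for one set of pairs
#'
#' Pearson correlation, linear regression of invasive on remote, and bias
#' (mean difference +/- SD), the per-stratum summary of a method-agreement
#' analysis.
#'
#' @param pairs a [paired_measurements()] with n >= 2 (n >= 3 for r).
#' @return An object of class `agreement_report`: `r`, `p_value`, `slope`,
#'   `intercept`, `mean_diff`, `sd_diff`, `n`.
#' @export
agreement_report <- function(pairs) {
  fit <- linear_fit(pairs$remote, pairs$invasive)
  md <- mean_difference(pairs)
  structure(list(r = fit$r, p_value = fit$p_value, slope = fit$slope,
                 intercept = fit$intercept, mean_diff = md$mean_diff,
                 sd_diff = md$sd_diff, n = nrow(pairs)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n=%d r=%.3f (p=%.3g) fit: invasive = %.3f*remote + %.3f, bias %.2f +/- %.2f\n",
              x$n, x$r, x$p_value, x$slope, x$intercept, x$mean_diff, x$sd_diff))
  invisible(x)
}

#' Summarize per-animal correlation coefficients as mean +/- SD
#'
#' Mirrors the per-setting presentation of per-animal agreement results:
#' mean and sample SD of the coefficients, their range, and the largest
#' per-animal p-value observed.
#'
#' @param per_animal_reports list of at least two [agreement_report()]s.
#' @param stratifiers optional named list (camera, position, distance, area).
#' @return An object of class `correlation_summary`: `mean_r`, `sd_r`,
#'   `range_r`, `max_p`, `n_animals`, `stratifiers`.
#' @export
summarize_correlations <- function(per_animal_reports, stratifiers = list()) {
  if (length(per_animal_reports) < 2) stop("need at least 2 reports")
  r <- vapply(per_animal_reports, function(a) a$r, numeric(1))
  p <- vapply(per_animal_reports, function(a) a$p_value, numeric(1))
  structure(list(mean_r = mean(r), sd_r = stats::sd(r), range_r = range(r),
                 max_p = max(p), n_animals = length(r),
                 stratifiers = stratifiers),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("<correlation_summary> %d animals: r = %.2f +/- %.2f, range %.2f-%.2f, max p %.3g\n",
              x$n_animals, x$mean_r, x$sd_r, x$range_r[1], x$range_r[2], x$max_p))
  invisible(x)
}
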
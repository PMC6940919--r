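test_that("a uniform frame yields identical mean, max and min and zero sd", {
  fr <- matrix(38.5, 16, 16)
  s <- extract_roi_temperature(fr, roi(c(2, 2, 12, 12), label = "ear_base"))
  expect_identical(s$mean_C, 38.5)
  expect_identical(s$max_C, 38.5)
  expect_identical(s$min_C, 38.5)
  expect_identical(s$sd_C, 0)
  expect_identical(s$n_pixels, 100L)
})

test_that("a single hot pixel drives the maximum but barely the mean", {
  fr <- matrix(38.0, 16, 16)
  fr[7, 9] <- 39.7
  r <- roi(c(2, 2, 12, 12), label = "eye_area")
  s <- extract_roi_temperature(fr, r)
  expect_identical(s$max_C, 39.7)
  expect_identical(s$min_C, 38.0)
  expect_equal(s$mean_C, (99 * 38.0 + 39.7) / 100)
  # the hot pixel can be excluded through the mask
  m <- matrix(TRUE, 10, 10)
  m[5, 7] <- FALSE  # frame (7,9) 1-based -> 0-based (6,8) -> mask index (5,7)
  s2 <- extract_roi_temperature(fr, roi(c(2, 2, 12, 12), m, "eye_area"))
  expect_identical(s2$max_C, 38.0)
  fr[7, 9] <- NaN
  expect_error(extract_roi_temperature(fr, r), "non-finite")
})

test_that("ROI statistics agree with an explicit double-loop oracle", {
  set.seed(42)
  for (k in 1:20) {
    fr <- matrix(runif(24 * 24, 30, 42), 24, 24)
    r0 <- sample(0:14, 1); c0 <- sample(0:14, 1)
    h <- sample(2:8, 1); w <- sample(2:8, 1)
    rect <- c(r0, c0, r0 + h, c0 + w)
    mask <- if (k %% 2 == 0) {
      m <- matrix(runif(h * w) > 0.4, h, w)
      if (!any(m)) m[1, 1] <- TRUE
      m
    } else NULL
    r <- roi(rect, mask, "eye_area")
    s <- extract_roi_temperature(fr, r)
    o <- oracle_roi_stats(fr, rect, mask)
    expect_equal(s$mean_C, o$mean, tolerance = 1e-9)
    expect_equal(s$max_C, o$max, tolerance = 1e-9)
    expect_equal(s$min_C, o$min, tolerance = 1e-9)
    expect_equal(s$sd_C, o$sd, tolerance = 1e-9)
    expect_identical(s$n_pixels, as.integer(o$n))
  }
})

test_that("statistic defaults to max for the eye area and mean elsewhere", {
  fr <- matrix(38, 16, 16); fr[5, 5] <- 40
  rs <- radiometric_sequence(list(fr))
  eye <- temperature_series(rs, roi(c(2, 2, 12, 12), label = "eye_area"))
  ear <- temperature_series(rs, roi(c(2, 2, 12, 12), label = "ear_base"))
  expect_identical(eye$statistic_used, "max")
  expect_identical(ear$statistic_used, "mean")
  expect_identical(summarize_temperature_series(eye)$value_C, 40)
  expect_equal(summarize_temperature_series(ear)$value_C, (99 * 38 + 40) / 100)
})

test_that("minute aggregation over constant frames returns the constant per bin", {
  rs <- radiometric_sequence(lapply(1:150, function(i) matrix(38.0, 8, 8)))
  ts <- temperature_series(rs, roi(c(1, 1, 7, 7), label = "ear_base"))
  agg <- summarize_temperature_series(ts, by = "minute")
  expect_identical(agg$group, c(0, 1, 2))  # 150 frames at 1 fps spans 3 bins
  expect_true(all(agg$value_C == 38.0))
  # frame 60 (t = 60 s) belongs to minute 1, not minute 0 (half-open bins)
  rs2 <- radiometric_sequence(c(lapply(1:60, function(i) matrix(30, 4, 4)),
                                list(matrix(42, 4, 4))))
  ts2 <- temperature_series(rs2, roi(c(0, 0, 4, 4), label = "ear_base"))
  agg2 <- summarize_temperature_series(ts2, by = "minute")
  expect_identical(agg2$value_C, c(30, 42))
})

test_that("period aggregation matches a brute-force group mean and flags gaps", {
  set.seed(7)
  temps <- runif(180, 36, 40)
  rs <- radiometric_sequence(lapply(temps, function(v) matrix(v, 4, 4)))
  ts <- temperature_series(rs, roi(c(0, 0, 4, 4), label = "ear_base"))
  pb <- data.frame(start_s = c(0, 60, 120), end_s = c(60, 120, 180),
                   period = c("crush1", "milking", "crush2"))
  agg <- summarize_temperature_series(ts, by = "period", period_bounds = pb)
  expect_identical(agg$group, c("crush1", "milking", "crush2"))
  expect_equal(agg$value_C,
               c(mean(temps[1:60]), mean(temps[61:120]), mean(temps[121:180])),
               tolerance = 1e-12)
  short <- pb; short$end_s[3] <- 170
  expect_error(summarize_temperature_series(ts, by = "period",
                                            period_bounds = short),
               "outside all period bounds")
  expect_error(summarize_temperature_series(ts, by = "period"),
               "period_bounds required")
})

test_that("period means are weighted means of the minute means (nesting)", {
  set.seed(21)
  temps <- runif(240, 36, 40)
  rs <- radiometric_sequence(lapply(temps, function(v) matrix(v, 4, 4)))
  ts <- temperature_series(rs, roi(c(0, 0, 4, 4), label = "ear_base"))
  per_min <- summarize_temperature_series(ts, by = "minute")
  pb <- data.frame(start_s = c(0, 120), end_s = c(120, 240),
                   period = c("crush1", "milking"))
  per_per <- summarize_temperature_series(ts, by = "period", period_bounds = pb)
  # each minute has the same frame count, so the period mean is the plain
  # mean of its minute means
  expect_equal(per_per$value_C[per_per$group == "crush1"],
               mean(per_min$value_C[per_min$group %in% 0:1]), tolerance = 1e-12)
  expect_equal(per_per$value_C[per_per$group == "milking"],
               mean(per_min$value_C[per_min$group %in% 2:3]), tolerance = 1e-12)
})

test_that("core-temperature structure survives the full thermal pipeline", {
  # six one-minute periods with distinct core temperatures; the eye reads
  # core minus a fixed physiological offset
  core <- rep(c(38.2, 38.5, 38.9, 38.4, 38.7, 39.1), each = 60)
  traj <- data.frame(time_s = 0:360, temp_C = c(core, core[360]))
  fx <- make_thermal_sequence(traj, offset_C = 1.1, noise_sd_C = 0.1,
                              duration_s = 360, seed = 31)
  ts <- temperature_series(fx$thermal, fx$rois$eye_area, statistic = "mean")
  pb <- data.frame(start_s = 60 * (0:5), end_s = c(60 * (1:5), 361),
                   period = paste0("p", 1:6))
  remote <- summarize_temperature_series(ts, by = "period", period_bounds = pb)
  invasive <- tapply(core, rep(1:6, each = 60), mean)
  expect_lt(max(abs((remote$value_C + 1.1) - invasive)), 0.1)
  r <- oracle_pearson(remote$value_C, as.numeric(invasive))
  expect_gt(r, 0.9)
})
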
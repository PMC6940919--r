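mkpairs <- function(inv, rem, animal = "A1", period = "crush1",
                    minute = seq_along(inv) - 1L) {
  paired_measurements(data.frame(animal_id = animal, period = period,
                                 minute_index = minute, invasive = inv,
                                 remote = rem))
}

test_that("the normality check accepts Gaussian and rejects exponential samples", {
  verdicts_norm <- verdicts_exp <- logical(3)
  for (s in 1:3) {
    set.seed(100 + s)
    verdicts_norm[s] <- check_normality(rnorm(200, 38.5, 0.4))$normal
    verdicts_exp[s] <- check_normality(rexp(200))$normal
  }
  expect_true(all(verdicts_norm))
  expect_true(all(!verdicts_exp))
  expect_error(check_normality(rnorm(5)), "n >= 8")
  expect_error(check_normality(rep(38.5, 20)), "zero variance")
})

test_that("Pearson correlation matches the product-moment formula and its trivials", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  y <- c(2, 1, 4, 3, 6)
  expect_equal(pearson_r(x, y)$r, oracle_pearson(x, y), tolerance = 1e-12)
  # two-sided p via the t transform with n - 2 degrees of freedom
  r <- pearson_r(x, y)
  tt <- r$r * sqrt(3 / (1 - r$r^2))
  expect_equal(r$p_value, 2 * stats::pt(-abs(tt), 3), tolerance = 1e-12)
  expect_error(pearson_r(x, y[1:4]), "length mismatch")
  expect_error(pearson_r(x[1:2], y[1:2]), "n >= 3")
  expect_error(pearson_r(rep(1, 5), y), "zero variance")
})

test_that("Pearson correlation is invariant under positive affine maps", {
  set.seed(12)
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.5)
  base <- pearson_r(x, y)$r
  expect_equal(pearson_r(3 * x + 7, y)$r, base, tolerance = 1e-12)
  expect_equal(pearson_r(x, 0.1 * y - 40)$r, base, tolerance = 1e-12)
  expect_equal(pearson_r(-x, y)$r, -base, tolerance = 1e-12)
})

test_that("the linear fit recovers exact and random-data coefficients", {
  x <- c(0, 1, 2, 3, 4)
  f <- linear_fit(x, 3 * x - 2)
  expect_equal(f$slope, 3, tolerance = 1e-12)
  expect_equal(f$intercept, -2, tolerance = 1e-12)
  expect_equal(f$r, 1, tolerance = 1e-12)
  set.seed(9)
  xr <- rnorm(20, 38, 0.5); yr <- 0.8 * xr + rnorm(20, 0, 0.2)
  fr <- linear_fit(xr, yr)
  o <- oracle_ols(xr, yr)
  expect_equal(fr$slope, unname(o["slope"]), tolerance = 1e-12)
  expect_equal(fr$intercept, unname(o["intercept"]), tolerance = 1e-12)
  expect_error(linear_fit(rep(2, 5), x), "zero variance")
})

test_that("bias is the mean and sample SD of invasive minus remote", {
  p <- mkpairs(c(38.6, 38.8, 39.0), c(37.5, 37.7, 37.9))
  md <- mean_difference(p)
  expect_equal(md$mean_diff, 1.1, tolerance = 1e-12)
  expect_equal(md$sd_diff, 0, tolerance = 1e-12)
  set.seed(4)
  inv <- rnorm(25, 38.6, 0.4); rem <- rnorm(25, 37.5, 0.4)
  md2 <- mean_difference(mkpairs(inv, rem))
  d <- inv - rem
  expect_equal(md2$mean_diff, sum(d) / 25, tolerance = 1e-12)
  expect_equal(md2$sd_diff, sqrt(sum((d - mean(d))^2) / 24), tolerance = 1e-12)
  expect_error(mean_difference(mkpairs(38.6, 37.5)), "at least 2")
})

test_that("animals are excluded only when the reference SD strictly exceeds 20", {
  series <- list(A = c(80, 85, 82, 81),          # sd ~ 2
                 B = c(60, 120, 70, 130),        # sd ~ 35
                 C = 80 + c(-20, 20, -20, 20))   # sd = 23.1
  out <- exclude_by_sd(series)
  expect_identical(out$retained, "A")
  expect_setequal(out$excluded, c("B", "C"))
  # partition property
  expect_setequal(c(out$retained, out$excluded), names(series))
  expect_length(intersect(out$retained, out$excluded), 0)
  # exactly at the threshold is retained
  exact <- list(D = c(80 - 20, 80 + 20))  # sd = sqrt(2)*20 > 20 -> excluded
  expect_identical(exclude_by_sd(exact)$excluded, "D")
  at <- list(E = c(80, 80 + 20 * sqrt(2)))  # sample sd exactly 20
  expect_identical(exclude_by_sd(at)$retained, "E")
  expect_error(exclude_by_sd(list(c(80, 81))), "named")
})

test_that("aggregation averages within cells and matches a brute-force check", {
  df <- data.frame(
    animal_id = rep(c("A1", "A2"), each = 6),
    period = rep(rep(c("crush1", "milking"), each = 3), 2),
    minute_index = rep(c(0L, 0L, 1L), 4),
    invasive = as.numeric(1:12), remote = as.numeric(12:1))
  p <- paired_measurements(df, quantity = "hr_bpm")
  g <- aggregate_pairs(p, level = "group", by = "minute")[[1]]
  # brute force over (animal, period, minute) cells
  key <- interaction(df$animal_id, df$period, df$minute_index, drop = TRUE)
  binv <- tapply(df$invasive, key, mean)
  for (i in seq_len(nrow(g))) {
    k <- paste(g$animal_id[i], g$period[i], g$minute_index[i], sep = ".")
    expect_equal(g$invasive[i], unname(binv[k]), tolerance = 1e-12)
  }
  expect_identical(nrow(g), length(unique(key)))
  # per-animal splitting partitions the group result
  pa <- aggregate_pairs(p, level = "per_animal", by = "minute")
  expect_setequal(names(pa), c("A1", "A2"))
  expect_identical(sum(vapply(pa, nrow, integer(1))), nrow(g))
  # period-level cells pool the minutes
  gp <- aggregate_pairs(p, level = "group", by = "period")[[1]]
  expect_identical(nrow(gp), 4L)
  expect_equal(sort(gp$invasive), c(2, 5, 8, 11), tolerance = 1e-12)
  expect_identical(attr(gp, "quantity"), "hr_bpm")
})

test_that("period cells equal minute cells re-averaged with minute weights", {
  set.seed(17)
  df <- data.frame(
    animal_id = rep("A1", 8), period = rep(c("crush1", "crush2"), each = 4),
    minute_index = rep(c(0L, 0L, 1L, 1L), 2),
    invasive = rnorm(8, 80, 5), remote = rnorm(8, 78, 5))
  p <- paired_measurements(df, quantity = "hr_bpm")
  per_min <- aggregate_pairs(p, "group", "minute")[[1]]
  per_per <- aggregate_pairs(p, "group", "period")[[1]]
  # every minute cell holds 2 raw rows here, so the period mean is the plain
  # mean of its minute-cell means
  for (pd in c("crush1", "crush2")) {
    expect_equal(per_per$invasive[per_per$period == pd],
                 mean(per_min$invasive[per_min$period == pd]),
                 tolerance = 1e-12)
  }
})

test_that("the agreement report ties correlation, regression and bias together", {
  set.seed(23)
  inv <- rnorm(30, 38.6, 0.4)
  rem <- inv - 1.1 + rnorm(30, 0, 0.15)
  rep_ <- agreement_report(mkpairs(inv, rem))
  expect_equal(rep_$r, oracle_pearson(rem, inv), tolerance = 1e-12)
  o <- oracle_ols(rem, inv)
  expect_equal(rep_$slope, unname(o["slope"]), tolerance = 1e-12)
  expect_equal(rep_$mean_diff, mean(inv - rem), tolerance = 1e-12)
  expect_identical(rep_$n, 30L)
  expect_lt(abs(rep_$mean_diff - 1.1), 0.1)
  expect_gt(rep_$r, 0.9)
})

test_that("correlation summaries report mean, SD, range and worst p", {
  mk <- function(seed) {
    set.seed(seed)
    inv <- rnorm(12, 80, 6); rem <- inv + rnorm(12, 0, 3)
    agreement_report(mkpairs(inv, rem))
  }
  reps <- lapply(31:38, mk)
  s <- summarize_correlations(reps)
  rs <- vapply(reps, function(a) a$r, numeric(1))
  ps <- vapply(reps, function(a) a$p_value, numeric(1))
  expect_equal(s$mean_r, mean(rs), tolerance = 1e-12)
  expect_equal(s$sd_r, stats::sd(rs), tolerance = 1e-12)
  expect_equal(s$range_r, range(rs), tolerance = 1e-12)
  expect_equal(s$max_p, max(ps), tolerance = 1e-12)
  expect_identical(s$n_animals, 8L)
  expect_error(summarize_correlations(reps[1]), "at least 2")
})

test_that("the generated paired series carries its target correlation", {
  for (rho in c(0.3, 0.9)) {
    p <- make_paired_series(rho, 10000, seed = 41)
    expect_lt(abs(pearson_r(p$invasive, p$remote)$r - rho), 0.03)
  }
  md <- mean_difference(make_paired_series(0.74, 5000, seed = 42))
  expect_lt(abs(md$mean_diff - 1.1), 0.05)
})
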
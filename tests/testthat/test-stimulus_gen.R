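test_that("delta pools are the scaled successive differences of the power series", {
  pool <- build_delta_pool(c(10, 12, 11), scale = 5)
  expect_equal(pool$values, c(10, -5))
  expect_warning(build_delta_pool(c(3, 3, 3)), "only zeros")
  expect_error(build_delta_pool(7))
  # standardized moments are invariant to the pixel scaling
  set.seed(1)
  series <- cumsum(rnorm(500))
  s1 <- trajectory_stats(build_delta_pool(series, scale = 1)$values)
  s2 <- trajectory_stats(build_delta_pool(series, scale = 12.3)$values)
  expect_equal(s1$skewness, s2$skewness, tolerance = 1e-12)
  expect_equal(s1$kurtosis, s2$kurtosis, tolerance = 1e-12)
})

test_that("trajectories follow the update-rate timing exactly", {
  pool <- build_delta_pool(c(0, 1, -1, 2, 0.5))
  for (rate in c(1, 5, 10)) {
    traj <- generate_trajectory(pool, rate, duration = 60, seed = 1)
    expect_equal(length(traj$radii), floor(60 * rate) + 1)
    expect_equal(unique(round(diff(traj$times), 12)), 1 / rate)
  }
  expect_equal(diff(generate_trajectory(pool, 5, seed = 1)$times)[1], 0.2)
  expect_equal(diff(generate_trajectory(pool, 1, seed = 1)$times)[1], 1.0)
  expect_equal(diff(generate_trajectory(pool, 10, seed = 1)$times)[1], 0.1)
})

test_that("trajectories start at baseline, respect bounds, and degenerate cleanly", {
  zero_pool <- suppressWarnings(build_delta_pool(c(1, 1, 1)))
  traj <- generate_trajectory(zero_pool, 5, duration = 10, baseline = 100)
  expect_true(all(traj$radii == 100))
  wide <- build_delta_pool(cumsum(rnorm(50, sd = 30)))
  for (seed in 1:25) {
    t2 <- generate_trajectory(wide, 10, duration = 60, baseline = 100,
                              bounds = c(50, 150), seed = seed)
    expect_true(all(t2$radii >= 50 & t2$radii <= 150))
    expect_equal(t2$radii[1], 100)
  }
  empty <- structure(list(values = numeric(0), provenance = list()),
                     class = "delta_pool")
  expect_error(generate_trajectory(empty, 5), "empty")
  expect_identical(generate_trajectory(wide, 5, seed = 3)$radii,
                   generate_trajectory(wide, 5, seed = 3)$radii)
})

test_that("trajectory statistics match known processes", {
  set.seed(11)
  # AR(1) with coefficient 0.6: lag-1 autocorrelation estimate near 0.6
  ar <- as.numeric(arima.sim(list(ar = 0.6), n = 10000))
  st <- trajectory_stats(ar)
  expect_lt(abs(st$lag1_autocorr - 0.6), 0.05)
  # i.i.d. sampling: lag1 within the 2/sqrt(n) null band
  iid <- rnorm(10000)
  expect_lt(abs(trajectory_stats(iid)$lag1_autocorr), 2 / sqrt(10000))
  # degenerate constant series
  cst <- trajectory_stats(rep(2, 10))
  expect_equal(cst$variance, 0)
  expect_true(is.na(cst$lag1_autocorr))
  expect_error(trajectory_stats(c(1, 2)), "at least 3")
})

test_that("resampling preserves distribution shape but destroys autocorrelation", {
  set.seed(12)
  # an autocorrelated, skewed source series of band-power variations
  src <- as.numeric(arima.sim(list(ar = 0.7), n = 2000))
  src <- exp(src / 2) - 1                      # skewed
  pool <- build_delta_pool(cumsum(src), id = "pilot-alpha")
  src_stats <- trajectory_stats(pool$values)
  expect_gt(abs(src_stats$lag1_autocorr), 0.2)
  traj <- generate_trajectory(pool, 10, duration = 60,
                              bounds = c(-1e9, 1e9), seed = 4)
  gen_stats <- trajectory_stats(traj)
  cmp <- compare_stats(src_stats, gen_stats)
  expect_equal(cmp$statistic,
               c("variance", "skewness", "kurtosis", "lag1_autocorr"))
  expect_true(cmp$matched[cmp$statistic == "skewness"])
  expect_false(cmp$matched[cmp$statistic == "lag1_autocorr"])
  expect_lt(abs(gen_stats$lag1_autocorr), 0.1)
})

test_that("stat comparison flags differences against tolerances", {
  s <- trajectory_stats(rnorm(100))
  same <- compare_stats(s, s)
  expect_true(all(same$abs_diff == 0))
  expect_true(all(same$matched))
  strict <- compare_stats(s, trajectory_stats(rnorm(100)),
                          tolerances = c(variance = 0, skewness = 0,
                                         kurtosis = 0, lag1_autocorr = 0))
  expect_false(any(strict$matched))
})

test_that("trajectories round-trip through the CSV writer", {
  pool <- build_delta_pool(c(10, 11, 9, 12))
  traj <- generate_trajectory(pool, 5, duration = 4, seed = 2)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "traj.csv")
  write_trajectory(traj, path)
  back <- utils::read.csv(path)
  expect_equal(back$radius_px, traj$radii)
  expect_true(file.exists(file.path(dir, "traj.json")))
})
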
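#' Delta pool for sham feedback generation
#'
#' Candidate stimulus size changes, built as the successive differences of
#' a band-power series (typically alpha power over time from a pilot
#' recording) mapped linearly to pixels. During sham feedback each update
#' draws one delta uniformly with replacement from this pool.
#'
#' @param power_series numeric band-power series (dB), length >= 2.
#' @param scale pixels per dB of power change.
#' @param id provenance label for the source series.
#' @return Object of class `delta_pool`.
#' @export
build_delta_pool <- function(power_series, scale = 1, id = "series") {
  stopifnot(is.numeric(power_series), length(power_series) >= 2,
            all(is.finite(power_series)))
  values <- diff(power_series) * scale
  if (all(values == 0))
    warning("constant power series: the delta pool contains only zeros",
            call. = FALSE)
  structure(list(values = values,
                 provenance = list(source = id, scale = scale,
                                   n_source = length(power_series))),
            class = "delta_pool")
}

#' Generate a sham feedback stimulus trajectory
#'
#' Circle-radius trajectory mimicking continuously modified visual
#' feedback: starting from `baseline`, at each update instant (every
#' `1/update_freq` seconds: 1000/200/100 ms at the task's 1/5/10 Hz rates)
#' one delta is drawn uniformly with replacement from the pool and added to
#' the current radius, clipping to `bounds`.
#'
#' @param pool a [build_delta_pool()] result.
#' @param update_freq update rate in Hz (the task uses 1, 5 or 10).
#' @param duration trajectory length in seconds.
#' @param baseline starting radius, pixels.
#' @param bounds `c(min, max)` radius clip limits, pixels.
#' @param seed optional seed for reproducibility.
#' @return Object of class `stimulus_trajectory` with `times` (the uniform
#'   update grid, starting at 0) and `radii` (`floor(duration *
#'   update_freq)` updates after the initial value).
#' @export
generate_trajectory <- function(pool, update_freq, duration = 60,
                                baseline = 100, bounds = c(10, 500),
                                seed = NULL) {
  if (!inherits(pool, "delta_pool") || length(pool$values) == 0)
    stop("generation error: empty or invalid delta pool", call. = FALSE)
  stopifnot(update_freq > 0, duration > 0,
            bounds[1] <= baseline, baseline <= bounds[2])
  if (!is.null(seed)) set.seed(seed)
  n_up <- floor(duration * update_freq)
  deltas <- pool$values[sample.int(length(pool$values), n_up,
                                   replace = TRUE)]
  radii <- numeric(n_up + 1L)
  radii[1] <- baseline
  for (i in seq_len(n_up))
    radii[i + 1L] <- min(max(radii[i] + deltas[i], bounds[1]), bounds[2])
  structure(list(update_freq = update_freq,
                 times = (0:n_up) / update_freq,
                 radii = radii,
                 baseline_radius = baseline,
                 bounds = bounds,
                 provenance = c(pool$provenance,
                                list(clipping = "hard clip at bounds"))),
            class = "stimulus_trajectory")
}

#' Temporal statistics of a stimulus trajectory
#'
#' Sample variance, standardized skewness, excess kurtosis and lag-1
#' autocorrelation of the *variation* (delta) series, i.e. the successive
#' radius differences, since the temporal dynamics of interest live in the
#' size variations rather than the size level. A zero-variance series
#' reports its lag-1 autocorrelation (and standardized moments) as `NA`,
#' never a fabricated value.
#'
#' @param x a `stimulus_trajectory`, or a numeric vector already holding a
#'   delta series.
#' @return Object of class `trajectory_stats`: variance (px^2), skewness,
#'   kurtosis (excess), lag1_autocorr, n.
#' @export
trajectory_stats <- function(x) {
  d <- if (inherits(x, "stimulus_trajectory")) diff(x$radii) else
    as.numeric(x)
  if (length(d) < 3)
    stop("at least 3 variation values are required", call. = FALSE)
  v <- var(d)
  if (v == 0) {
    sk <- ku <- l1 <- NA_real_
  } else {
    sk <- e1071::skewness(d, type = 2)
    ku <- e1071::kurtosis(d, type = 2)
    m <- mean(d)
    l1 <- sum((d[-1] - m) * (d[-length(d)] - m)) / sum((d - m)^2)
  }
  structure(list(variance = v, skewness = sk, kurtosis = ku,
                 lag1_autocorr = l1, n = length(d)),
            class = "trajectory_stats")
}

#' @export
print.trajectory_stats <- function(x, ...) {
  cat(sprintf("<trajectory_stats> n = %d: var %.3g, skew %.3g, kurt %.3g, lag1 %.3g\n",
              x$n, x$variance, x$skewness, x$kurtosis, x$lag1_autocorr))
  invisible(x)
}

#' Compare temporal statistics of source and generated variations
#'
#' Side-by-side comparison of the delta-series statistics of a source
#' (e.g. pilot band-power variations) and a generated trajectory, with
#' absolute differences flagged against per-statistic tolerances. Note that
#' i.i.d. resampling from a delta pool preserves the pool's distribution
#' shape (skewness, kurtosis) but destroys its serial structure, so the
#' lag-1 autocorrelation of generated trajectories tends to zero regardless
#' of the source dynamics.
#'
#' @param source,generated `trajectory_stats` objects (both computed on
#'   delta series).
#' @param tolerances named numeric tolerances per statistic.
#' @return Data frame: statistic, source, generated, abs_diff, tolerance,
#'   matched.
#' @export
compare_stats <- function(source, generated,
                          tolerances = c(variance = Inf, skewness = 0.2,
                                         kurtosis = 0.2,
                                         lag1_autocorr = 0.1)) {
  stopifnot(inherits(source, "trajectory_stats"),
            inherits(generated, "trajectory_stats"))
  stats <- c("variance", "skewness", "kurtosis", "lag1_autocorr")
  s <- unlist(source[stats])
  g <- unlist(generated[stats])
  diff <- abs(s - g)
  tol <- tolerances[stats]
  data.frame(statistic = stats, source = unname(s), generated = unname(g),
             abs_diff = unname(diff), tolerance = unname(tol),
             matched = unname(!is.na(diff) & diff <= tol),
             stringsAsFactors = FALSE)
}

#' Write a trajectory and its provenance
#'
#' @param traj a `stimulus_trajectory`.
#' @param path CSV output path (`time_s`, `radius_px`); a JSON provenance
#'   sidecar is written next to it.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(data.frame(time_s = traj$times, radius_px = traj$radii),
                   path, row.names = FALSE)
  jsonlite::write_json(
    c(traj$provenance,
      list(update_freq = traj$update_freq,
           baseline_radius = traj$baseline_radius, bounds = traj$bounds)),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
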
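#' Canonical EEG frequency bands
#'
#' The four narrowband ranges classically targeted in neurofeedback:
#' theta 4-8 Hz, alpha 8-12 Hz, sensorimotor rhythm (SMR) 12-15 Hz and
#' beta 15-30 Hz. Band membership is half-open, `[low, high)`, so no
#' frequency bin ever contributes to two bands.
#'
#' @return Named list of `c(low, high)` edges in Hz.
#' @export
eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 12), smr = c(12, 15), beta = c(15, 30))
}

.conditions <- c("Control", "1Hz", "5Hz", "10Hz")
.ssvep_freq <- c(Control = NA_real_, `1Hz` = NA_real_, `5Hz` = 5, `10Hz` = 10)

#' Configuration for the synthetic EEG cohort generator
#'
#' Defaults emulate the study conditions of a single passive
#' neurofeedback-like session: 32 subjects, 4 conditions (Control, 1 Hz,
#' 5 Hz, 10 Hz stimulus-update rates) x 8 trials of 60 s sampled at 250 Hz
#' on Fz/Cz/Pz, a 1/f aperiodic background with band-limited oscillations,
#' a small linear increase in alpha log-power per trial, a condition-level
#' theta increment at Pz, and a steady-state visual response at the
#' stimulus-update frequency in the 5 and 10 Hz conditions (none at 1 Hz).
#'
#' Effect sizes (`alpha_trend`, `theta_condition_effect`, `subject_sd`) are
#' expressed in z-units of the standardized dB band power, i.e. on the scale
#' on which the multilevel models are fitted. The generator converts them to
#' dB internally through an analytic prediction of the pooled dB standard
#' deviation (see the methods vignette).
#'
#' @param n_subjects number of subjects in the cohort.
#' @param n_conditions number of conditions (the task design has 4).
#' @param n_trials_per_condition trials per condition block.
#' @param trial_duration trial length in seconds.
#' @param sampling_rate sampling rate in Hz; must exceed twice the highest
#'   band edge (30 Hz).
#' @param channels electrode labels.
#' @param aperiodic_exponent exponent of the 1/f^x background.
#' @param background_sd broadband background RMS amplitude in microvolts.
#' @param band_amplitudes named vector of baseline oscillation RMS
#'   amplitudes (microvolts) for theta/alpha/smr/beta.
#' @param alpha_trend ground-truth increase in z-scored alpha dB power per
#'   global trial (the "Trial" slope the models should recover).
#' @param theta_condition_effect ground-truth z-unit theta increment in the
#'   experimental (non-Control) conditions, applied on
#'   `theta_effect_channels`.
#' @param theta_effect_channels channels carrying the theta condition effect.
#' @param ssvep_amplitude amplitude (microvolts) of the sinusoidal
#'   steady-state component at the condition's stimulus frequency (5 or
#'   10 Hz; the 1 Hz condition deliberately carries none).
#' @param ssvep_channel_gain named per-channel gain applied to the
#'   steady-state component (posterior-dominant by default).
#' @param subject_sd between-subject SD (z-units) of Gaussian perturbations
#'   of the varying effects (alpha slope, theta condition effect).
#' @param intercept_sd_db between-subject SD of band-power intercepts, dB.
#' @param trial_noise_db within-subject trial-to-trial band-power jitter, dB.
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 32,
                              n_conditions = 4,
                              n_trials_per_condition = 8,
                              trial_duration = 60,
                              sampling_rate = 250,
                              channels = c("Fz", "Cz", "Pz"),
                              aperiodic_exponent = 1,
                              background_sd = 10,
                              band_amplitudes = c(theta = 3, alpha = 6,
                                                  smr = 1.5, beta = 2),
                              alpha_trend = 0.02,
                              theta_condition_effect = 0.165,
                              theta_effect_channels = "Pz",
                              ssvep_amplitude = 1.5,
                              ssvep_channel_gain = c(Fz = 0.4, Cz = 0.7, Pz = 1),
                              subject_sd = 0.015,
                              intercept_sd_db = 2.5,
                              trial_noise_db = 0.2,
                              seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_conditions = as.integer(n_conditions),
              n_trials_per_condition = as.integer(n_trials_per_condition),
              trial_duration = trial_duration,
              sampling_rate = sampling_rate,
              channels = channels,
              aperiodic_exponent = aperiodic_exponent,
              background_sd = background_sd,
              band_amplitudes = band_amplitudes,
              alpha_trend = alpha_trend,
              theta_condition_effect = theta_condition_effect,
              theta_effect_channels = theta_effect_channels,
              ssvep_amplitude = ssvep_amplitude,
              ssvep_channel_gain = ssvep_channel_gain,
              subject_sd = subject_sd,
              intercept_sd_db = intercept_sd_db,
              trial_noise_db = trial_noise_db,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  counts <- c("n_subjects", "n_conditions", "n_trials_per_condition")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("configuration error: '", nm, "' must be a count >= 1",
           call. = FALSE)
  }
  if (cfg$n_conditions > length(.conditions))
    stop("configuration error: at most ", length(.conditions),
         " conditions are defined", call. = FALSE)
  top_edge <- max(vapply(eeg_bands(), max, numeric(1)))
  if (cfg$sampling_rate <= 2 * top_edge)
    stop("configuration error: sampling_rate must exceed twice the highest ",
         "band edge (", 2 * top_edge, " Hz)", call. = FALSE)
  if (cfg$trial_duration <= 0)
    stop("configuration error: trial_duration must be positive",
         call. = FALSE)
  amps <- c(cfg$band_amplitudes, cfg$ssvep_amplitude, cfg$background_sd)
  if (any(!is.finite(amps)) || any(amps < 0))
    stop("configuration error: amplitudes must be finite and >= 0",
         call. = FALSE)
  if (!all(names(eeg_bands()) %in% names(cfg$band_amplitudes)))
    stop("configuration error: band_amplitudes must name all of ",
         paste(names(eeg_bands()), collapse = ", "), call. = FALSE)
  invisible(cfg)
}

#' Latin-square condition orders
#'
#' The partial Latin-square counterbalancing of the task: four quadruplets
#' of condition indices (2143, 1432, 3214, 4321; 1 = Control, 2 = 1 Hz,
#' 3 = 5 Hz, 4 = 10 Hz) so each condition occupies every temporal position.
#'
#' @return List of four integer vectors of length 4.
#' @seealso [assign_latin_square()]
#' @export
latin_square_orders <- function() {
  list(c(2L, 1L, 4L, 3L),
       c(1L, 4L, 3L, 2L),
       c(3L, 2L, 1L, 4L),
       c(4L, 3L, 2L, 1L))
}

#' Assign subjects to Latin-square orders
#'
#' Distributes subjects across the four quadruplets as evenly as possible
#' (cyclic assignment), so 32 subjects give exactly 8 per quadruplet.
#'
#' @param n_subjects number of subjects.
#' @return Integer vector of length `n_subjects` indexing
#'   [latin_square_orders()].
#' @export
assign_latin_square <- function(n_subjects) {
  ((seq_len(n_subjects) - 1L) %% 4L) + 1L
}

## ---- internal synthesis helpers ----------------------------------------

# one-sided background PSD (uV^2/Hz) on a frequency grid; total power
# over (0, nyquist] equals background_sd^2
.background_psd <- function(freq, exponent, background_sd, df) {
  f <- pmax(freq, 0.5)
  u <- f^(-exponent)
  u[1] <- 0                                   # no DC power
  u * background_sd^2 / (sum(u) * df)
}

# same 1/f shape evaluated on an arbitrary grid, reusing the scale constant
# fixed on the synthesis grid
.background_on <- function(freq, exponent, scale_c) {
  f <- pmax(freq, 0.5)
  out <- scale_c * f^(-exponent)
  out[freq == 0] <- 0
  out
}

# oscillation bump shape restricted to its band (half-open edges)
.band_bump_shape <- function(freq, band) {
  centres <- c(theta = 6, alpha = 10, smr = 13.5, beta = 20)
  widths  <- c(theta = 1, alpha = 1,  smr = 0.8,  beta = 4)
  edges <- eeg_bands()[[band]]
  inside <- freq >= edges[1] & freq < edges[2]
  shape <- exp(-(freq - centres[band])^2 / (2 * widths[band]^2))
  shape[!inside] <- 0
  shape
}

# synthesize a real signal whose one-sided PSD matches `S` on the rfft grid
.synth_from_psd <- function(S, n, fs) {
  nh <- length(S)                              # n/2 + 1 bins for even n
  amp <- sqrt(S * fs * n / 2)
  re <- rnorm(nh)
  im <- rnorm(nh)
  x_half <- complex(real = amp * re / sqrt(2), imaginary = amp * im / sqrt(2))
  x_half[1] <- 0
  if (n %% 2L == 0L)                            # Nyquist bin must be real
    x_half[nh] <- complex(real = sqrt(S[nh] * fs * n) * re[nh], imaginary = 0)
  full <- c(x_half, Conj(x_half[seq(nh - 1L, 2L)]))
  Re(fft(full, inverse = TRUE)) / n
}

# expected SD (dB) of a Welch band-power estimate given the default
# preprocessing trim and segmentation rule; drives the dB <-> z conversion.
# The constant lumps the Hamming equivalent noise bandwidth with the
# overlap-induced correlation between averaged segments.
.measurement_noise_db <- function(cfg, bandwidth,
                                  trim_seconds = 3, max_segments = 8,
                                  overlap = 0.5) {
  n <- round((cfg$trial_duration - trim_seconds) * cfg$sampling_rate)
  if (n < 16) return(1)
  seg <- .welch_segment_length(n, max_segments, overlap)
  df <- cfg$sampling_rate / seg$length
  10 / log(10) * sqrt(1.6 * df / (bandwidth * seg$count))
}

# grid and background of the band-power measurement chain under default
# preprocessing/spectral settings, used to express per-trial band targets
# in the same statistic the pipeline measures (the mean of dB bins)
.analysis_view <- function(cfg, scale_c, trim_seconds = 3,
                           max_segments = 8, overlap = 0.5,
                           bin_spacing = 0.305) {
  n <- round((cfg$trial_duration - trim_seconds) * cfg$sampling_rate)
  L <- .welch_segment_length(n, max_segments, overlap)$length
  nfft <- .welch_nfft(L, cfg$sampling_rate, bin_spacing)
  freq <- (0:(floor(nfft / 2))) * cfg$sampling_rate / nfft
  bands <- eeg_bands()
  list(freq = freq,
       bg = .background_on(freq, cfg$aperiodic_exponent, scale_c),
       bins = lapply(bands, function(e)
         which(freq >= e[1] & freq < e[2])))
}

# mean-dB of the analysis-grid band bins for an injected oscillation level
# `osc` (osc = in-band mean PSD on the synthesis grid); inverted per trial
# by root finding so measured band power lands on the requested dB target
.mean_db_for_osc <- function(osc, bg_bins, shape_bins) {
  mean(10 * log10(bg_bins + shape_bins * osc))
}

.osc_for_target_db <- function(target_db, bg_bins, shape_bins, osc_ref) {
  lo <- osc_ref * 1e-4
  hi <- osc_ref * 1e4
  f <- function(o) .mean_db_for_osc(o, bg_bins, shape_bins) - target_db
  if (f(lo) >= 0) return(lo)                   # at the 1/f floor
  if (f(hi) <= 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = osc_ref * 1e-6)$root
}

#' Predicted pooled SD of measured dB band power
#'
#' Analytic fixed-point prediction of the standard deviation of the dB band
#' powers pooled over all subjects, conditions and trials, per band. This is
#' the scale factor the generator uses to convert z-unit effect sizes
#' (`alpha_trend`, `theta_condition_effect`) into dB increments, so that the
#' downstream z-scored response carries the configured effects.
#'
#' @param cfg a [simulation_config()].
#' @return Named numeric vector (one value per band), in dB.
#' @export
predict_pooled_sd <- function(cfg) {
  bands <- eeg_bands()
  n_total <- cfg$n_conditions * cfg$n_trials_per_condition
  gt <- 0:(n_total - 1L)
  v_t <- mean((gt - mean(gt))^2)
  m2_t <- mean(gt^2)
  p_exp <- (cfg$n_conditions - 1) / cfg$n_conditions
  out <- numeric(length(bands))
  names(out) <- names(bands)
  for (b in names(bands)) {
    bw <- diff(bands[[b]])
    base_var <- cfg$intercept_sd_db^2 + cfg$trial_noise_db^2 +
      .measurement_noise_db(cfg, bw)^2
    denom <- 1
    if (b == "alpha")
      denom <- denom - cfg$alpha_trend^2 * v_t - cfg$subject_sd^2 * m2_t
    if (b == "theta")
      denom <- denom - cfg$theta_condition_effect^2 * p_exp * (1 - p_exp) -
        cfg$subject_sd^2 * p_exp
    if (denom <= 0.1)
      stop("configuration error: effect sizes too large for a stable ",
           "dB <-> z calibration", call. = FALSE)
    out[b] <- sqrt(base_var / denom)
  }
  out
}

#' Simulate a trial-structured EEG cohort
#'
#' Generates one full session per subject: 4 condition blocks x 8 trials
#' (by default) in a Latin-square block order, each trial a multichannel
#' 60-s recording at 250 Hz composed of a 1/f aperiodic background plus
#' band-limited theta/alpha/SMR/beta oscillations. Ground-truth effects:
#' alpha log-power rises by `alpha_trend` (z-units) per global trial, theta
#' log-power is raised by `theta_condition_effect` in non-Control conditions
#' on the configured channels, and the 5/10 Hz conditions carry a sinusoidal
#' steady-state component at the stimulus frequency. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return List of `trial_recording` objects (one per subject x trial),
#'   with the configuration and per-subject ground truth attached as
#'   attributes `config` and `truth`.
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "simulation_config")) cfg <- do.call(simulation_config, cfg)
  validate_simulation_config(cfg)
  set.seed(cfg$seed)

  bands <- eeg_bands()
  fs <- cfg$sampling_rate
  n <- round(cfg$trial_duration * fs)
  nh <- floor(n / 2) + 1L
  freq <- (seq_len(nh) - 1L) * fs / n
  df <- fs / n
  tgrid <- (seq_len(n) - 1L) / fs

  bg <- .background_psd(freq, cfg$aperiodic_exponent, cfg$background_sd, df)
  scale_c <- bg[which(freq >= 1)[1]] * pmax(freq[which(freq >= 1)[1]], 0.5)^
    cfg$aperiodic_exponent
  bump_shapes <- lapply(names(bands), function(b) .band_bump_shape(freq, b))
  names(bump_shapes) <- names(bands)
  band_bins <- lapply(bands, function(e) which(freq >= e[1] & freq < e[2]))
  bump_band_mean <- vapply(names(bands), function(b)
    mean(bump_shapes[[b]][band_bins[[b]]]), numeric(1))

  # analysis-grid view: express targets in the statistic the pipeline
  # measures (mean of dB bins over the band, after trim + Welch)
  av <- .analysis_view(cfg, scale_c)
  a_bg <- lapply(names(bands), function(b) av$bg[av$bins[[b]]])
  names(a_bg) <- names(bands)
  a_shape <- lapply(names(bands), function(b)
    .band_bump_shape(av$freq, b)[av$bins[[b]]] / bump_band_mean[b])
  names(a_shape) <- names(bands)

  osc0 <- cfg$band_amplitudes[names(bands)]^2 / vapply(bands, diff, numeric(1))
  osc0 <- pmax(osc0, 1e-8)
  base_db <- vapply(names(bands), function(b)
    .mean_db_for_osc(osc0[b], a_bg[[b]], a_shape[[b]]), numeric(1))

  orders <- latin_square_orders()
  assign <- assign_latin_square(cfg$n_subjects)
  conds <- .conditions[seq_len(cfg$n_conditions)]
  gain <- cfg$ssvep_channel_gain
  n_ch <- length(cfg$channels)

  eta_slope <- rnorm(cfg$n_subjects, 0, cfg$subject_sd)
  eta_theta <- rnorm(cfg$n_subjects, 0, cfg$subject_sd)
  # between-subject amplitude differences enter as a whole-channel gain
  # (anatomy/impedance-like), which shifts every band's dB power exactly
  gain_db <- matrix(rnorm(cfg$n_subjects * n_ch, 0, cfg$intercept_sd_db),
                    nrow = cfg$n_subjects,
                    dimnames = list(NULL, cfg$channels))

  # dB <-> z scale per (band, channel): the SD the pooled z-scoring will
  # realize on THIS cohort, assembled from the drawn gains and effect
  # perturbations plus the predictable within-trial noise terms, so the
  # configured z-unit effects land on the z scale the pipeline produces
  n_total <- cfg$n_conditions * cfg$n_trials_per_condition
  gt_seq <- 0:(n_total - 1L)
  p_exp <- (cfg$n_conditions - 1) / cfg$n_conditions
  slopes_z <- cfg$alpha_trend + eta_slope
  trend_cells <- as.vector(outer(slopes_z, gt_seq))
  q_alpha <- if (length(trend_cells) > 1) var(trend_cells) else 0
  th_z <- cfg$theta_condition_effect + eta_theta
  q_theta <- mean(th_z^2) * p_exp - (mean(th_z) * p_exp)^2
  s_db <- matrix(0, nrow = length(bands), ncol = n_ch,
                 dimnames = list(names(bands), cfg$channels))
  for (ch in seq_len(n_ch)) {
    v_gain <- if (cfg$n_subjects > 1) var(gain_db[, ch]) else 0
    for (b in names(bands)) {
      base_var <- v_gain + cfg$trial_noise_db^2 +
        .measurement_noise_db(cfg, diff(bands[[b]]))^2
      q <- 0
      if (b == "alpha") q <- q_alpha
      if (b == "theta" && cfg$channels[ch] %in% cfg$theta_effect_channels)
        q <- q_theta
      if (q >= 0.9)
        stop("configuration error: effect sizes too large for a stable ",
             "dB <-> z calibration", call. = FALSE)
      s_db[b, ch] <- sqrt(base_var / (1 - q))
    }
  }

  recordings <- vector("list", cfg$n_subjects * cfg$n_conditions *
                         cfg$n_trials_per_condition)
  k <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    order_s <- orders[[assign[s]]]
    order_s <- order_s[order_s <= cfg$n_conditions]
    for (blk in seq_along(order_s)) {
      cond <- conds[order_s[blk]]
      f_ssvep <- .ssvep_freq[[cond]]
      for (tr in seq_len(cfg$n_trials_per_condition)) {
        gt <- (blk - 1L) * cfg$n_trials_per_condition + tr
        samples <- matrix(0, nrow = n_ch, ncol = n,
                          dimnames = list(cfg$channels, NULL))
        for (ch in seq_len(n_ch)) {
          ch_lab <- cfg$channels[ch]
          target_db <- base_db
          target_db["alpha"] <- target_db["alpha"] +
            (cfg$alpha_trend + eta_slope[s]) * s_db["alpha", ch] * (gt - 1L)
          if (cond != "Control" && ch_lab %in% cfg$theta_effect_channels)
            target_db["theta"] <- target_db["theta"] +
              (cfg$theta_condition_effect + eta_theta[s]) * s_db["theta", ch]
          target_db <- target_db + rnorm(length(bands), 0, cfg$trial_noise_db)

          S <- bg
          for (b in names(bands)) {
            osc <- .osc_for_target_db(target_db[b], a_bg[[b]], a_shape[[b]],
                                      osc0[b])
            S <- S + bump_shapes[[b]] * (osc / bump_band_mean[b])
          }
          x <- .synth_from_psd(S, n, fs)
          if (!is.na(f_ssvep) && cfg$ssvep_amplitude > 0) {
            g <- if (ch_lab %in% names(gain)) gain[[ch_lab]] else 1
            x <- x + cfg$ssvep_amplitude * g *
              sin(2 * pi * f_ssvep * tgrid + runif(1, 0, 2 * pi))
          }
          samples[ch, ] <- x * 10^(gain_db[s, ch] / 20)
        }
        k <- k + 1L
        recordings[[k]] <- trial_recording(
          subject_id = sprintf("S%02d", s),
          condition = cond,
          trial_index = tr,
          global_trial_index = gt,
          sampling_rate = fs,
          samples = samples)
      }
    }
  }
  attr(recordings, "config") <- cfg
  attr(recordings, "truth") <- list(
    pooled_sd_db = s_db,
    base_db = base_db,
    subject_alpha_slope_z = cfg$alpha_trend + eta_slope,
    subject_theta_effect_z = cfg$theta_condition_effect + eta_theta)
  recordings
}

#' One trial of multichannel EEG
#'
#' @param subject_id subject identifier.
#' @param condition one of Control, 1Hz, 5Hz, 10Hz.
#' @param trial_index trial number within its condition block (1-based).
#' @param global_trial_index trial number within the whole session.
#' @param sampling_rate sampling rate in Hz.
#' @param samples channels x time matrix in microvolts, with channel labels
#'   as row names.
#' @return A `trial_recording` object.
#' @export
trial_recording <- function(subject_id, condition, trial_index,
                            global_trial_index, sampling_rate, samples) {
  if (is.null(rownames(samples)))
    stop("samples must carry channel labels as row names", call. = FALSE)
  if (anyDuplicated(rownames(samples)))
    stop("channel labels must be unique", call. = FALSE)
  structure(list(subject_id = subject_id,
                 condition = condition,
                 trial_index = as.integer(trial_index),
                 global_trial_index = as.integer(global_trial_index),
                 channel_labels = rownames(samples),
                 sampling_rate = sampling_rate,
                 samples = samples),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s %s trial %d (global %d): %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$condition, x$trial_index, x$global_trial_index,
              nrow(x$samples), ncol(x$samples), x$sampling_rate))
  invisible(x)
}

.trial_label <- function(rec) {
  sprintf("%s/%s/trial %d", rec$subject_id, rec$condition, rec$trial_index)
}

#' Inject ocular-like artifacts into recordings
#'
#' Adds low-frequency, frontally weighted blink transients (Gaussian bumps,
#' ~70 ms half-width) at Poisson-distributed times. A convenience fixture to
#' exercise the pluggable artifact-removal stage; the injected component is
#' attached to each recording as attribute `"artifact"` so a known-mixing
#' remover can be built in tests.
#'
#' @param recordings list of `trial_recording`.
#' @param blink_rate expected blinks per second; `0` returns the input
#'   unchanged.
#' @param amplitude blink peak amplitude at Fz, microvolts.
#' @param seed optional seed for reproducible artifact placement.
#' @return The recordings with artifacts added.
#' @export
inject_artifacts <- function(recordings, blink_rate, amplitude = 80,
                             seed = NULL) {
  stopifnot(blink_rate >= 0)
  if (blink_rate == 0) return(recordings)
  if (!is.null(seed)) set.seed(seed)
  weights <- c(Fz = 1, Fpz = 1, Fp1 = 1, Fp2 = 1, Cz = 0.5, Pz = 0.2)
  lapply(recordings, function(rec) {
    n <- ncol(rec$samples)
    fs <- rec$sampling_rate
    dur <- n / fs
    n_blinks <- rpois(1, blink_rate * dur)
    art <- matrix(0, nrow = nrow(rec$samples), ncol = n,
                  dimnames = dimnames(rec$samples))
    if (n_blinks > 0) {
      t0 <- runif(n_blinks, 0, dur)
      tgrid <- (seq_len(n) - 1) / fs
      wave <- rep(0, n)
      for (tb in t0) wave <- wave + exp(-((tgrid - tb) / 0.07)^2)
      for (ch in seq_len(nrow(art))) {
        w <- weights[rec$channel_labels[ch]]
        if (is.na(w)) w <- 0.3
        art[ch, ] <- amplitude * w * wave
      }
    }
    rec$samples <- rec$samples + art
    attr(rec, "artifact") <- art
    rec
  })
}

#' Write a cohort to disk as plain-text trials
#'
#' One multichannel CSV per trial (columns = channels, rows = samples) plus
#' a JSON sidecar with metadata, and a manifest CSV listing every trial.
#'
#' @param recordings list of `trial_recording`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    stem <- sprintf("%s_%s_t%02d", rec$subject_id, rec$condition,
                    rec$trial_index)
    csv <- file.path(dir, paste0(stem, ".csv"))
    utils::write.csv(as.data.frame(t(rec$samples)), csv, row.names = FALSE)
    meta <- rec[c("subject_id", "condition", "trial_index",
                  "global_trial_index", "channel_labels", "sampling_rate")]
    jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                         auto_unbox = TRUE)
    data.frame(subject = rec$subject_id, condition = rec$condition,
               trial = rec$trial_index, path = csv,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
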
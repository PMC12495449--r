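# Closed-form normal-normal Bayes factor for a point null at 0, via the
# sufficient statistic ybar ~ N(theta, sigma^2/n): the independent oracle
# for the Savage-Dickey estimator.
bf_normal_normal <- function(y, sigma, prior_sd) {
  n <- length(y)
  ybar <- mean(y)
  dnorm(ybar, 0, sqrt(prior_sd^2 + sigma^2 / n)) /
    dnorm(ybar, 0, sigma / sqrt(n))
}

# single-channel trial recording holding an arbitrary signal
tone_recording <- function(x, fs = 250, channel = "Fz",
                           condition = "Control", trial = 1) {
  trial_recording("S01", condition, trial, trial, fs,
                  matrix(x, nrow = 1, dimnames = list(channel, NULL)))
}

sine_recording <- function(freq, fs = 250, duration = 60, amp = 1, ...) {
  t <- seq_len(round(duration * fs)) / fs
  tone_recording(amp * sin(2 * pi * freq * t), fs = fs, ...)
}

# fabricate an encoded design table directly at the band-power level:
# Gaussian multilevel data with known fixed effects, bypassing the raw-EEG
# stages (fast fixtures for the model-layer tests)
fake_design <- function(n_subjects = 8, trial_slope = 0, cond_effect = 0,
                        subject_sd = 0.05, sigma = 0.3, seed = 1,
                        analysis = "condition") {
  set.seed(seed)
  conds <- c("Control", "1Hz", "5Hz", "10Hz")
  rows <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                      condition = conds, trial_index = 1:8,
                      stringsAsFactors = FALSE)
  rows$global_trial_index <- (match(rows$condition, conds) - 1L) * 8L +
    rows$trial_index
  rows$electrode <- "Fz"
  rows$band <- "alpha"
  u <- rnorm(n_subjects, 0, subject_sd)
  sl <- rnorm(n_subjects, trial_slope, subject_sd / 2)
  names(u) <- names(sl) <- sprintf("S%02d", seq_len(n_subjects))
  cm <- condition_contrasts()
  expw <- cm[rows$condition, "ExpVsControl"]
  rows$power_db <- NA_real_
  rows$power_z <- u[rows$subject] + sl[rows$subject] * (rows$trial_index - 1) +
    cond_effect * expw + rnorm(nrow(rows), 0, sigma)
  encode_design(rows, cm, analysis = analysis)
}

# light sampler settings for reduced-scale test fits
fast_spec <- function(seed = 1, ...) {
  model_spec(chains = 2, iter = 800, warmup = 400, adapt = 300,
             seed = seed, rhat_max = 1.1, ess_min = 50,
             on_nonconvergence = "ignore", ...)
}
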
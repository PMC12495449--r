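#!/usr/bin/env Rscript
# Sham feedback stimulus generation and its temporal-statistics audit.
# A delta pool is built from the successive variations of an alpha
# band-power series (here simulated; in the original protocol, pilot
# recordings), and circle-radius trajectories are generated at the three
# task update rates by i.i.d. resampling from the pool. The audit compares
# the variation statistics of source and generated series: distribution
# shape (skewness, kurtosis) is preserved by construction, but i.i.d.
# resampling destroys the serial structure, so the generated lag-1
# autocorrelation collapses to ~0 however autocorrelated the source was --
# the known temporal-dynamics limitation of this sham scheme.

library(nfdrift)
dir.create("results", showWarnings = FALSE)
set.seed(52)

# alpha band-power series from a short simulated resting recording:
# per-second Welch band powers over a 200-s single-channel cohort trial
cfg <- simulation_config(n_subjects = 1, n_conditions = 1,
                         n_trials_per_condition = 1, trial_duration = 200,
                         channels = "Pz", ssvep_amplitude = 0, seed = 52)
rec <- preprocess_trials(simulate_cohort(cfg),
                         trim = trim_spec(1, 1))[[1]]
win <- 2 * rec$sampling_rate
n_win <- floor(ncol(rec$samples) / win)
alpha_db <- vapply(seq_len(n_win), function(i) {
  seg <- rec$samples[, ((i - 1) * win + 1):(i * win), drop = FALSE]
  psd <- to_db(welch_psd(trial_recording(rec$subject_id, rec$condition, 1,
                                         1, rec$sampling_rate, seg)))
  band_power(psd, eeg_bands()$alpha)[[1]]
}, numeric(1))

pool <- build_delta_pool(alpha_db, scale = 5, id = "simulated-alpha-Pz")
src <- trajectory_stats(pool$values)
message(sprintf("source deltas: n = %d, lag1 = %.2f, skew = %.2f",
                length(pool$values), src$lag1_autocorr, src$skewness))

rows <- lapply(c(1, 5, 10), function(rate) {
  traj <- generate_trajectory(pool, rate, duration = 60, baseline = 100,
                              bounds = c(10, 500), seed = 52 + rate)
  write_trajectory(traj, sprintf("results/trajectory_%dhz.csv", rate))
  gen <- trajectory_stats(traj)
  cmp <- compare_stats(src, gen)
  cmp$update_freq <- rate
  cmp
})
audit <- do.call(rbind, rows)
write.csv(audit, "results/stimulus_stats.csv", row.names = FALSE)
print(audit, digits = 3)

message("lag-1 autocorrelation: source ",
        sprintf("%.2f", src$lag1_autocorr), " vs generated ",
        paste(sprintf("%.2f", audit$generated[
          audit$statistic == "lag1_autocorr"]), collapse = " / "),
        " at 1/5/10 Hz (resampling destroys the temporal dynamics)")
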
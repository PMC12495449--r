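test_that("Latin-square orders are the four counterbalancing quadruplets", {
  orders <- latin_square_orders()
  expect_equal(orders, list(c(2L, 1L, 4L, 3L), c(1L, 4L, 3L, 2L),
                            c(3L, 2L, 1L, 4L), c(4L, 3L, 2L, 1L)))
  for (o in orders) expect_setequal(o, 1:4)
  expect_equal(as.integer(table(assign_latin_square(32))), rep(8L, 4))
  expect_true(all(table(assign_latin_square(12)) == 3L))
})

test_that("cohorts are deterministic given the seed and carry the design", {
  cfg <- simulation_config(n_subjects = 2, trial_duration = 4, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
  expect_length(a, 2 * 32)
  r1 <- a[[1]]
  expect_s3_class(r1, "trial_recording")
  expect_equal(ncol(r1$samples), 4 * 250)
  expect_equal(r1$channel_labels, c("Fz", "Cz", "Pz"))
  # block order of subject 1 follows quadruplet 2143
  conds_s1 <- vapply(a[1:32], `[[`, character(1), "condition")
  expect_equal(unique(conds_s1), c("1Hz", "Control", "10Hz", "5Hz"))
  expect_equal(vapply(a[1:32], `[[`, integer(1), "global_trial_index"), 1:32)
  # different seed changes the data
  c2 <- simulate_cohort(simulation_config(n_subjects = 2, trial_duration = 4,
                                          seed = 12))
  expect_false(identical(a[[1]]$samples, c2[[1]]$samples))
})

test_that("with no oscillations the spectrum is pure 1/f", {
  cfg <- simulation_config(n_subjects = 1, trial_duration = 30,
                           band_amplitudes = c(theta = 0, alpha = 0,
                                               smr = 0, beta = 0),
                           ssvep_amplitude = 0, trial_noise_db = 0,
                           intercept_sd_db = 0, seed = 3)
  coh <- simulate_cohort(cfg)
  psd <- welch_psd(coh[[1]])
  sel <- psd$freq >= 2 & psd$freq <= 40
  logf <- log10(psd$freq[sel])
  for (ch in 1:3) {
    slope <- coef(lm(log10(psd$power[ch, sel]) ~ logf))[2]
    expect_lt(abs(slope + cfg$aperiodic_exponent), 0.2)
  }
})

test_that("the alpha oscillation dominates the spectrum above the aperiodic edge", {
  cfg <- simulation_config(n_subjects = 1, trial_duration = 20, seed = 4,
                           ssvep_amplitude = 0)
  coh <- simulate_cohort(cfg)
  for (rec in coh[c(1, 17)]) {
    psd <- welch_psd(rec)
    sel <- psd$freq >= 2
    for (ch in 1:3) {
      fmax <- psd$freq[sel][which.max(psd$power[ch, sel])]
      expect_gte(fmax, 8)
      expect_lt(fmax, 12)
    }
  }
})

test_that("alpha band power is the largest of the four bands", {
  cfg <- simulation_config(n_subjects = 1, trial_duration = 20, seed = 5,
                           ssvep_amplitude = 0)
  coh <- simulate_cohort(cfg)
  psd <- to_db(welch_psd(coh[[1]]))
  bp <- vapply(eeg_bands(), function(e) band_power(psd, e)[["Fz"]],
               numeric(1))
  expect_equal(names(which.max(bp)), "alpha")
})

test_that("stimulus-frequency conditions carry a spectral peak, 1 Hz does not", {
  # modest ongoing theta/alpha so the entrained line is visible against the
  # band oscillations it sits inside
  cfg <- simulation_config(n_subjects = 1, trial_duration = 20, seed = 6,
                           band_amplitudes = c(theta = 1.5, alpha = 2,
                                               smr = 1.5, beta = 2))
  coh <- simulate_cohort(cfg)
  conds <- vapply(coh, `[[`, character(1), "condition")
  peak_ratio <- function(recs, f0) {
    mean(vapply(recs, function(rec) {
      psd <- welch_psd(rec)
      p <- psd$power["Pz", ]
      centre <- p[which.min(abs(psd$freq - f0))]
      flank <- p[(psd$freq > f0 - 1 & psd$freq < f0 - 0.3) |
                   (psd$freq > f0 + 0.3 & psd$freq < f0 + 1)]
      centre / mean(flank)
    }, numeric(1)))
  }
  expect_gt(peak_ratio(coh[conds == "5Hz"][1:4], 5), 1.4)
  expect_gt(peak_ratio(coh[conds == "10Hz"][1:4], 10), 1.4)
  expect_lt(peak_ratio(coh[conds == "1Hz"][1:4], 1), 1.4)
})

test_that("the induced alpha trend scales with the configured slope", {
  # realized dB drift across trials should track alpha_trend on average
  slope_of <- function(trend, seed) {
    cfg <- simulation_config(n_subjects = 2, trial_duration = 10,
                             alpha_trend = trend, subject_sd = 0,
                             trial_noise_db = 0.1, ssvep_amplitude = 0,
                             seed = seed)
    coh <- simulate_cohort(cfg)
    tab <- band_power_table(preprocess_trials(coh))
    d <- tab[tab$band == "alpha" & tab$electrode == "Fz", ]
    mean(vapply(split(d, d$subject), function(x)
      coef(lm(power_db ~ global_trial_index, x))[[2]], numeric(1))) /
      mean(attr(coh, "truth")$pooled_sd_db["alpha", ])
  }
  s0 <- slope_of(0, 21)
  s2 <- slope_of(0.02, 22)
  s5 <- slope_of(0.05, 23)
  expect_lt(abs(s0), 0.012)
  expect_gt(s2, s0 + 0.005)
  expect_gt(s5, s2 + 0.01)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_subjects = 0), "count")
  expect_error(simulation_config(sampling_rate = 50), "twice the highest")
  expect_error(simulation_config(background_sd = -1), "amplitudes")
})

test_that("artifact injection is additive and removable by a known-mixing stage", {
  cfg <- simulation_config(n_subjects = 1, trial_duration = 8, seed = 7)
  coh <- simulate_cohort(cfg)[1:2]
  expect_identical(inject_artifacts(coh, 0), coh)
  dirty <- inject_artifacts(coh, blink_rate = 0.5, seed = 99)
  v_clean <- var(coh[[1]]$samples["Fz", ])
  v_dirty <- var(dirty[[1]]$samples["Fz", ])
  expect_gt(v_dirty, v_clean)
  # known-mixing remover: subtract the recorded artifact component
  remover <- function(rec) {
    rec$samples <- rec$samples - attr(rec, "artifact")
    attr(rec, "components_removed") <- 1L
    rec
  }
  cleaned <- remove_artifact_components(dirty[[1]], remover)
  expect_gt(cor(cleaned$samples["Fz", ], coh[[1]]$samples["Fz", ]), 0.95)
  expect_identical(attr(cleaned, "components_removed"), 1L)
})

test_that("cohorts round-trip through the plain-text writer", {
  cfg <- simulation_config(n_subjects = 1, trial_duration = 2, seed = 8)
  coh <- simulate_cohort(cfg)[1:2]
  dir <- withr::local_tempdir()
  manifest <- write_cohort(coh, dir)
  expect_equal(nrow(manifest), 2)
  expect_true(all(file.exists(manifest$path)))
  back <- utils::read.csv(manifest$path[1])
  expect_equal(unname(as.matrix(back)), unname(t(coh[[1]]$samples)),
               tolerance = 1e-12)
})
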
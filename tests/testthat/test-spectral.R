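test_that("a pure tone localizes to its frequency bin", {
  p <- welch_psd(sine_recording(10, duration = 57))
  expect_lt(abs(p$freq[which.max(p$power[1, ])] - 10),
            p$freq[2] - p$freq[1] + 1e-9)
})

test_that("the PSD integrates to the signal variance (Parseval)", {
  set.seed(42)
  x <- rnorm(60 * 250)
  p <- welch_psd(x, fs = 250)
  df <- p$freq[2] - p$freq[1]
  expect_lt(abs(sum(p$power[1, ]) * df - var(x)) / var(x), 0.05)
})

test_that("57 s at 250 Hz divides into 7-8 half-overlapping segments", {
  p <- welch_psd(sine_recording(10, duration = 57))
  expect_lte(p$meta$n_segments, 8)
  expect_gte(p$meta$n_segments, 7)
  # the bin spacing honors the configured upper bound
  expect_lte(p$freq[2] - p$freq[1], 0.305)
})

test_that("segment choice picks the longest length within the segment budget", {
  seg <- nfdrift:::.welch_segment_length(14250, 8, 0.5)
  expect_equal(seg$count, 8)
  step <- seg$length - floor(0.5 * seg$length)
  expect_equal((14250 - seg$length) %/% step + 1, 8)
  longer <- seg$length + 1
  step2 <- longer - floor(0.5 * longer)
  expect_lt((14250 - longer) %/% step2 + 1, 8)
  # degenerate: record shorter than would allow 8 segments still works
  seg1 <- nfdrift:::.welch_segment_length(16, 8, 0.5)
  expect_lte(seg1$count, 8)
})

test_that("dB transform is the 10 log10 map with flooring", {
  expect_equal(to_db(1), 0)
  expect_equal(to_db(100), 20)
  expect_equal(to_db(0), 10 * log10(1e-12))
  p <- c(0.5, 1, 2, 8)
  expect_true(all(diff(to_db(p)) > 0))
  psd <- welch_psd(sine_recording(10, duration = 10))
  expect_error(to_db(to_db(psd)), "already in dB")
})

test_that("band power is the mean of dB bins over a half-open range", {
  psd <- structure(list(freq = 4:8,
                        power = matrix(-(1:5), nrow = 1,
                                       dimnames = list("Fz", NULL)),
                        channel_labels = "Fz", fs = 250, scale = "dB",
                        meta = list()),
                   class = "nf_psd")
  expect_equal(band_power(psd, c(4, 8))[["Fz"]], -2.5)  # bins 4,5,6,7
  flat <- psd
  flat$power[] <- 7
  expect_equal(band_power(flat, c(4, 8))[["Fz"]], 7)
  expect_error(band_power(psd, c(4.1, 4.2)), "no frequency bins")
  expect_error(band_power(psd, c(4, 200)), "beyond the frequency grid")
  raw <- welch_psd(sine_recording(10, duration = 10))
  expect_error(band_power(raw, c(8, 12)), "expects a dB spectrum")
})

test_that("the four bands are disjoint under the half-open convention", {
  p <- welch_psd(sine_recording(10, duration = 57))
  sel <- lapply(eeg_bands(), function(e) which(p$freq >= e[1] & p$freq < e[2]))
  all_bins <- unlist(sel)
  expect_equal(anyDuplicated(all_bins), 0)
})

test_that("doubling a band-filling oscillation raises its band by ~6 dB and others by little", {
  # band-limited alpha noise over a weak broadband floor; identical noise
  # realization at both amplitudes isolates the amplitude effect
  n <- 57 * 250
  freq <- (0:(n / 2)) * 250 / n
  floor_psd <- rep(0.02, length(freq))
  alpha_shape <- as.numeric(freq >= 8 & freq < 12)
  bp <- function(amp) {
    set.seed(77)
    x <- nfdrift:::.synth_from_psd(floor_psd + amp^2 / 4 * alpha_shape,
                                   n, 250)
    psd <- to_db(welch_psd(tone_recording(x)))
    vapply(eeg_bands(), function(e) band_power(psd, e)[[1]], numeric(1))
  }
  b1 <- bp(2)
  b2 <- bp(4)
  expect_lt(abs((b2["alpha"] - b1["alpha"]) - 20 * log10(2)), 0.3)
  expect_true(all(abs((b2 - b1)[c("theta", "smr", "beta")]) < 0.5))
})

test_that("z-scoring standardizes each electrode x band group exactly", {
  set.seed(10)
  tab <- expand.grid(subject = c("a", "b", "c"), condition = "Control",
                     trial_index = 1:5, electrode = c("Fz", "Pz"),
                     band = c("alpha", "theta"), stringsAsFactors = FALSE)
  tab$global_trial_index <- tab$trial_index
  tab$power_db <- rnorm(nrow(tab), mean = rep(c(0, 5), each = 1))
  z <- zscore_powers(tab)
  for (g in split(z, interaction(z$electrode, z$band))) {
    expect_lt(abs(mean(g$power_z)), 1e-10)
    expect_lt(abs(sd(g$power_z) - 1), 1e-10)
  }
  # scale and shift invariance
  tab2 <- tab
  tab2$power_db <- tab$power_db * 10 + 3
  expect_equal(zscore_powers(tab2)$power_z, z$power_z, tolerance = 1e-10)
  # an outlier gets the extreme z-score in its group
  tab3 <- tab
  tab3$power_db[1] <- 1e3
  z3 <- zscore_powers(tab3)
  g <- z3[z3$electrode == "Fz" & z3$band == "alpha", ]
  expect_equal(which.max(g$power_z), 1L)
  # degenerate groups error
  tab4 <- tab
  tab4$power_db[tab4$electrode == "Fz" & tab4$band == "alpha"] <- 1
  expect_error(zscore_powers(tab4), "zero variance")
})

test_that("band-power tables are reproducible and tidy", {
  cfg <- simulation_config(n_subjects = 1, trial_duration = 6, seed = 12)
  coh <- simulate_cohort(cfg)[1:4]
  t1 <- band_power_table(coh)
  t2 <- band_power_table(coh)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 4 * 3 * 4)
  expect_setequal(unique(t1$band), names(eeg_bands()))
})
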
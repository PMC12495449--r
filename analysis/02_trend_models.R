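#!/usr/bin/env Rscript
# Trial-repetition trend analyses on the simulated cohort: for each of the
# 12 response variables (4 bands x 3 electrodes), fit the Bayesian
# multilevel trend model with maximal varying effects, once on the eight
# Control-condition trials and once across all 32 trials ignoring
# condition. Each model is fitted five times (the stability protocol) and
# the mean estimates / envelope credible intervals / mean Bayes factors
# are reported, in the published table layout.
#
# Expected finding with the default ground truth: substantial evidence
# (BF10 > 3) for a positive trial effect in the alpha rows and evidence
# for the null elsewhere. Because the Bayes factor is steep where the
# posterior sits ~3 SDs from zero, a weak cohort draw can leave a single
# alpha electrode insensitive in the 8-trial Control-only analysis; the
# 32-trial whole-task analysis is decisive at every electrode.

library(nfdrift)

tab <- read.csv("results/band_power.csv")
spec <- model_spec(chains = 2, iter = 1000, warmup = 400, adapt = 300,
                   rhat_max = 1.1, ess_min = 50, seed = 11)

fit_table <- function(analysis) {
  enc <- encode_design(tab, analysis = analysis)
  grid <- expand.grid(electrode = unique(tab$electrode),
                      band = unique(tab$band), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rep <- suppressWarnings(
      stability_protocol(enc, spec, n_runs = 5, parameters = "trial_c",
                         electrode = grid$electrode[i], band = grid$band[i]))
    cbind(band = grid$band[i], electrode = grid$electrode[i],
          rep[, c("estimate", "lower", "upper", "bf10", "bf10_plus",
                  "evidence")])
  })
  do.call(rbind, rows)
}

message("control-condition trend models (12 responses x 5 runs) ...")
ctrl <- fit_table("control_only")
write.csv(ctrl, "results/trend_control.csv", row.names = FALSE)
print(ctrl, digits = 3)

message("whole-task trend models (trials 1-32) ...")
whole <- fit_table("whole_task")
write.csv(whole, "results/trend_whole_task.csv", row.names = FALSE)
print(whole, digits = 3)

message("H1 rows (control condition): ",
        paste(ctrl$band[ctrl$evidence == "H1"],
              ctrl$electrode[ctrl$evidence == "H1"], collapse = ", "))
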
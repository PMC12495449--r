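test_that("Savage-Dickey matches the conjugate normal-normal Bayes factor", {
  for (seed in 1:3) {
    set.seed(seed)
    y <- rnorm(30, mean = 0.2, sd = 1)
    draws <- fit_gaussian_mean(y, sigma = 1, prior_sd = 1, iter = 8000,
                               seed = seed)
    bf_sd <- bayes_factor(draws, prior_sd = 1)
    bf_exact <- bf_normal_normal(y, sigma = 1, prior_sd = 1)
    expect_lt(abs(bf_sd - bf_exact) / bf_exact, 0.05)
  }
})

test_that("a posterior identical to the prior gives BF10 = 1", {
  set.seed(1)
  draws <- rnorm(20000)
  expect_lt(abs(bayes_factor(draws, prior_sd = 1) - 1), 0.05)
})

test_that("directional BFs follow the positive-mass correction", {
  set.seed(2)
  sym <- rnorm(20000)                       # symmetric around 0
  expect_lt(abs(directional_bf(sym, prior_sd = 1) /
                  bayes_factor(sym, prior_sd = 1) - 1), 0.05)
  pos <- rnorm(20000, mean = 6, sd = 1)     # entirely above 0
  expect_equal(directional_bf(pos, prior_sd = 1),
               2 * bayes_factor(pos, prior_sd = 1))
  expect_error(bayes_factor(rnorm(50)), "too few posterior draws")
})

test_that("evidence classification uses the 3 and 1/3 thresholds", {
  expect_equal(classify_evidence(c(7.642, 0.065, 2.219, 3.0001, 1 / 3.001)),
               c("H1", "H0", "insensitive", "H1", "H0"))
  expect_error(classify_evidence(-1))
})

test_that("the multilevel model recovers a strong simulated effect", {
  design <- fake_design(n_subjects = 10, trial_slope = 0.1,
                        cond_effect = 0.5, sigma = 0.25, seed = 3)
  fit <- fit_multilevel(design, fast_spec(seed = 3))
  s <- fit$summary
  sl <- s[s$parameter == "trial_c", ]
  expect_gt(sl$lower, 0.05)
  expect_lt(abs(sl$estimate - 0.1), 0.03)
  ce <- s[s$parameter == "ExpVsControl", ]
  expect_lt(abs(ce$estimate - 0.5), 0.15)
  expect_gt(bayes_factor(fit, "trial_c"), 3)
  expect_gt(bayes_factor(fit, "ExpVsControl"), 3)
  expect_gte(directional_bf(fit, "trial_c"), bayes_factor(fit, "trial_c"))
})

test_that("posterior means agree with an independent mixed-model fit (lme4)", {
  design <- fake_design(n_subjects = 12, trial_slope = 0.06,
                        cond_effect = 0.3, subject_sd = 0.08, sigma = 0.3,
                        seed = 8)
  fit <- fit_multilevel(design, model_spec(chains = 2, iter = 2000,
                                           warmup = 500, seed = 2,
                                           on_nonconvergence = "ignore"))
  lmer_fit <- lme4::lmer(
    power_z ~ trial_c + ExpVsControl + F5v1 + F10v5 +
      trial_x_ExpVsControl + trial_x_F5v1 + trial_x_F10v5 +
      (1 + trial_c + ExpVsControl + F5v1 + F10v5 +
         trial_x_ExpVsControl + trial_x_F5v1 + trial_x_F10v5 || subject),
    data = design)
  ref <- lme4::fixef(lmer_fit)
  for (p in c("trial_c", "ExpVsControl")) {
    row <- fit$summary[fit$summary$parameter == p, ]
    post_sd <- (row$upper - row$lower) / (2 * 1.96)
    expect_lt(abs(row$estimate - ref[[p]]), 0.5 * post_sd)
  }
})

test_that("fits are deterministic given the seed", {
  design <- fake_design(n_subjects = 6, trial_slope = 0.05, seed = 4)
  f1 <- fit_multilevel(design, fast_spec(seed = 9))
  f2 <- fit_multilevel(design, fast_spec(seed = 9))
  expect_identical(f1$summary$estimate, f2$summary$estimate)
})

test_that("model preconditions and diagnostics gates are enforced", {
  design <- fake_design(n_subjects = 6, seed = 5)
  one <- design[design$subject == "S01", ]
  attr(one, "fixed_terms") <- attr(design, "fixed_terms")
  expect_error(fit_multilevel(one, fast_spec()), "at least 2 subjects")
  no_terms <- design
  attr(no_terms, "fixed_terms") <- NULL
  expect_error(fit_multilevel(no_terms, fast_spec()), "fixed_terms")
  strict <- model_spec(chains = 2, iter = 200, warmup = 50, adapt = 100,
                       rhat_max = 1.0001, ess_min = 1e5,
                       on_nonconvergence = "error")
  expect_error(fit_multilevel(design, strict), "diagnostics")
})

test_that("the stability protocol aggregates runs with the envelope convention", {
  design <- fake_design(n_subjects = 8, trial_slope = 0.08, sigma = 0.25,
                        seed = 6)
  rep5 <- stability_protocol(design, fast_spec(seed = 1), n_runs = 3,
                             parameters = c("trial_c", "ExpVsControl"))
  runs <- attr(rep5, "runs")
  expect_equal(nrow(rep5), 2)
  expect_equal(unique(runs$run), 1:3)
  for (p in rep5$parameter) {
    rp <- runs[runs$parameter == p, ]
    ag <- rep5[rep5$parameter == p, ]
    expect_equal(ag$bf10, mean(rp$bf10))
    expect_equal(ag$estimate, mean(rp$estimate))
    expect_equal(ag$lower, min(rp$lower))
    expect_equal(ag$upper, max(rp$upper))
    expect_true(all(rp$lower >= ag$lower & rp$upper <= ag$upper))
  }
  # run-to-run estimate spread is small next to the posterior spread
  sl <- runs[runs$parameter == "trial_c", ]
  post_sd <- (mean(sl$upper) - mean(sl$lower)) / (2 * 1.96)
  expect_lt(sd(sl$estimate), 0.1 * post_sd)
})

test_that("the sensitivity sweep spans the default prior grid and shows Lindley behavior", {
  grid <- formals(sensitivity_sweep)$prior_sds
  expect_equal(eval(grid), c(1.0, 0.8, 0.6, 0.4, 0.2))
  null_design <- fake_design(n_subjects = 8, trial_slope = 0,
                             cond_effect = 0, sigma = 0.25, seed = 7)
  sw <- sensitivity_sweep(null_design, fast_spec(seed = 2),
                          prior_sds = c(1, 0.2), n_runs = 1,
                          parameters = "trial_c")
  expect_equal(nrow(sw), 2)
  # under the null, widening the prior strengthens support for H0
  expect_lt(sw$bf10[sw$prior_sd == 1], sw$bf10[sw$prior_sd == 0.2])
})
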
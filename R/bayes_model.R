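#' Settings for the Bayesian multilevel model
#'
#' The response (z-scored dB band power for one electrode x band) is
#' modelled as Gaussian with fixed effects intercept + trial + condition
#' contrasts + trial x contrast interactions (whichever the design encodes)
#' and the maximal varying-effect structure: every fixed term also varies
#' by subject. Fixed coefficients get independent regularizing
#' `N(0, prior_sd)` priors; varying-effect scales and the residual scale get
#' half-normal(0, 1) priors.
#'
#' @param prior_sd SD of the normal prior on each fixed coefficient,
#'   z-units (default 1: a 95% prior probability of lying within +-2 SD of
#'   the standardized response).
#' @param chains number of MCMC chains.
#' @param iter posterior draws per chain (after warmup).
#' @param warmup warmup (burn-in) iterations per chain.
#' @param adapt adaptation iterations (used by the JAGS-based auxiliary
#'   samplers such as [fit_gaussian_mean()]; the collapsed Gibbs sampler
#'   needs none).
#' @param seed integer seed; chain RNGs are derived from it.
#' @param rhat_max convergence gate on the split-chain potential scale
#'   reduction factor.
#' @param ess_min convergence gate on effective draws per fixed effect.
#' @param on_nonconvergence what to do when a gate fails: warn (default),
#'   error (carrying the diagnostics), or ignore.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(prior_sd = 1, chains = 4, iter = 2000, warmup = 1000,
                       adapt = 500, seed = 1L, rhat_max = 1.01,
                       ess_min = 400,
                       on_nonconvergence = c("warn", "error", "ignore")) {
  stopifnot(prior_sd > 0, chains >= 1, iter >= 100, warmup >= 0)
  structure(list(prior_sd = prior_sd, chains = as.integer(chains),
                 iter = as.integer(iter), warmup = as.integer(warmup),
                 adapt = as.integer(adapt), seed = as.integer(seed),
                 rhat_max = rhat_max, ess_min = ess_min,
                 on_nonconvergence = match.arg(on_nonconvergence)),
            class = "model_spec")
}

# univariate slice sampler (stepping out + shrinkage) on an unnormalized
# log-density; used for the scale parameters, whose half-normal priors are
# not conditionally conjugate
.slice_step <- function(x0, logf, w = 1, lower = -14, upper = 4,
                        max_steps = 50) {
  f0 <- logf(x0)
  z <- f0 - stats::rexp(1)
  L <- max(x0 - w * runif(1), lower)
  R <- min(L + w, upper)
  k <- max_steps
  while (k > 0 && L > lower && logf(L) > z) { L <- max(L - w, lower); k <- k - 1 }
  k <- max_steps
  while (k > 0 && R < upper && logf(R) > z) { R <- min(R + w, upper); k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# Collapsed Gibbs sampler for the Gaussian multilevel model
#   y_i ~ N(x_i' bs_{subj(i)}, sigma^2),  bs_s ~ N(beta, diag(sd_b^2)),
#   beta_j ~ N(0, prior_sd^2),  sd_b_j, sigma ~ half-normal(0, 1).
# The fixed effects are drawn from their conditional with the subject
# effects integrated out (via Woodbury on per-subject blocks), which
# removes the funnel-type slow mixing that alternating updates suffer
# from in this model; the scale parameters take slice steps on the log
# scale. All conditionals are exact, so effective sample sizes are close
# to the number of draws.
.gibbs_lmm_chain <- function(y, X, subj, prior_sd, n_iter, warmup, seed) {
  set.seed(seed)
  S <- max(subj)
  P <- ncol(X)
  XtX <- vector("list", S)
  Xty <- vector("list", S)
  idx <- split(seq_along(y), subj)
  for (s in seq_len(S)) {
    Xs <- X[idx[[s]], , drop = FALSE]
    XtX[[s]] <- crossprod(Xs)
    Xty[[s]] <- crossprod(Xs, y[idx[[s]]])
  }
  p0 <- rep(1 / prior_sd^2, P)
  beta <- numeric(P)
  bs <- matrix(0, S, P)
  log_sd_b <- rep(log(0.5), P)
  log_sigma <- log(0.5)
  n_keep <- n_iter
  draws <- matrix(NA_real_, n_keep, P + 1)
  for (it in seq_len(warmup + n_iter)) {
    sig2 <- exp(2 * log_sigma)
    dinv <- exp(-2 * log_sd_b)
    # collapsed update of beta: subject effects integrated out
    A <- diag(p0, P)
    r <- numeric(P)
    M_chol <- vector("list", S)
    for (s in seq_len(S)) {
      G <- XtX[[s]] / sig2
      M <- G + diag(dinv, P)
      ch <- chol(M)
      M_chol[[s]] <- ch
      MiG <- chol2inv(ch) %*% G
      A <- A + G - G %*% MiG
      r <- r + (Xty[[s]] / sig2) - G %*% (chol2inv(ch) %*% (Xty[[s]] / sig2))
    }
    chA <- chol(A)
    mu_beta <- backsolve(chA, forwardsolve(t(chA), r))
    beta <- mu_beta + backsolve(chA, rnorm(P))
    # subject effects given beta
    for (s in seq_len(S)) {
      ch <- M_chol[[s]]
      rhs <- Xty[[s]] / sig2 + dinv * beta
      mu_s <- backsolve(ch, forwardsolve(t(ch), rhs))
      bs[s, ] <- mu_s + backsolve(ch, rnorm(P))
    }
    # scale parameters
    b <- sweep(bs, 2, beta)
    for (j in seq_len(P)) {
      ssq <- sum(b[, j]^2)
      log_sd_b[j] <- .slice_step(log_sd_b[j], function(ls) {
        sd2 <- exp(2 * ls)
        -S * ls - ssq / (2 * sd2) - sd2 / 2
      })
    }
    e <- y - rowSums(X * bs[subj, , drop = FALSE])
    sse <- sum(e^2)
    log_sigma <- .slice_step(log_sigma, function(ls) {
      s2 <- exp(2 * ls)
      -length(y) * ls - sse / (2 * s2) - s2 / 2
    })
    if (it > warmup)
      draws[it - warmup, ] <- c(beta, exp(log_sigma))
  }
  draws
}

.subset_response <- function(design, electrode, band) {
  if (!is.null(electrode)) design <- design[design$electrode == electrode, ]
  if (!is.null(band)) design <- design[design$band == band, ]
  if (!is.null(design$electrode) && length(unique(design$electrode)) > 1)
    stop("model error: design spans several electrodes; pass `electrode`",
         call. = FALSE)
  if (!is.null(design$band) && length(unique(design$band)) > 1)
    stop("model error: design spans several bands; pass `band`",
         call. = FALSE)
  if (nrow(design) == 0)
    stop("model error: empty design after subsetting", call. = FALSE)
  design
}

#' Fit the Bayesian linear multilevel model
#'
#' Exact collapsed Gibbs sampling of the Gaussian multilevel model on an
#' encoded design (see [encode_design()]), with the maximal varying-effect
#' structure mirrored from the fixed terms. Fixed effects are drawn with
#' the subject effects integrated out, so the chains mix at close to one
#' effective draw per iteration even when varying-effect scales are near
#' zero; scale parameters take slice steps under their half-normal priors.
#'
#' @param design an encoded design table carrying attribute `fixed_terms`;
#'   may contain several (electrode, band) responses, in which case
#'   `electrode`/`band` select one.
#' @param spec a [model_spec()].
#' @param response response column, default `"power_z"`.
#' @param electrode,band optional response selectors.
#' @return Object of class `nf_fit`: a draws matrix (iterations x fixed
#'   effects, plus `sigma`), a summary data frame (posterior mean, 95%
#'   credible interval, split-chain Rhat, effective draws), and the spec.
#' @export
fit_multilevel <- function(design, spec = model_spec(),
                           response = "power_z",
                           electrode = NULL, band = NULL) {
  fixed <- attr(design, "fixed_terms")
  if (is.null(fixed))
    stop("model error: design lacks fixed_terms; use encode_design()",
         call. = FALSE)
  design <- .subset_response(design, electrode, band)
  if (!response %in% names(design))
    stop("model error: no response column '", response, "'", call. = FALSE)
  subj <- factor(design$subject)
  if (nlevels(subj) < 2)
    stop("model error: at least 2 subjects are required", call. = FALSE)
  X <- cbind(Intercept = 1, as.matrix(design[fixed]))
  storage.mode(X) <- "double"
  y <- design[[response]]
  if (any(!is.finite(y)))
    stop("model error: non-finite response values", call. = FALSE)

  par_names <- c(colnames(X), "sigma")
  chains <- lapply(seq_len(spec$chains), function(ch) {
    d <- .gibbs_lmm_chain(y, X, as.integer(subj), spec$prior_sd,
                          n_iter = spec$iter, warmup = spec$warmup,
                          seed = (spec$seed %% 1000000L) * 100L + ch)
    colnames(d) <- par_names
    d
  })
  samp <- coda::mcmc.list(lapply(chains, coda::mcmc))
  draws <- do.call(rbind, chains)

  rhat <- rep(NA_real_, length(par_names))
  if (spec$chains >= 2) {
    gd <- try(coda::gelman.diag(samp, autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) rhat <- gd$psrf[, 1]
  }
  ess <- as.numeric(coda::effectiveSize(samp))
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975))
  summary <- data.frame(parameter = par_names,
                        estimate = colMeans(draws),
                        lower = qs[1, ], upper = qs[2, ],
                        rhat = rhat, ess = ess,
                        row.names = NULL, stringsAsFactors = FALSE)

  fixed_rows <- summary$parameter != "sigma"
  bad_rhat <- fixed_rows & is.finite(summary$rhat) &
    summary$rhat > spec$rhat_max
  bad_ess <- fixed_rows & summary$ess < spec$ess_min
  if (any(bad_rhat | bad_ess) && spec$on_nonconvergence != "ignore") {
    msg <- sprintf(
      "model diagnostics outside gates (max Rhat %.3f > %.3f or min ESS %.0f < %.0f)",
      max(summary$rhat[fixed_rows], na.rm = TRUE), spec$rhat_max,
      min(summary$ess[fixed_rows]), spec$ess_min)
    if (spec$on_nonconvergence == "error")
      stop("model error: ", msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }

  structure(list(draws = draws, summary = summary, spec = spec,
                 fixed_terms = colnames(X),
                 n_obs = length(y), n_subjects = nlevels(subj),
                 response = response,
                 electrode = if (!is.null(design$electrode))
                   design$electrode[1] else NA_character_,
                 band = if (!is.null(design$band)) design$band[1]
                   else NA_character_),
            class = "nf_fit")
}

#' @export
print.nf_fit <- function(x, ...) {
  cat(sprintf("<nf_fit> %s ~ %s | %d obs, %d subjects, %d draws\n",
              x$response, paste(x$fixed_terms, collapse = " + "),
              x$n_obs, x$n_subjects, nrow(x$draws)))
  print(x$summary, digits = 3)
  invisible(x)
}

.param_draws <- function(fit, parameter) {
  if (inherits(fit, "nf_fit")) {
    if (!parameter %in% colnames(fit$draws))
      stop("model error: unknown parameter '", parameter, "'",
           call. = FALSE)
    fit$draws[, parameter]
  } else as.numeric(fit)
}

# Posterior density at the null value. A Gaussian-kernel estimate
# (Sheather-Jones bandwidth, evaluated exactly at 0) where the null lies
# inside the bulk of the draws; when the posterior mass sits far from zero
# (beyond 3 posterior SDs) the kernel estimate at 0 is dominated by a
# handful of extreme draws and degenerates, so a moment-matched Gaussian
# tail is used instead.
.posterior_density_at_zero <- function(draws) {
  m <- mean(draws)
  s <- sd(draws)
  if (s == 0) return(if (m == 0) Inf else 0)
  if (abs(m) / s > 3) return(dnorm(0, m, s))
  bw <- tryCatch(stats::bw.SJ(draws), error = function(e)
    stats::bw.nrd0(draws))
  kde0 <- mean(dnorm(0, mean = draws, sd = bw))
  # first-order deconvolution of the kernel smoothing: for a Gaussian
  # posterior the kernel estimate has expectation dnorm(0, m, sqrt(s^2 +
  # bw^2)), so this factor removes the smoothing bias exactly in that case
  kde0 * dnorm(0, m, s) / dnorm(0, m, sqrt(s^2 + bw^2))
}

#' Savage-Dickey Bayes factor for a point null at zero
#'
#' `BF10` is the ratio of the prior to the posterior density of the
#' parameter at 0. The prior is the model's `N(0, prior_sd)`; the posterior
#' density at 0 is a kernel estimate from the draws (Sheather-Jones plug-in
#' bandwidth, Gaussian kernel).
#'
#' @param fit an `nf_fit`, or a numeric vector of posterior draws.
#' @param parameter fixed-effect name (ignored for numeric input).
#' @param prior_sd prior SD; defaults to the fit's.
#' @return The Bayes factor BF10 (> 1 favors the presence of the effect).
#' @export
bayes_factor <- function(fit, parameter = "trial_c",
                         prior_sd = NULL) {
  draws <- .param_draws(fit, parameter)
  if (length(draws) < 200)
    stop("BF error: too few posterior draws (", length(draws),
         ") for a stable density estimate at 0; increase iterations",
         call. = FALSE)
  if (is.null(prior_sd))
    prior_sd <- if (inherits(fit, "nf_fit")) fit$spec$prior_sd else 1
  d0 <- .posterior_density_at_zero(draws)
  dnorm(0, 0, prior_sd) / max(d0, 1e-10)
}

#' Directional (one-sided) Bayes factor
#'
#' Order-restricted `BF10+` for a positive effect versus the point null:
#' the Savage-Dickey BF10 multiplied by the posterior-to-prior ratio of the
#' probability mass above zero (the prior is symmetric, so its positive
#' mass is 1/2).
#'
#' @inheritParams bayes_factor
#' @return The directional Bayes factor BF10+.
#' @export
directional_bf <- function(fit, parameter = "trial_c", prior_sd = NULL) {
  draws <- .param_draws(fit, parameter)
  bf <- bayes_factor(fit, parameter, prior_sd)
  bf * mean(draws > 0) / 0.5
}

#' Classify strength of evidence from a Bayes factor
#'
#' Jeffreys-style thresholds: BF10 above 3 is substantial evidence for the
#' presence of an effect (`"H1"`), below 1/3 substantial evidence for its
#' absence (`"H0"`), anything between is insensitive.
#'
#' @param bf10 numeric vector of Bayes factors (> 0).
#' @return Character vector: `"H1"`, `"H0"` or `"insensitive"`.
#' @export
classify_evidence <- function(bf10) {
  stopifnot(all(bf10 > 0))
  ifelse(bf10 > 3, "H1", ifelse(bf10 < 1 / 3, "H0", "insensitive"))
}

#' Repeat-fit stability protocol for Bayes factors
#'
#' MCMC-based Bayes factors fluctuate across runs, so every reported
#' analysis is computed `n_runs` times (default 5) with distinct seeds.
#' Reported per parameter: the mean posterior estimate, the envelope 95%
#' credible interval (smallest lower, largest upper bound across runs), the
#' per-run and mean BF10, the mean directional BF10+, and the evidence
#' class of the mean BF10.
#'
#' @inheritParams fit_multilevel
#' @param n_runs number of repeated fits (>= 2 recommended).
#' @param parameters fixed effects to report; default all but the
#'   intercept.
#' @return A data frame of class `bf_report`; per-run results are attached
#'   as attribute `"runs"`.
#' @export
stability_protocol <- function(design, spec = model_spec(), n_runs = 5,
                               parameters = NULL, response = "power_z",
                               electrode = NULL, band = NULL) {
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    spec_r <- spec
    spec_r$seed <- spec$seed + (r - 1L)
    runs[[r]] <- tryCatch({
      fit <- fit_multilevel(design, spec_r, response, electrode, band)
      pars <- parameters
      if (is.null(pars)) pars <- setdiff(fit$fixed_terms, "Intercept")
      data.frame(run = r, parameter = pars,
                 estimate = fit$summary$estimate[match(pars,
                   fit$summary$parameter)],
                 lower = fit$summary$lower[match(pars,
                   fit$summary$parameter)],
                 upper = fit$summary$upper[match(pars,
                   fit$summary$parameter)],
                 bf10 = vapply(pars, function(p)
                   bayes_factor(fit, p), numeric(1)),
                 bf10_plus = vapply(pars, function(p)
                   directional_bf(fit, p), numeric(1)),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("stability run ", r, " failed and was excluded: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  }
  ok <- Filter(Negate(is.null), runs)
  if (!length(ok))
    stop("model error: every stability run failed", call. = FALSE)
  all_runs <- do.call(rbind, ok)
  agg <- do.call(rbind, lapply(split(all_runs, all_runs$parameter),
    function(d) data.frame(parameter = d$parameter[1],
                           estimate = mean(d$estimate),
                           lower = min(d$lower), upper = max(d$upper),
                           bf10 = mean(d$bf10),
                           bf10_plus = mean(d$bf10_plus),
                           n_runs = nrow(d),
                           stringsAsFactors = FALSE)))
  agg <- agg[match(unique(all_runs$parameter), agg$parameter), ]
  agg$evidence <- classify_evidence(agg$bf10)
  rownames(agg) <- NULL
  attr(agg, "runs") <- all_runs
  class(agg) <- c("bf_report", "data.frame")
  agg
}

#' Prior-sensitivity sweep of Bayes factors
#'
#' Because Bayes factors depend on the prior width, the analysis is
#' repeated over a grid of prior SDs, by default 1.0 down to 0.2 (a priori
#' 95% effect-size ranges from +-2 SD down to +-0.4 SD of the standardized
#' response), with the full stability protocol at each grid point. A
#' failing grid cell is reported as `NA` without aborting the sweep.
#'
#' @inheritParams stability_protocol
#' @param prior_sds grid of prior SDs.
#' @return Data frame with one row per (prior_sd, parameter).
#' @export
sensitivity_sweep <- function(design, spec = model_spec(),
                              prior_sds = seq(1, 0.2, by = -0.2),
                              n_runs = 5, parameters = NULL,
                              response = "power_z",
                              electrode = NULL, band = NULL) {
  stopifnot(all(prior_sds > 0))
  out <- lapply(prior_sds, function(ps) {
    spec_p <- spec
    spec_p$prior_sd <- ps
    rep_p <- tryCatch(
      stability_protocol(design, spec_p, n_runs, parameters, response,
                         electrode, band),
      error = function(e) {
        warning("sensitivity cell prior_sd = ", ps, " failed: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(rep_p))
      return(data.frame(prior_sd = ps, parameter = NA_character_,
                        estimate = NA_real_, bf10 = NA_real_,
                        evidence = NA_character_,
                        stringsAsFactors = FALSE))
    data.frame(prior_sd = ps, parameter = rep_p$parameter,
               estimate = rep_p$estimate, bf10 = rep_p$bf10,
               evidence = rep_p$evidence, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Posterior draws for a Gaussian mean with known noise SD
#'
#' Single-group conjugate toy model (`y ~ N(theta, sigma)` with known
#' `sigma` and `theta ~ N(0, prior_sd)`) sampled with JAGS. Used to
#' validate the Savage-Dickey Bayes factor against the closed-form
#' normal-normal marginal-likelihood ratio.
#'
#' @param y data vector.
#' @param sigma known noise SD.
#' @param prior_sd prior SD on the mean.
#' @param iter draws per chain; `chains`, `warmup`, `seed` as elsewhere.
#' @param chains,warmup,seed sampler settings.
#' @return Numeric vector of posterior draws of the mean.
#' @export
fit_gaussian_mean <- function(y, sigma, prior_sd = 1, iter = 4000,
                              chains = 2, warmup = 500, seed = 1L) {
  code <- "
  model {
    for (i in 1:N) { y[i] ~ dnorm(theta, tau) }
    theta ~ dnorm(0, prior_prec)
  }"
  data <- list(y = y, N = length(y), tau = 1 / sigma^2,
               prior_prec = 1 / prior_sd^2)
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed %% 1000000L) * 100L + ch))
  jm <- rjags::jags.model(textConnection(code), data = data, inits = inits,
                          n.chains = chains, n.adapt = 200, quiet = TRUE)
  if (warmup > 0) stats::update(jm, warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, "theta", n.iter = iter,
                              progress.bar = "none")
  as.numeric(do.call(rbind, lapply(samp, as.matrix)))
}
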
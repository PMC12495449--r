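---
title: "Methods: simulating and modelling spontaneous EEG band-power dynamics"
author: "nfdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and modelling spontaneous EEG band-power dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Neurofeedback protocols reward participants for modulating the power of an
EEG frequency band, and attribute observed band-power changes to that
self-regulation. But the task environment itself -- watching the same
stimulus over many trials, watching a stimulus that is continuously
modified, and the rate at which it is modified -- can move the same EEG
features without any self-regulation at all. Quantifying those
non-specific dynamics requires a pipeline that (i) extracts band power
per trial with a fixed spectral recipe, (ii) tests planned condition
hypotheses with Bayesian multilevel models and Bayes factors, and (iii)
can generate the sham "feedback" stimulus whose dynamics are the control
condition of such experiments. `nfdrift` implements that pipeline
end-to-end, together with a synthetic-cohort generator that provides
ground truth for every downstream stage.

The package analyses a single passive session structured as 4 conditions
(Control, and stimulus updates at 1, 5, 10 Hz) x 8 trials x 60 s at
250 Hz on electrodes Fz, Cz, Pz, with condition order counterbalanced
across subjects by the partial Latin square (2143, 1432, 3214, 4321).

## The synthetic cohort generator

Each trial of each channel is synthesized in the frequency domain as a
`1/f^x` aperiodic background (default exponent 1, broadband RMS 10 uV)
plus four band-limited Gaussian-noise oscillations (truncated Gaussian
bumps inside theta 4-8, alpha 8-12, SMR 12-15 and beta 15-30 Hz). The 5
and 10 Hz conditions additionally carry a deterministic sinusoid at the
stimulus-update frequency -- the steady-state visual response -- with a
posterior-dominant channel profile; the 1 Hz condition deliberately
carries none, mirroring the empirical observation that a 1 Hz update
leaves no spectral line.

Ground-truth effects are specified in *z-units of the standardized dB
band power*, the scale on which the models are fitted:

* `alpha_trend` (default 0.02 z/trial): a linear increase of alpha dB
  power per global trial, on all channels;
* `theta_condition_effect` (default 0.165 z): a theta increment in the
  three experimental conditions, at Pz by default;
* `subject_sd` (default 0.015 z): Gaussian between-subject perturbations
  of both effects, motivating the maximal varying-effect models;
* `trial_noise_db` (default 0.2 dB): within-subject trial-to-trial
  band-power jitter;
* `intercept_sd_db` (default 2.5 dB): between-subject amplitude
  differences, implemented as a whole-channel gain so that every band of
  a subject's channel shifts by the same dB offset (an
  anatomy/impedance-like gain). Band-specific subject traits beyond this
  shared gain are not modelled.

Three numerical points make the effect calibration exact rather than
approximate:

1. **Band powers are means of dB bins.** The spectral stage averages the
   *decibel-transformed* bins across a band (see below), which is a
   Jensen-inequality-different quantity from the dB of the mean power.
   The generator therefore expresses each per-trial band target in
   exactly that statistic -- the mean of `10 log10(PSD)` over the band
   bins of the analysis grid -- and inverts it to an oscillation level by
   root finding against the known injected spectrum. Without this, the
   injected effects would be compressed by a shape-dependent factor.
2. **The dB-to-z scale is computed from the realized cohort.** The
   pooled z-scoring divides by the realized pooled SD, which at modest
   cohort sizes fluctuates noticeably with the drawn subject gains. The
   generator assembles the scale factor from the quantities it has just
   drawn (sample variance of the gains, the drawn effect perturbations)
   plus the predictable within-trial terms, so the configured z-unit
   effects land on the z scale the pipeline actually produces.
3. **The Welch estimation noise enters the scale.** The expected SD of a
   Welch band-power estimate is predicted analytically from the segment
   length, segment count and bandwidth (with a constant lumping the
   Hamming noise bandwidth and overlap correlation, checked against
   simulation), assuming the default trim and segmentation settings; the
   prediction adapts when trials are shortened.

What the generator does **not** emulate: artifacts other than the
optional blink fixture, non-stationarities (drowsiness, impedance drift),
correlated noise across channels and bands, band-specific subject traits,
and any real head geometry. Passing tests on synthetic cohorts therefore
demonstrate that the *pipeline* recovers what was injected under clean,
stationary conditions -- not that real recordings are this well behaved.
Real data will show wider intervals and less tidy evidence patterns; the
simulated Bayes factors for the injected effects are correspondingly more
extreme than a real session would produce.

## Preprocessing

Filtering follows the narrowband recipe: a 0.5 Hz 6th-order Butterworth
high-pass and a 50 Hz 2nd-order IIR notch, each applied
forward-backward so the net phase response is zero. The notch bandwidth
is not part of the published recipe; it is realized as an RBJ biquad
with quality factor Q = 35 (about 1.4 Hz wide), recorded in the
provenance log. Zero-phase application uses odd-reflection padding
(3 s) with steady-state initial conditions, so a constant input maps to
(DC gain)^2 x constant with no startup transient; the residual
commutation error of the two pass orders is bounded by the conditioning
of the 6th-order direct-form high-pass at its very low normalized cutoff
(about 1e-4 relative, far below any quantity of interest).

Trials are trimmed *after* filtering -- the trim exists to delete the
filter transients -- removing `round(2 s x fs)` samples from the head and
`round(1 s x fs)` from the tail (half-open sample interval), so a 60-s
trial at 250 Hz becomes exactly 14250 samples (57 s).

Ocular-artifact removal was a manual, visual-inspection step in the
workflow this package systematizes; it is therefore a pluggable stage:
any callable `trial_recording -> trial_recording` can be supplied, the
default is the identity, and the blink-injection fixture plus a
known-mixing remover exercise the contract in the tests.

## Spectral estimation

Per trial and channel, Welch's method divides the segment into the
longest windows that give at most 8 segments at 50% overlap (14250
samples yield 8 segments of 3166 samples), Hamming-tapers each, and
averages one-sided periodogram densities (uV^2/Hz). Two stated properties
of the original recipe -- the 8-segment rule and a ~0.305 Hz grid -- are
mutually inconsistent for a plain averaged periodogram (8 segments of a
57-s trial give ~0.08 Hz natural spacing), so the configured
`bin_spacing` is honored as an *upper bound*: segments are zero-padded
whenever their natural grid would be coarser, and left on their finer
natural grid otherwise. FFT lengths are rounded up to 2-3-5-smooth
numbers. Power is floored at 1e-12 uV^2/Hz before the `10 log10`
transform, and band power is the arithmetic mean of the dB bins in the
half-open range `[low, high)` -- 8 Hz belongs to alpha, 12 Hz to SMR,
15 Hz to beta -- so no bin is double-counted. z-scoring pools all
subjects, conditions and trials within each (electrode, band).

## Contrasts by generalized inverse

The three condition hypotheses -- experimental-vs-control,
5 Hz-vs-1 Hz, 10 Hz-vs-5 Hz -- are non-orthogonal, so the model's
contrast columns are obtained by applying the Moore-Penrose generalized
inverse to the hypothesis matrix. The intercept row of the hypothesis
matrix uses grand-mean weights (1/4 each), the convention under which
the generalized inverse yields an all-ones intercept column; the
resulting condition matrix has rows Control (1, -3/4, 0, 0),
1 Hz (1, 1/4, -2/3, -1/3), 5 Hz (1, 1/4, 1/3, -1/3) and
10 Hz (1, 1/4, 1/3, 2/3). Entries are snapped to exact small rationals
(and serialized as fraction strings) whenever the numerical inverse
lands within 1e-9 of one, which makes fitted coefficients estimate their
hypothesis quantities exactly. The trial covariate is coded `trial - 1`
(not mean-centred), so condition effects are evaluated at the first
trial of each condition; the whole-task variant codes global trial
`1..32` as `0..31` and drops the condition terms.

## The Bayesian multilevel model

For one (electrode, band) response, the z-scored power is modelled as
Gaussian with fixed effects intercept + trial + three condition
contrasts + trial x contrast interactions, and the maximal varying-effect
structure: every fixed term also varies by subject. Fixed coefficients
get independent regularizing N(0, 1) priors (a 95% prior band of +-2 SD
of the standardized response; the sensitivity sweep narrows this to
+-0.4 SD). Varying-effect scales and the residual scale get
half-normal(0, 1) priors. Varying effects are independent across
coefficients (the zero-correlation-parameter form of the maximal
structure): with the generator's independent perturbations this loses
nothing, and on real data it is the usual robust simplification.

Sampling is by an exact collapsed Gibbs sampler written for this model:
the fixed effects are drawn from their conditional with the subject
effects integrated out (per-subject Woodbury blocks), the subject
effects follow conditionally, and the scales take slice steps on the log
scale under their half-normal priors. Marginalizing the subject effects
removes the funnel-type slow mixing that alternating location updates
suffer from in hierarchical Gaussian models — general-purpose Gibbs
engines showed fixed-effect Rhat up to ~1.5 on this model at practical
budgets, with correspondingly overconfident intervals — and yields close
to one effective draw per iteration (verified by the Rhat/ESS gates).
Posterior means are cross-checked against lme4 mixed-model fits in the
test suite. Default sampling: 4 chains x 2000 draws after 1000 warmup,
with convergence gates Rhat < 1.01 and effective draws > 400 (a gate
failure warns with the diagnostics by default and can be promoted to an
error).

Evidence for each effect is the Savage-Dickey density ratio: BF10 =
prior density at 0 / posterior density at 0, the prior being the known
N(0, prior_sd). The posterior density at 0 is a Gaussian-kernel estimate
at the point (Sheather-Jones bandwidth) with an exact Gaussian
deconvolution factor that removes the kernel's smoothing bias for
normal-shaped posteriors; when the posterior mass sits more than 3
posterior SDs from zero the kernel estimate degenerates (it is then
carried by a handful of extreme draws), so a moment-matched Gaussian
tail is used instead -- this only affects Bayes factors that are already
decisively large. The estimator is held to 5% agreement with the
conjugate closed form in the shipped checks. The directional BF10+ multiplies BF10 by
the posterior-to-prior ratio of mass above zero (prior mass 1/2).
Because MCMC-based Bayes factors fluctuate, every reported analysis is
fitted five times with distinct seeds: tables report the mean estimate,
the envelope credible interval (smallest lower, largest upper bound) and
the mean BF10/BF10+, and evidence is classified H1 above 3, H0 below
1/3, insensitive between. No multiplicity correction is applied; the
regularizing priors carry that burden.

The Savage-Dickey estimator is validated against the closed-form
normal-normal Bayes factor on conjugate toy data (5% tolerance), and the
whole chain against parameter-recovery and null-calibration harnesses.

## Sham stimulus generation and its audit

The sham feedback stimulus is a circle whose radius changes every
1000/200/100 ms (1/5/10 Hz): at each update one delta is drawn uniformly
with replacement from a pool built as the successive differences of an
alpha band-power series mapped linearly to pixels (the pixel-per-dB
scale and the clip bounds are configurable; the original mapping's
quantization is not published, so the linear map is validated through
the distribution-shape statistics only). Radii are hard-clipped at the
bounds, which is recorded in the provenance because clipping can bias
moments. The audit statistics -- variance, skewness, excess kurtosis and
lag-1 autocorrelation -- are computed on the *variation* (delta) series,
where the temporal dynamics live. I.i.d. resampling preserves the pool's
distribution shape but destroys its serial structure, so generated
trajectories match source skewness/kurtosis while their lag-1
autocorrelation collapses to ~0 however autocorrelated the source was:
the package reproduces this known limitation of the sham scheme as a
property, and `compare_stats()` makes it visible per trajectory.

## Problem sizes used in the shipped checks

The test-suite harnesses run at reduced scale, chosen as the smallest
sizes at which the scientific property under test is decided: recovery
and null-calibration use 20 replicate cohorts of 12 subjects with
shortened trials (30 s in the test suite, 20 s in the acceptance
script; the dB-to-z calibration adapts to trial length) and a
2-chain x 1000-draw sampler; the evidence-pattern check runs one
32-subject cohort with full 60-s trials, single fits per response; the
conjugate Bayes-factor oracle uses 10 toy datasets of n = 30 with 50000
draws. The five-run stability protocol and the sensitivity sweep are
exercised on small fabricated designs and in the analysis drivers. With
these sizes the recovery coverage check has a residual flake
probability of a few percent from its 40 binomial coverage events; the
generator seeds are fixed in the tests.

## Known limitations

* The Bayes-factor magnitudes are estimator-dependent (the original
  toolchain bridge-samples marginal likelihoods); evidence *classes*,
  not BF digits, are the comparable quantity.
* Varying-effect correlations are not modelled (the varying-effect
  covariance is diagonal).
* The generator's clean stationarity makes simulated evidence stronger
  than real recordings would yield at the same effect sizes.
* `bin_spacing` is honored as an upper bound on the reporting grid, not
  an exact grid, for the reason given above.
* EDF input/output is not provided (no EDF reader in the dependency
  set); trials are exchanged as multichannel CSV + JSON sidecars.
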
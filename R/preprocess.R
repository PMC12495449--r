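#' Filter specification for trial preprocessing
#'
#' A 0.5 Hz high-pass (6th-order IIR Butterworth) and a 50 Hz notch
#' (2nd-order IIR), both applied forward-backward (zero-phase). The notch
#' quality factor is not part of the published recipe; the default Q = 35
#' gives a -3 dB bandwidth of about 1.4 Hz.
#'
#' @param highpass_cutoff high-pass cutoff, Hz.
#' @param highpass_order Butterworth order of the high-pass.
#' @param notch_freq notch centre frequency, Hz.
#' @param notch_order notch order; must be even (cascaded biquads).
#' @param notch_q notch quality factor (centre frequency / bandwidth).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(highpass_cutoff = 0.5, highpass_order = 6,
                        notch_freq = 50, notch_order = 2, notch_q = 35) {
  stopifnot(highpass_order >= 1, notch_order >= 1, notch_q > 0)
  if (notch_order %% 2 != 0)
    stop("notch_order must be even (realized as cascaded biquads)",
         call. = FALSE)
  structure(list(highpass_cutoff = highpass_cutoff,
                 highpass_order = as.integer(highpass_order),
                 notch_freq = notch_freq,
                 notch_order = as.integer(notch_order),
                 notch_q = notch_q),
            class = "filter_spec")
}

#' Edge-trim specification
#'
#' Head/tail seconds removed from each trial after filtering, to delete
#' filter transients: defaults trim the first 2 s and the last 1 s, so a
#' 60-s trial becomes a 57-s segment.
#'
#' @param head_trim seconds removed from the start.
#' @param tail_trim seconds removed from the end.
#' @return Object of class `trim_spec`.
#' @export
trim_spec <- function(head_trim = 2, tail_trim = 1) {
  stopifnot(head_trim >= 0, tail_trim >= 0)
  structure(list(head_trim = head_trim, tail_trim = tail_trim),
            class = "trim_spec")
}

.check_inside_nyquist <- function(f, fs, what) {
  if (f <= 0 || f >= fs / 2)
    stop("preprocessing error: ", what, " (", f,
         " Hz) must lie strictly inside (0, Nyquist = ", fs / 2, " Hz)",
         call. = FALSE)
}

# RBJ-style second-order IIR notch, normalized coefficients
.design_notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

.design_highpass <- function(cutoff, order, fs) {
  bt <- signal::butter(order, cutoff / (fs / 2), type = "high")
  list(b = bt$b, a = bt$a)
}

# complex frequency response of a rational filter at frequencies f (Hz)
filter_response <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  num <- vapply(z, function(zz) sum(b * zz^(seq_along(b) - 1)), complex(1))
  den <- vapply(z, function(zz) sum(a * zz^(seq_along(a) - 1)), complex(1))
  num / den
}

# forward-backward filtering with odd-reflection padding and steady-state
# initial conditions, so a constant input maps to its (DC-gain)^2 multiple
# with no startup transient
.filtfilt_ss <- function(b, a, x, fs) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(3 * fs))
  g <- sum(b) / sum(a)
  m <- mean(x)
  z <- x - m
  nb <- length(b) - 1L
  na <- length(a) - 1L
  one_pass <- function(v) {
    if (pad > 0) {
      left <- 2 * v[1] - v[seq(pad + 1L, 2L)]
      right <- 2 * v[length(v)] - v[seq(length(v) - 1L, length(v) - pad)]
      vv <- c(left, v, right)
    } else vv <- v
    # steady-state initial conditions at the level of the first sample
    u <- stats::filter(c(rep(vv[1], nb), vv), b, method = "convolution",
                       sides = 1)[-seq_len(nb)]
    y <- if (na > 0)
      stats::filter(u, -a[-1], method = "recursive",
                    init = rep(vv[1] * g, na))
    else u
    as.numeric(y)[seq(pad + 1L, pad + length(v))]
  }
  y <- rev(one_pass(rev(one_pass(z))))
  y + m * g^2
}

#' Zero-phase filter a trial
#'
#' Applies the high-pass and notch filters of a [filter_spec()] to every
#' channel, each forward-backward so the net phase response is zero (no
#' group delay). DC is removed by the high-pass.
#'
#' @param recording a `trial_recording`.
#' @param spec a [filter_spec()].
#' @return The filtered `trial_recording`.
#' @export
zero_phase_filter <- function(recording, spec = filter_spec()) {
  fs <- recording$sampling_rate
  n <- ncol(recording$samples)
  max_order <- max(spec$highpass_order, spec$notch_order)
  if (n <= 3 * max_order)
    stop("preprocessing error: recording too short to filter (",
         .trial_label(recording), ")", call. = FALSE)
  .check_inside_nyquist(spec$highpass_cutoff, fs, "high-pass cutoff")
  .check_inside_nyquist(spec$notch_freq, fs, "notch frequency")
  hp <- .design_highpass(spec$highpass_cutoff, spec$highpass_order, fs)
  nt <- .design_notch_biquad(spec$notch_freq, fs, spec$notch_q)
  n_sections <- spec$notch_order %/% 2L
  for (ch in seq_len(nrow(recording$samples))) {
    x <- .filtfilt_ss(hp$b, hp$a, recording$samples[ch, ], fs)
    for (i in seq_len(n_sections)) x <- .filtfilt_ss(nt$b, nt$a, x, fs)
    recording$samples[ch, ] <- x
  }
  recording
}

#' Trim filter transients from a trial
#'
#' Removes `head_trim` seconds from the start and `tail_trim` from the end,
#' sample-accurately: counts are `round(seconds * sampling_rate)` and the
#' kept range is the half-open sample interval `[head, N - tail)`.
#'
#' @param recording a `trial_recording`.
#' @param spec a [trim_spec()].
#' @return The trimmed `trial_recording`.
#' @export
trim_trial <- function(recording, spec = trim_spec()) {
  n <- ncol(recording$samples)
  head_n <- round(spec$head_trim * recording$sampling_rate)
  tail_n <- round(spec$tail_trim * recording$sampling_rate)
  if (head_n + tail_n >= n)
    stop("preprocessing error: trial too short to trim (",
         .trial_label(recording), ": ", n, " samples, trim ",
         head_n + tail_n, ")", call. = FALSE)
  recording$samples <- recording$samples[, seq(head_n + 1L, n - tail_n),
                                         drop = FALSE]
  recording
}

#' Apply a pluggable artifact-removal stage
#'
#' Ocular component identification was a manual step in the original
#' workflow and is not automated here: the stage accepts any remover
#' callable (`function(trial_recording) -> trial_recording`), defaulting to
#' the identity. A remover may record how many components it removed via
#' the attribute `"components_removed"` on its result.
#'
#' @param recording a `trial_recording`.
#' @param remover `NULL` (identity) or a function of one recording.
#' @return The (possibly cleaned) `trial_recording`.
#' @export
remove_artifact_components <- function(recording, remover = NULL) {
  if (is.null(remover)) return(recording)
  out <- tryCatch(remover(recording), error = function(e)
    stop("preprocessing error: artifact remover failed on ",
         .trial_label(recording), ": ", conditionMessage(e), call. = FALSE))
  if (!inherits(out, "trial_recording"))
    stop("preprocessing error: remover must return a trial_recording",
         call. = FALSE)
  out
}

#' Preprocess a list of trials
#'
#' Filter (zero-phase high-pass + notch), then trim edges, then apply the
#' artifact-removal stage; trimming after filtering deletes the filter
#' transients the trim exists for. A provenance record (filter spec, trim
#' spec, remover name) is attached to the result.
#'
#' @param recordings list of `trial_recording`.
#' @param filter a [filter_spec()].
#' @param trim a [trim_spec()].
#' @param remover optional artifact remover, see
#'   [remove_artifact_components()].
#' @return List of preprocessed recordings.
#' @export
preprocess_trials <- function(recordings, filter = filter_spec(),
                              trim = trim_spec(), remover = NULL) {
  out <- lapply(recordings, function(rec) {
    rec <- zero_phase_filter(rec, filter)
    rec <- trim_trial(rec, trim)
    remove_artifact_components(rec, remover)
  })
  attr(out, "config") <- attr(recordings, "config")
  attr(out, "provenance") <- list(
    filter = unclass(filter), trim = unclass(trim),
    remover = if (is.null(remover)) "identity" else
      deparse(substitute(remover))[1])
  out
}
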
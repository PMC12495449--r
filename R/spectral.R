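#' Spectral estimation settings
#'
#' Welch averaged-periodogram settings: trials are divided into the longest
#' segments yielding at most `max_segments` segments at the given overlap,
#' each segment Hamming-tapered, and periodograms averaged into a power
#' spectral density (uV^2/Hz). `bin_spacing` is the coarsest admissible
#' reporting grid: segments are zero-padded whenever their natural grid
#' (sampling rate / segment length) would be coarser than this, so the
#' configured spacing is honored as an upper bound.
#'
#' @param max_segments maximum number of averaged segments.
#' @param overlap_fraction fractional overlap between segments, in `[0, 1)`.
#' @param window taper; only `"hamming"` is implemented.
#' @param bin_spacing coarsest admissible frequency-bin spacing, Hz.
#' @param detrend `"constant"` (per-segment mean removal) or `"none"`.
#' @return Object of class `spectral_config`.
#' @export
spectral_config <- function(max_segments = 8, overlap_fraction = 0.5,
                            window = "hamming", bin_spacing = 0.305,
                            detrend = c("constant", "none")) {
  stopifnot(max_segments >= 1, overlap_fraction >= 0, overlap_fraction < 1,
            bin_spacing > 0)
  window <- match.arg(window, "hamming")
  structure(list(max_segments = as.integer(max_segments),
                 overlap_fraction = overlap_fraction,
                 window = window,
                 bin_spacing = bin_spacing,
                 detrend = match.arg(detrend)),
            class = "spectral_config")
}

# longest segment length whose overlapping-segment count comes as close to
# (without exceeding) `max_segments`
.welch_segment_length <- function(n, max_segments, overlap) {
  count_for <- function(L) {
    step <- L - floor(overlap * L)
    if (step < 1L) step <- 1L
    as.integer((n - L) %/% step + 1L)
  }
  L <- max(1L, as.integer(n %/% (1 + (max_segments - 1) * (1 - overlap))))
  while (L > 1L && count_for(L) > max_segments) L <- L - 1L
  target <- count_for(L)
  while (L < n && count_for(L + 1L) == target) L <- L + 1L
  list(length = L, count = count_for(L),
       step = L - floor(overlap * L))
}

# FFT length: at least the segment and fine enough for the configured bin
# spacing, rounded up to a 2-3-5-smooth length for fast transforms
.welch_nfft <- function(L, fs, bin_spacing) {
  stats::nextn(max(L, ceiling(fs / bin_spacing)), c(2, 3, 5))
}

.hamming <- function(L) {
  if (L == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
}

#' Welch power spectral density of a trial
#'
#' Averaged, Hamming-windowed, overlapping periodograms per channel,
#' normalized as one-sided density in uV^2/Hz.
#'
#' @param x a `trial_recording`, or a numeric vector (single channel; then
#'   `fs` is required).
#' @param config a [spectral_config()].
#' @param fs sampling rate in Hz, only for numeric input.
#' @return Object of class `nf_psd`: frequencies, a channels x bins power
#'   matrix, and segmentation metadata.
#' @export
welch_psd <- function(x, config = spectral_config(), fs = NULL) {
  if (inherits(x, "trial_recording")) {
    samples <- x$samples
    fs <- x$sampling_rate
    meta <- x[c("subject_id", "condition", "trial_index",
                "global_trial_index")]
  } else {
    stopifnot(is.numeric(x), !is.null(fs))
    samples <- matrix(x, nrow = 1, dimnames = list("x1", NULL))
    meta <- list()
  }
  n <- ncol(samples)
  if (n < 8)
    stop("spectral error: recording shorter than one segment", call. = FALSE)
  seg <- .welch_segment_length(n, config$max_segments,
                               config$overlap_fraction)
  L <- seg$length
  nfft <- .welch_nfft(L, fs, config$bin_spacing)
  w <- .hamming(L)
  u <- sum(w^2)
  nh <- floor(nfft / 2) + 1L
  freq <- (seq_len(nh) - 1L) * fs / nfft
  starts <- seq(1L, n - L + 1L, by = seg$step)[seq_len(seg$count)]

  pow <- matrix(0, nrow = nrow(samples), ncol = nh,
                dimnames = list(rownames(samples), NULL))
  for (ch in seq_len(nrow(samples))) {
    acc <- numeric(nh)
    for (st in starts) {
      s <- samples[ch, st:(st + L - 1L)]
      if (config$detrend == "constant") s <- s - mean(s)
      xt <- c(s * w, numeric(nfft - L))
      X <- fft(xt)[seq_len(nh)]
      p <- (Mod(X)^2) / (fs * u)
      p[2:(nh - 1L)] <- 2 * p[2:(nh - 1L)]
      acc <- acc + p
    }
    pow[ch, ] <- acc / length(starts)
  }
  structure(list(freq = freq, power = pow,
                 channel_labels = rownames(samples),
                 fs = fs, scale = "density",
                 meta = c(meta, list(segment_length = L,
                                     n_segments = seg$count,
                                     nfft = nfft,
                                     config = unclass(config)))),
            class = "nf_psd")
}

#' @export
print.nf_psd <- function(x, ...) {
  cat(sprintf("<nf_psd> %d channel(s), %d bins (%.4g Hz spacing), %d x %d-sample segments, scale = %s\n",
              nrow(x$power), length(x$freq), x$freq[2] - x$freq[1],
              x$meta$n_segments, x$meta$segment_length, x$scale))
  invisible(x)
}

#' Decibel transform of spectral power
#'
#' Maps power to `10 * log10(power)`, flooring at 1e-12 uV^2/Hz so zero
#' power cannot produce `-Inf`. The dB transform is what makes band powers
#' approximately normally distributed for downstream Gaussian modelling.
#'
#' @param x an `nf_psd` (density scale) or a numeric vector of powers.
#' @return Same type as the input, in dB.
#' @export
to_db <- function(x) {
  if (inherits(x, "nf_psd")) {
    if (identical(x$scale, "dB"))
      stop("spectral error: PSD is already in dB", call. = FALSE)
    x$power <- 10 * log10(pmax(x$power, 1e-12))
    x$scale <- "dB"
    return(x)
  }
  10 * log10(pmax(x, 1e-12))
}

#' Average band power from a dB spectrum
#'
#' Arithmetic mean of the dB bins in the half-open range
#' `[band_edges[1], band_edges[2])`, so adjacent bands never share a bin.
#'
#' @param psd_db an `nf_psd` in dB (see [to_db()]).
#' @param band_edges numeric `c(low, high)` in Hz.
#' @return Named numeric vector, one mean dB value per channel.
#' @export
band_power <- function(psd_db, band_edges) {
  stopifnot(inherits(psd_db, "nf_psd"))
  if (!identical(psd_db$scale, "dB"))
    stop("spectral error: band_power expects a dB spectrum; apply to_db()",
         call. = FALSE)
  if (band_edges[2] > max(psd_db$freq) + 1e-9)
    stop("spectral error: band extends beyond the frequency grid",
         call. = FALSE)
  sel <- psd_db$freq >= band_edges[1] & psd_db$freq < band_edges[2]
  if (!any(sel))
    stop("spectral error: no frequency bins fall inside the band",
         call. = FALSE)
  rowMeans(psd_db$power[, sel, drop = FALSE])
}

#' Tidy band-power table for a set of trials
#'
#' The pipeline's central exchange format: one row per trial x electrode x
#' band with the Welch band power in dB.
#'
#' @param recordings list of (preprocessed) `trial_recording`.
#' @param config a [spectral_config()].
#' @param bands named list of band edges, default [eeg_bands()].
#' @return Data frame with columns subject, condition, trial_index,
#'   global_trial_index, electrode, band, power_db.
#' @export
band_power_table <- function(recordings, config = spectral_config(),
                             bands = eeg_bands()) {
  rows <- lapply(recordings, function(rec) {
    psd <- to_db(welch_psd(rec, config))
    per_band <- lapply(names(bands), function(b) {
      p <- band_power(psd, bands[[b]])
      data.frame(subject = rec$subject_id,
                 condition = rec$condition,
                 trial_index = rec$trial_index,
                 global_trial_index = rec$global_trial_index,
                 electrode = names(p),
                 band = b,
                 power_db = unname(p),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_band)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standardize band powers across subjects
#'
#' Adds `power_z`: within each (electrode, band) group, dB powers pooled
#' over all subjects, conditions and trials are z-scored to mean 0, SD 1.
#'
#' @param records a band-power table from [band_power_table()].
#' @return The table with a `power_z` column.
#' @export
zscore_powers <- function(records) {
  stopifnot(all(c("electrode", "band", "power_db") %in% names(records)))
  grp <- interaction(records$electrode, records$band, drop = TRUE)
  if (any(table(grp) < 2))
    stop("standardization error: every (electrode, band) group needs at ",
         "least 2 records", call. = FALSE)
  mu <- ave(records$power_db, grp, FUN = mean)
  sdv <- ave(records$power_db, grp, FUN = sd)
  if (any(sdv == 0))
    stop("standardization error: zero variance in a (electrode, band) group",
         call. = FALSE)
  records$power_z <- (records$power_db - mu) / sdv
  records
}
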
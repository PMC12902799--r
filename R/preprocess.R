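#' Remove amplitude outliers from a timestamped series
#'
#' Flags samples further than `k` standard deviations from the
#' time-averaged value (mean and SD computed on the original series) and
#' deletes them; the gap is bridged later by cubic-spline resampling.
#' A zero-variance series is returned unchanged, since no outlier is
#' definable.
#'
#' @param series Data frame with columns `time_s` and `value`.
#' @param k SD multiple for the threshold (> 0); the conventional rule is 3.
#' @return The cleaned tibble, with attributes `flagged` (integer indices
#'   into the original series) and `removed_fraction`.
#' @export
remove_outliers <- function(series, k = 3) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    abort("`k` must be a single positive number.")
  }
  if (nrow(series) < 10) abort("Series must have at least 10 samples.")
  v <- series$value
  m <- mean(v)
  s <- sd(v)
  flagged <- integer(0)
  if (s > 0) flagged <- which(abs(v - m) > k * s)
  out <- series
  if (length(flagged)) out <- series[-flagged, , drop = FALSE]
  out <- tibble::as_tibble(out)
  attr(out, "flagged") <- flagged
  attr(out, "removed_fraction") <- length(flagged) / length(v)
  out
}

#' Synchronize and resample all channels onto a shared uniform grid
#'
#' Cubic-spline interpolation of every channel onto the common overlap
#' window at sampling interval `Ts`. The grid never extends beyond any
#' channel's observed range, so no extrapolation occurs.
#'
#' @param recording A [physio_recording()] (channels may already have been
#'   outlier-cleaned).
#' @param Ts Sampling interval in seconds.
#' @return A wide tibble (`time_s` plus one column per channel).
#' @export
synchronize_resample <- function(recording, Ts = 1) {
  chans <- recording_channels(recording)
  ranges <- lapply(chans, function(nm) range(recording_channel(recording, nm)$time_s))
  t0 <- max(vapply(ranges, `[`, numeric(1), 1))
  t1 <- min(vapply(ranges, `[`, numeric(1), 2))
  if (t1 - t0 < 120) {
    abort("Channels overlap for less than 120 s; recording unusable.",
          class = "hemodyn_unusable_recording")
  }
  grid <- seq(t0, t1, by = Ts)
  out <- tibble::tibble(time_s = grid)
  for (nm in chans) {
    ch <- recording_channel(recording, nm)
    out[[nm]] <- splinefun(ch$time_s, ch$value, method = "fmm")(grid)
  }
  out
}

#' Zero-phase high-pass filtering of a uniform series
#'
#' Removes the mean and all spectral components below `f_cut` by hard
#' truncation in the frequency domain (an ideal zero-phase brick-wall
#' high-pass). The binary mask makes the filter exactly idempotent;
#' components at or above `f_cut` are untouched, so passband loss is zero.
#' Spectral leakage of near-cutoff content is handled downstream: kernel
#' estimation projects the record's sub-cutoff Fourier terms out of the
#' regression.
#'
#' @param x Numeric vector, uniformly sampled.
#' @param Ts Sampling interval (s).
#' @param f_cut Cut-off frequency (Hz); very-low-frequency drifts and
#'   measurement trends live below 0.005 Hz.
#' @return Filtered numeric vector of the same length.
#' @export
highpass_detrend <- function(x, Ts = 1, f_cut = 0.005) {
  n <- length(x)
  if (n * Ts < 1 / f_cut) {
    abort("Series shorter than one cut-off period; cannot high-pass filter.")
  }
  X <- fft(x - mean(x))
  f <- seq(0, n - 1) / (n * Ts)
  f <- pmin(f, 1 / Ts - f) # two-sided frequency magnitude
  g <- as.numeric(f >= f_cut)
  g[1] <- 0
  Re(fft(X * g, inverse = TRUE)) / n
}

#' Preprocess a raw recording into model-ready uniform series
#'
#' Composes outlier removal, cubic-spline synchronization onto a uniform
#' grid, and zero-phase high-pass filtering, per channel. The result is
#' mean-removed and band-limited above `f_cut`, ready for kernel
#' estimation.
#'
#' @param recording A [physio_recording()].
#' @param Ts Uniform sampling interval (s).
#' @param f_cut High-pass cut-off (Hz).
#' @param outlier_k SD multiple for outlier flagging.
#' @return A tibble of class `uniform_series` (`time_s` plus one column
#'   per available channel) with attributes `Ts`, `removed_fraction`
#'   (named per channel), `flags` (outlier indices per channel),
#'   `qc_warnings` and `subject_id`.
#' @export
preprocess_recording <- function(recording, Ts = 1, f_cut = 0.005,
                                 outlier_k = 3) {
  stopifnot(inherits(recording, "physio_recording"))
  chans <- recording_channels(recording)
  cleaned <- list()
  flags <- list()
  gaps <- list()
  removed <- c()
  for (nm in chans) {
    raw <- recording_channel(recording, nm)
    cl <- remove_outliers(raw, k = outlier_k)
    cleaned[[nm]] <- cl
    flags[[nm]] <- attr(cl, "flagged")
    removed[nm] <- attr(cl, "removed_fraction")
    # Time span bridged by interpolation for each deleted sample: from the
    # last retained sample before it to the first retained one after it.
    fl <- attr(cl, "flagged")
    if (length(fl)) {
      keep_t <- cl$time_s
      gaps[[nm]] <- t(vapply(fl, function(i) {
        lo <- keep_t[keep_t < raw$time_s[i]]
        hi <- keep_t[keep_t > raw$time_s[i]]
        c(if (length(lo)) max(lo) else -Inf, if (length(hi)) min(hi) else Inf)
      }, numeric(2)))
    }
  }
  clean_rec <- physio_recording(
    attr(recording, "subject_id"), cleaned, attr(recording, "duration_s"),
    attr(recording, "site"), attr(recording, "meta")
  )
  wide <- synchronize_resample(clean_rec, Ts = Ts)
  for (nm in chans) wide[[nm]] <- highpass_detrend(wide[[nm]], Ts, f_cut)

  qc <- character(0)
  high <- names(removed)[removed > 0.2]
  if (length(high)) {
    qc <- sprintf("removed_fraction > 20%% on channel %s", high)
    warn(paste(qc, collapse = "; "))
  }
  structure(
    wide,
    Ts = Ts, f_cut = f_cut, removed_fraction = removed, flags = flags,
    gaps = gaps,
    qc_warnings = qc, subject_id = attr(recording, "subject_id"),
    class = c("uniform_series", class(tibble::tibble()))
  )
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf(
    "<uniform_series> subject %s: %d samples at Ts = %.3g s, channels %s\n",
    attr(x, "subject_id") %||% "?", nrow(x), attr(x, "Ts"),
    toString(setdiff(names(x), "time_s"))
  ))
  NextMethod()
}
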
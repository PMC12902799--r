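#' Construct a multi-channel physiological recording
#'
#' A `physio_recording` holds one subject's raw resting recording: up to
#' four irregularly sampled channels (beat-to-beat arterial pressure `ABP`
#' in mmHg, breath-to-breath end-tidal CO2 `ETCO2` in mmHg, beat-to-beat
#' middle-cerebral-artery velocity `CBV` in cm/s, and NIRS tissue
#' oxygenation `OXY` in %). Internally it is a long tibble
#' (`channel`, `time_s`, `value`) with subject metadata in attributes, so
#' it round-trips through the long CSV interchange format unchanged.
#'
#' @param subject_id Character id.
#' @param channels Named list of tibbles with columns `time_s`, `value`;
#'   names among `ABP`, `ETCO2`, `CBV`, `OXY`. `ABP` and `ETCO2` are
#'   required, plus at least one output channel; `CBV` may be absent
#'   (undetectable transcranial Doppler signal).
#' @param duration_s Recording duration in seconds (>= 120).
#' @param site Acquisition site label.
#' @param metadata List of acquisition notes (e.g. TCD hemisphere) and,
#'   for synthetic recordings, the ground truth.
#' @return A tibble of class `physio_recording`.
#' @export
physio_recording <- function(subject_id, channels, duration_s,
                             site = "unknown", metadata = list()) {
  bad <- setdiff(names(channels), .channels)
  if (length(bad)) abort(paste0("Unknown channel(s): ", toString(bad)))
  for (req in c("ABP", "ETCO2")) {
    if (is.null(channels[[req]])) {
      abort(sprintf("Required channel %s is missing.", req),
            class = "hemodyn_missing_channel")
    }
  }
  if (is.null(channels$CBV) && is.null(channels$OXY)) {
    abort("At least one output channel (CBV or OXY) is required.",
          class = "hemodyn_missing_channel")
  }
  if (duration_s < 120) abort("Recordings must last at least 120 s.")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!all(c("time_s", "value") %in% names(ch))) {
      abort(sprintf("Channel %s must have columns time_s and value.", nm))
    }
    if (any(diff(ch$time_s) <= 0)) {
      abort(sprintf("Timestamps of channel %s must be strictly increasing.", nm))
    }
    if (any(!is.finite(ch$value))) {
      abort(sprintf("Channel %s contains non-finite values.", nm))
    }
  }
  long <- dplyr::bind_rows(lapply(names(channels), function(nm) {
    tibble::tibble(channel = nm, time_s = channels[[nm]]$time_s,
                   value = channels[[nm]]$value)
  }))
  structure(
    long,
    subject_id = as.character(subject_id),
    duration_s = duration_s,
    site = site,
    meta = metadata,
    class = c("physio_recording", class(tibble::tibble()))
  )
}

#' @export
print.physio_recording <- function(x, ...) {
  chans <- unique(x$channel)
  cat(sprintf(
    "<physio_recording> subject %s: %.0f s, channels %s\n",
    attr(x, "subject_id"), attr(x, "duration_s"), toString(chans)
  ))
  NextMethod()
}

#' Extract one channel of a recording as a tibble
#' @param recording A [physio_recording()].
#' @param channel Channel name.
#' @return Tibble with `time_s`, `value`, or `NULL` if absent.
#' @export
recording_channel <- function(recording, channel) {
  stopifnot(inherits(recording, "physio_recording"))
  keep <- recording$channel == channel
  if (!any(keep)) return(NULL)
  tibble::tibble(time_s = recording$time_s[keep], value = recording$value[keep])
}

recording_channels <- function(recording) {
  intersect(.channels, unique(recording$channel))
}
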
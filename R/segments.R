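#' Construct an iEEG signal segment
#'
#' A fixed-length, single-channel raw voltage window together with its
#' sampling rate, class label and any known event intervals. Event intervals
#' use 0-based, half-open sample coordinates `[onset_sample, offset_sample)`,
#' the same convention as the CSV sidecar written by [write_dataset()].
#'
#' @param samples Numeric vector of voltages (microvolts, or background-SD
#'   units for synthetic data).
#' @param fs Sampling rate in Hz.
#' @param label One of [ieeg_classes()] or `"unlabeled"`.
#' @param events Data frame with columns `onset_sample`, `offset_sample`,
#'   `kind` (0-based, half-open). Defaults to no events.
#' @param source_id Free-form provenance string.
#'
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(samples, fs, label = "unlabeled",
                        events = empty_events(), source_id = "") {
  check_that(is.numeric(samples) && length(samples) > 0,
             "`samples` must be a non-empty numeric vector")
  check_that(is_number(fs) && fs > 0, "`fs` must be a positive number")
  check_that(label %in% c(ieeg_classes(), "unlabeled"),
             "`label` must be one of the known classes or 'unlabeled'")
  check_that(is.data.frame(events) &&
               all(c("onset_sample", "offset_sample", "kind") %in% names(events)),
             "`events` must have columns onset_sample, offset_sample, kind")
  if (nrow(events) > 0) {
    check_that(all(events$onset_sample >= 0) &&
                 all(events$offset_sample <= length(samples)) &&
                 all(events$onset_sample < events$offset_sample),
               "`events` intervals must lie within [0, length(samples))")
  }
  structure(list(samples = as.numeric(samples), fs = fs, label = label,
                 events = events, source_id = source_id),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d samples @ %g Hz (%.3f s), label=%s, %d event(s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              x$label, nrow(x$events)))
  invisible(x)
}

#' @export
length.eeg_segment <- function(x) length(x$samples)

#' Specify a synthetic graphoelement event
#'
#' Describes one event to inject into a background segment: an interictal
#' spike with a superimposed high-frequency oscillation, a broadband muscle
#' (chewing) artifact burst, or sustained powerline interference.
#'
#' Amplitudes are expressed in multiples of the background standard deviation
#' (backgrounds are normalized to SD = 1 before injection), so an amplitude of
#' 0 is a documented no-op: the segment is returned unchanged, label included.
#'
#' @param kind `"spike_hfo"`, `"muscle_artifact"` or `"powerline"`.
#' @param onset Event onset in seconds from segment start.
#' @param duration Event duration in seconds.
#' @param amplitude Peak amplitude in background-SD units; must be >= 0.
#' @param hfo_freq Oscillation frequency in Hz (spike_hfo only; 80-600 Hz).
#' @param line_freq Mains frequency in Hz (powerline only; typically 50/60).
#'
#' @return An object of class `event_spec`.
#' @export
event_spec <- function(kind, onset, duration, amplitude,
                       hfo_freq = NULL, line_freq = NULL) {
  check_that(kind %in% c("spike_hfo", "muscle_artifact", "powerline"),
             "`kind` must be spike_hfo, muscle_artifact or powerline")
  check_that(is_number(onset) && onset >= 0, "`onset` must be >= 0 seconds")
  check_that(is_number(duration) && duration > 0, "`duration` must be > 0 seconds")
  check_that(is_number(amplitude) && amplitude >= 0, "`amplitude` must be >= 0")
  if (kind == "spike_hfo") {
    check_that(is_number(hfo_freq) && hfo_freq >= 80 && hfo_freq <= 600,
               "`hfo_freq` must lie in 80-600 Hz")
  }
  if (kind == "powerline") {
    check_that(is_number(line_freq) && line_freq > 0,
               "`line_freq` must be a positive frequency")
  }
  structure(list(kind = kind, onset = onset, duration = duration,
                 amplitude = amplitude, hfo_freq = hfo_freq,
                 line_freq = line_freq),
            class = "event_spec")
}

# Sample interval (0-based half-open) of an event inside a segment; errors if
# the event does not fit.
event_interval <- function(event, segment) {
  n <- length(segment$samples)
  i0 <- round(event$onset * segment$fs)
  i1 <- i0 + round(event$duration * segment$fs)
  check_that(i0 >= 0 && i1 <= n,
             sprintf("event [%g, %g] s lies outside the %g-s segment",
                     event$onset, event$onset + event$duration, n / segment$fs))
  c(onset_sample = i0, offset_sample = i1)
}
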
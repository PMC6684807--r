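# Annotation aid: bandpass + Hilbert-envelope thresholding against baseline
# statistics of steady-state physiological activity, for candidate event
# detection (the manual-review pre-screening role).

#' Configure the envelope-threshold event detector
#'
#' The detection threshold is `mean + k_sd * SD` of the envelope over a
#' baseline interval of steady-state physiological activity. Whether the
#' original annotation aid used `mean + k*SD` or `k*SD` alone is not
#' recoverable; `mean + k*SD` is this package's documented reading.
#'
#' @param band `(low, high)` bandpass edges in Hz.
#' @param k_sd Threshold multiplier (> 0, default 3).
#' @param baseline `(start, end)` baseline interval in 0-based half-open
#'   samples; must be event-free.
#' @param min_event Minimum event length in samples (default: 10 ms at the
#'   detection-time sampling rate).
#' @param merge_gap Merge detections separated by less than this many samples
#'   (default: 10 ms).
#' @return An object of class `pdm_config`.
#' @export
pdm_config <- function(band = c(80, 600), k_sd = 3, baseline = NULL,
                       min_event = NULL, merge_gap = NULL) {
  check_that(length(band) == 2 && band[1] > 0 && band[1] < band[2],
             "`band` must be (low, high) with 0 < low < high")
  check_that(is_number(k_sd) && k_sd > 0, "`k_sd` must be > 0")
  if (!is.null(baseline))
    check_that(length(baseline) == 2 && baseline[1] >= 0 &&
                 baseline[1] < baseline[2],
               "`baseline` must be (start, end), 0-based half-open, non-empty")
  structure(list(band = band, k_sd = k_sd, baseline = baseline,
                 min_event = min_event, merge_gap = merge_gap),
            class = "pdm_config")
}

# rle-based supra-threshold runs -> 0-based half-open intervals.
runs_above <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(onset_sample = starts[keep], offset_sample = ends[keep])
}

merge_intervals <- function(iv, gap) {
  if (nrow(iv) < 2) return(iv)
  out <- iv[1, ]
  for (i in 2:nrow(iv)) {
    if (iv$onset_sample[i] - out$offset_sample[nrow(out)] < gap)
      out$offset_sample[nrow(out)] <- iv$offset_sample[i]
    else out <- rbind(out, iv[i, ])
  }
  rownames(out) <- NULL
  out
}

#' Detect candidate events by envelope thresholding
#'
#' Computes the analytic-signal envelope of the bandpass-filtered signal,
#' thresholds it at `mean + k_sd * SD` of the baseline envelope, merges
#' supra-threshold runs separated by less than `merge_gap`, and emits runs of
#' at least `min_event` samples as 0-based half-open intervals.
#'
#' @param x An [eeg_segment()] or numeric voltage series.
#' @param fs Sampling rate (taken from the segment when omitted).
#' @param cfg A [pdm_config()]. A missing `baseline` defaults to the first
#'   0.5 s; missing `min_event`/`merge_gap` default to 10 ms each.
#' @return Data frame with `onset_sample`, `offset_sample`, `kind`
#'   (`"candidate"`), compatible with the dataset CSV sidecar dialect.
#' @export
pdm_detect <- function(x, fs = NULL, cfg = pdm_config()) {
  if (inherits(x, "eeg_segment")) {
    fs <- x$fs
    x <- x$samples
  }
  check_that(is_number(fs) && fs > 0, "`fs` must be a positive number")
  check_that(inherits(cfg, "pdm_config"), "`cfg` must be a pdm_config")
  check_that(cfg$band[2] < fs / 2, "`band` upper edge must be below fs/2")
  baseline <- if (is.null(cfg$baseline)) c(0, round(0.5 * fs)) else cfg$baseline
  check_that(baseline[2] <= length(x), "`baseline` extends past the signal end")
  min_event <- if (is.null(cfg$min_event)) round(0.010 * fs) else cfg$min_event
  merge_gap <- if (is.null(cfg$merge_gap)) round(0.010 * fs) else cfg$merge_gap

  if (all(x == 0))
    return(data.frame(onset_sample = integer(0), offset_sample = integer(0),
                      kind = character(0), stringsAsFactors = FALSE))

  env <- bandpass_envelope(x, fs, low = cfg$band[1], high = cfg$band[2])
  bl <- env[(baseline[1] + 1):baseline[2]]
  thr <- mean(bl) + cfg$k_sd * stats::sd(bl)

  iv <- runs_above(env > thr)
  iv <- merge_intervals(iv, merge_gap)
  iv <- iv[iv$offset_sample - iv$onset_sample >= min_event, , drop = FALSE]
  if (nrow(iv) > 0 &&
      any(iv$onset_sample < baseline[2] & iv$offset_sample > baseline[1]))
    warning("a detection overlaps the baseline interval; ",
            "the baseline may not be event-free", call. = FALSE)
  rownames(iv) <- NULL
  iv$kind <- rep("candidate", nrow(iv))
  iv
}
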
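# Raw segments -> normalized spectrogram batches.
# Conventions (recorded in every manifest):
#   * STFT: Hann window 256, hop 128, NFFT 1024, one-sided, linear magnitude.
#   * Band truncation: DC bin discarded, the 200 lowest non-DC bins kept
#     (4.88 - 976.56 Hz at fs = 5000), matching the stated 200-band count.
#   * z-scores per frequency band, per segment, population SD.

#' Cut a continuous recording into fixed-length segments
#'
#' Non-overlapping consecutive windows of exactly `seg_len * fs` samples; any
#' trailing remainder is dropped. Event intervals given in recording
#' coordinates are clipped into each segment's local 0-based coordinates (an
#' event spanning a boundary yields one clipped interval per segment).
#'
#' @param continuous Numeric voltage series.
#' @param fs Sampling rate in Hz.
#' @param seg_len Segment length in seconds (default 3).
#' @param events Optional data frame (`onset_sample`, `offset_sample`, `kind`)
#'   in recording coordinates, 0-based half-open.
#' @param source_id Provenance string stamped on each segment.
#'
#' @return List of [eeg_segment()] objects.
#' @export
segment_signal <- function(continuous, fs, seg_len = 3,
                           events = empty_events(), source_id = "record") {
  check_that(is_number(fs) && fs > 0, "`fs` must be a positive number")
  check_that(is_number(seg_len) && seg_len > 0, "`seg_len` must be > 0")
  n_seg_samp <- round(seg_len * fs)
  check_that(length(continuous) >= n_seg_samp,
             "`continuous` is shorter than one segment")
  n_seg <- floor(length(continuous) / n_seg_samp)
  lapply(seq_len(n_seg), function(k) {
    a <- (k - 1) * n_seg_samp        # segment start, 0-based
    b <- a + n_seg_samp
    loc <- empty_events()
    if (nrow(events) > 0) {
      keep <- events$onset_sample < b & events$offset_sample > a
      if (any(keep)) {
        ev <- events[keep, , drop = FALSE]
        loc <- data.frame(onset_sample = pmax(ev$onset_sample - a, 0),
                          offset_sample = pmin(ev$offset_sample - a, n_seg_samp),
                          kind = ev$kind, stringsAsFactors = FALSE)
      }
    }
    eeg_segment(continuous[(a + 1):b], fs, events = loc,
                source_id = sprintf("%s_seg%04d", source_id, k))
  })
}

#' Short-time Fourier transform spectrogram of a segment
#'
#' Magnitude STFT with a periodic Hann window of 256 samples, 128-sample hop
#' and 1024-point FFT (one-sided), giving `floor((N - 256)/128) + 1` frames
#' and a band spacing of `fs/1024` Hz (4.883 Hz at 5 kHz). Frame k (0-based)
#' spans samples `[k*128, k*128 + 256)`; `frame_centers` records its center.
#'
#' @param segment An [eeg_segment()] (or bare numeric vector plus `fs`).
#' @param fs Sampling rate, required only when `segment` is numeric.
#' @param window,hop,nfft STFT parameters in samples.
#' @param mode `"log"` (log1p of magnitude, the package default: the linear
#'   magnitude is Rayleigh-tailed per cell and the compressed scale z-scores
#'   far more stably), `"magnitude"` or `"power"`.
#'
#' @return An object of class `eeg_spectrogram` with fields `values`
#'   (bands x frames), `band_freqs`, `frame_centers` (0-based sample indices),
#'   `window`, `hop`, `nfft`, `fs`, `normalized`.
#' @export
stft_spectrogram <- function(segment, fs = NULL, window = 256, hop = 128,
                             nfft = 1024, mode = c("log", "magnitude", "power")) {
  mode <- match.arg(mode)
  if (inherits(segment, "eeg_segment")) {
    x <- segment$samples
    fs <- segment$fs
  } else {
    check_that(is.numeric(segment) && is_number(fs),
               "`fs` is required when `segment` is a bare numeric vector")
    x <- as.numeric(segment)
  }
  check_that(length(x) >= window,
             sprintf("segment has %d samples, shorter than the %d-sample window",
                     length(x), window))
  n_frames <- floor((length(x) - window) / hop) + 1
  idx <- outer(seq_len(window), (seq_len(n_frames) - 1) * hop, "+")
  frames <- matrix(x[idx], nrow = window) * hann_window(window)
  padded <- rbind(frames, matrix(0, nfft - window, n_frames))
  spec <- stats::mvfft(padded)[seq_len(nfft / 2 + 1), , drop = FALSE]
  mag <- Mod(spec)
  values <- switch(mode, magnitude = mag, power = mag^2, log = log1p(mag))
  structure(list(values = values,
                 band_freqs = (0:(nfft / 2)) * fs / nfft,
                 frame_centers = (seq_len(n_frames) - 1) * hop + window / 2,
                 window = window, hop = hop, nfft = nfft, fs = fs,
                 normalized = FALSE, mode = mode),
            class = "eeg_spectrogram")
}

#' @export
print.eeg_spectrogram <- function(x, ...) {
  cat(sprintf("<eeg_spectrogram> %d bands x %d frames, %.4g-%.4g Hz, %s%s\n",
              nrow(x$values), ncol(x$values), min(x$band_freqs),
              max(x$band_freqs), x$mode,
              if (x$normalized) ", z-scored" else ""))
  invisible(x)
}

#' Discard the DC bin and all bands above the retained count
#'
#' Keeps exactly `n_bands` bins: the lowest non-DC frequencies (bins 1..200 of
#' the one-sided FFT, i.e. about 4.88-976.6 Hz at 5 kHz / NFFT 1024), so that
#' everything at and above roughly 1 kHz is discarded. Idempotent: an already
#' truncated spectrogram is returned unchanged.
#'
#' @param spec An `eeg_spectrogram`.
#' @param n_bands Number of bands to keep (default 200).
#' @return The truncated `eeg_spectrogram`.
#' @export
truncate_bands <- function(spec, n_bands = 200) {
  check_that(inherits(spec, "eeg_spectrogram"), "`spec` must be an eeg_spectrogram")
  if (nrow(spec$values) == n_bands && spec$band_freqs[1] > 0) return(spec)
  check_that(nrow(spec$values) >= n_bands + 1,
             sprintf("`spec` has %d bins; need at least %d to truncate",
                     nrow(spec$values), n_bands + 1))
  keep <- 2:(n_bands + 1)
  spec$values <- spec$values[keep, , drop = FALSE]
  spec$band_freqs <- spec$band_freqs[keep]
  spec
}

#' z-score each frequency band across frames
#'
#' Centers and scales every band row to mean 0, SD 1 (population SD) using the
#' segment's own frames, so inference works on a single unseen segment.
#' Constant rows (SD below `eps`) map to all zeros.
#'
#' @param spec An `eeg_spectrogram` with at least 2 frames.
#' @param eps Guard for constant rows.
#' @return The normalized `eeg_spectrogram` (`normalized = TRUE`).
#' @export
zscore_bands <- function(spec, eps = 1e-12) {
  check_that(inherits(spec, "eeg_spectrogram"), "`spec` must be an eeg_spectrogram")
  check_that(ncol(spec$values) >= 2, "`spec` must have at least 2 frames")
  v <- spec$values
  mu <- rowMeans(v)
  sd_pop <- sqrt(pmax(rowMeans(v^2) - mu^2, 0))
  z <- (v - mu) / ifelse(sd_pop < eps, Inf, sd_pop)   # constant rows -> 0
  spec$values <- z
  spec$normalized <- TRUE
  spec
}

#' Full preprocessing of one segment
#'
#' Convenience chain: [stft_spectrogram()], [truncate_bands()],
#' [zscore_bands()]. A standard 15000-sample, 5 kHz segment yields a
#' normalized 200 x 116 spectrogram.
#'
#' @inheritParams stft_spectrogram
#' @param n_bands Bands kept after truncation.
#' @return A normalized `eeg_spectrogram`.
#' @export
preprocess_segment <- function(segment, n_bands = 200, window = 256, hop = 128,
                               nfft = 1024, mode = "log") {
  zscore_bands(truncate_bands(
    stft_spectrogram(segment, window = window, hop = hop, nfft = nfft,
                     mode = mode),
    n_bands = n_bands))
}

#' Stack spectrograms into a 4-axis mini-batch tensor
#'
#' @param specs List of normalized `eeg_spectrogram`s of identical shape.
#' @param labels Optional labels (character or factor over [ieeg_classes()]).
#' @param ids Optional segment identifiers.
#' @return An object of class `spectrogram_batch` with `values` of shape
#'   `(n, 1, bands, frames)`, plus `labels`, `ids`, `fs`.
#' @export
batch_spectrograms <- function(specs, labels = NULL, ids = NULL) {
  check_that(is.list(specs) && length(specs) > 0, "`specs` must be a non-empty list")
  check_that(all(vapply(specs, inherits, TRUE, "eeg_spectrogram")),
             "`specs` must all be eeg_spectrogram objects")
  shp <- vapply(specs, function(s) dim(s$values), integer(2))
  check_that(all(shp[1, ] == shp[1, 1]) && all(shp[2, ] == shp[2, 1]),
             "`specs` must share one shape")
  norm <- vapply(specs, function(s) s$normalized, TRUE)
  check_that(all(norm) || all(!norm),
             "`specs` mix normalized and unnormalized spectrograms")
  n <- length(specs)
  values <- array(0, dim = c(n, 1, shp[1, 1], shp[2, 1]))
  for (i in seq_len(n)) values[i, 1, , ] <- specs[[i]]$values
  if (!is.null(labels)) {
    check_that(length(labels) == n, "`labels` length must match `specs`")
    labels <- factor(as.character(labels), levels = ieeg_classes())
  }
  if (is.null(ids)) ids <- sprintf("seg%04d", seq_len(n))
  structure(list(values = values, labels = labels, ids = ids,
                 fs = specs[[1]]$fs, normalized = norm[1]),
            class = "spectrogram_batch")
}

#' Preprocess a whole dataset into a batch
#'
#' @param dataset List of [eeg_segment()] objects.
#' @param ... Passed to [preprocess_segment()].
#' @return A `spectrogram_batch` carrying the dataset's labels and ids.
#' @export
preprocess_dataset <- function(dataset, ...) {
  specs <- lapply(dataset, preprocess_segment, ...)
  batch_spectrograms(specs,
                     labels = vapply(dataset, function(s) s$label, ""),
                     ids = vapply(dataset, function(s) s$source_id, ""))
}
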
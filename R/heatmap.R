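# Classification heatmaps: per-sample probability traces aligned to the raw
# segment, final-timestamp labeling, transition localization, and the
# 200-600 Hz envelope display trace.

#' Upsample frame probabilities to per-sample resolution
#'
#' Zero-order-hold expansion: frame k (0-based) covers samples
#' `[k*hop, k*hop + hop)`; the final frame is extended to the segment end and
#' the first frame back-fills to sample 0. Because frame k's window only
#' closes at sample `k*hop + window`, the heatmap shows decisions
#' `window` (= 256) samples ahead of the data that completes them — the
#' documented decision lead. Rows remain exact softmax outputs. A `"linear"`
#' mode interpolates between frame anchors and renormalizes rows.
#'
#' @param fp A `frames x n_classes` probability matrix ([infer_many_to_many()]).
#' @param n_samples Raw segment length (15000 for standard segments).
#' @param fs Sampling rate in Hz.
#' @param hop,window STFT hop and window in samples.
#' @param method `"zoh"` (default) or `"linear"`.
#' @return Object of class `prob_heatmap`: `probs` (`n_samples x n_classes`),
#'   `fs`, `lead_samples` (= `window`), `hop`.
#' @export
upsample_heatmap <- function(fp, n_samples, fs, hop = 128, window = 256,
                             method = c("zoh", "linear")) {
  method <- match.arg(method)
  fp <- as.matrix(fp)
  check_that(nrow(fp) >= 1 && ncol(fp) >= 2, "`fp` must be a frames x classes matrix")
  check_that(is_count(n_samples) && n_samples >= nrow(fp),
             "`n_samples` must be at least the frame count")
  T_f <- nrow(fp)
  if (method == "zoh") {
    k <- pmin(floor((seq_len(n_samples) - 1) / hop), T_f - 1) + 1
    probs <- fp[k, , drop = FALSE]
  } else {
    anchors <- pmin((seq_len(T_f) - 1) * hop, n_samples - 1)
    s <- seq_len(n_samples) - 1
    probs <- apply(fp, 2, function(col)
      stats::approx(anchors, col, xout = s, rule = 2)$y)
    probs <- probs / rowSums(probs)
  }
  dimnames(probs) <- list(NULL, colnames(fp))
  structure(list(probs = probs, fs = fs, lead_samples = window, hop = hop),
            class = "prob_heatmap")
}

#' @export
print.prob_heatmap <- function(x, ...) {
  cat(sprintf("<prob_heatmap> %d samples x %d classes @ %g Hz (lead %d samples)\n",
              nrow(x$probs), ncol(x$probs), x$fs, x$lead_samples))
  invisible(x)
}

# argmax with ties broken toward the earlier (canonical-order) class.
argmax_rows <- function(p) max.col(p, ties.method = "first")

#' Final-timestamp classification of a heatmap
#'
#' The label is the argmax of the LAST sample's probability row; ties break
#' toward the earlier class in canonical order. A segment whose heatmap ends
#' in the artifact state despite an earlier pathological excursion is labeled
#' artifact.
#'
#' @param hm A `prob_heatmap` (or bare probability matrix).
#' @return List with `label` (character) and `final_probs` (named numeric).
#' @export
classify_segment <- function(hm) {
  p <- if (inherits(hm, "prob_heatmap")) hm$probs else as.matrix(hm)
  last <- p[nrow(p), ]
  cls <- colnames(p)
  if (is.null(cls)) cls <- ieeg_classes()[seq_along(last)]
  list(label = cls[which.max(last)], final_probs = stats::setNames(last, cls))
}

#' Locate class-state transitions in a heatmap
#'
#' Computes the per-sample argmax state sequence, merges runs shorter than
#' `min_dwell` into the preceding state (a leading short run merges forward),
#' and reports the boundaries of the surviving runs in temporal order.
#'
#' @param hm A `prob_heatmap` (or probability matrix).
#' @param min_dwell Minimum run length in samples (default 640 = 128 ms at
#'   5 kHz, five STFT hops) to suppress flicker.
#' @return Data frame with `sample` (0-based index of the first sample of the
#'   new state), `from_class`, `to_class`, `dwell` (length of the new run).
#' @export
locate_transitions <- function(hm, min_dwell = 640) {
  check_that(is_count(min_dwell) && min_dwell >= 1, "`min_dwell` must be >= 1")
  p <- if (inherits(hm, "prob_heatmap")) hm$probs else as.matrix(hm)
  cls <- colnames(p)
  if (is.null(cls)) cls <- ieeg_classes()[seq_len(ncol(p))]
  s <- argmax_rows(p)
  r <- rle(s)
  out_v <- integer(0); out_l <- integer(0)
  pending <- 0L
  for (i in seq_along(r$values)) {
    if (r$lengths[i] < min_dwell) {
      if (length(out_v)) out_l[length(out_l)] <- out_l[length(out_l)] + r$lengths[i]
      else pending <- pending + r$lengths[i]
    } else if (length(out_v) && out_v[length(out_v)] == r$values[i]) {
      out_l[length(out_l)] <- out_l[length(out_l)] + r$lengths[i] + pending
      pending <- 0L
    } else {
      out_v <- c(out_v, r$values[i])
      out_l <- c(out_l, r$lengths[i] + pending)
      pending <- 0L
    }
  }
  if (!length(out_v)) {                 # every run shorter than min_dwell
    out_v <- s[length(s)]
    out_l <- length(s)
  }
  if (length(out_v) < 2)
    return(data.frame(sample = integer(0), from_class = character(0),
                      to_class = character(0), dwell = integer(0),
                      stringsAsFactors = FALSE))
  starts <- cumsum(out_l)
  data.frame(sample = starts[-length(starts)],
             from_class = cls[out_v[-length(out_v)]],
             to_class = cls[out_v[-1]],
             dwell = out_l[-1],
             stringsAsFactors = FALSE)
}

# FFT-based analytic signal; magnitude is the instantaneous envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Zero-phase bandpass envelope of a raw trace
#'
#' FIR bandpass (Hamming-windowed, order `order`, >= 40 dB stopband after the
#' forward-backward pass) applied with `signal::filtfilt` for zero phase,
#' followed by the analytic-signal magnitude. The 200-600 Hz default
#' highlights HFO and muscle-artifact content for the display panel under the
#' raw trace.
#'
#' @param x An [eeg_segment()] or numeric vector.
#' @param fs Sampling rate (taken from the segment when omitted).
#' @param low,high Band edges in Hz (`0 < low < high < fs/2`).
#' @param order FIR order.
#' @return Numeric envelope, same length as the input.
#' @export
bandpass_envelope <- function(x, fs = NULL, low = 200, high = 600, order = 256) {
  if (inherits(x, "eeg_segment")) {
    fs <- x$fs
    x <- x$samples
  }
  check_that(is_number(fs) && fs > 0, "`fs` must be a positive number")
  check_that(is_number(low) && is_number(high) && low > 0 && low < high,
             "`low`/`high` must satisfy 0 < low < high")
  check_that(high < fs / 2, "`high` must be below the Nyquist frequency fs/2")
  if (all(x == 0)) return(numeric(length(x)))
  b <- as.numeric(signal::fir1(order, c(low, high) / (fs / 2), type = "pass"))
  y <- signal::filtfilt(b, 1, x)
  Mod(analytic_signal(y))
}

#' Heatmap of one raw segment through a trained model
#'
#' Preprocess, infer, upsample: the full inference path for a single segment.
#'
#' @param model A trained `conv_lstm`.
#' @param segment An [eeg_segment()].
#' @param seed Optional seed for the LSTM state draw.
#' @return A `prob_heatmap` with as many rows as the segment has samples.
#' @export
segment_heatmap <- function(model, segment, seed = NULL) {
  spec <- preprocess_segment(segment)
  batch <- batch_spectrograms(list(spec))
  fp <- infer_many_to_many(model, batch, seed = seed)[[1]]
  upsample_heatmap(fp, n_samples = length(segment$samples), fs = segment$fs)
}

#' Three-panel display: raw trace, 200-600 Hz envelope, heatmap
#'
#' @param segment An [eeg_segment()].
#' @param hm Its `prob_heatmap`.
#' @param file Optional PNG path; when given the figure is written there.
#' @return Invisibly, `file` (or NULL when plotting to the active device).
#' @export
plot_heatmap_panels <- function(segment, hm, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 800, res = 120)
    on.exit(grDevices::dev.off())
  }
  t <- (seq_along(segment$samples) - 1) / segment$fs
  old <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(old), add = TRUE)
  graphics::plot(t, segment$samples, type = "l", xlab = "", ylab = "iEEG (SD units)",
                 main = sprintf("segment %s (%s)", segment$source_id, segment$label))
  graphics::plot(t, bandpass_envelope(segment), type = "l", xlab = "",
                 ylab = "200-600 Hz envelope")
  cols <- c(physiological = "blue", pathological = "red", artifact = "darkgreen")
  ltys <- c(physiological = 1, pathological = 2, artifact = 3)
  graphics::matplot(t, hm$probs, type = "l", lty = ltys, col = cols,
                    xlab = "time (s)", ylab = "probability", ylim = c(0, 1))
  graphics::legend("topright", legend = colnames(hm$probs),
                   col = cols[colnames(hm$probs)], lty = ltys[colnames(hm$probs)],
                   cex = 0.8, bg = "white")
  invisible(file)
}
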
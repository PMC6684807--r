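# Synthetic iEEG generation: awake background (pink noise + beta rhythm),
# interictal spike + HFO, muscle artifact bursts, powerline interference.
# All waveform parameters are in background-SD units and seconds; ground-truth
# event intervals are recorded exactly.

# Frequency-domain noise synthesis. `amp` gives the spectral amplitude for
# positive-frequency bins k = 1..floor(n/2) (cycles per record); phases are
# drawn from the current RNG stream. Output is scaled to unit SD.
synth_noise <- function(n, amp) {
  stopifnot(length(amp) == n %/% 2)
  m <- (n - 1) %/% 2                     # strictly positive, non-Nyquist bins
  X <- complex(length.out = n)
  ph <- stats::runif(m, 0, 2 * pi)
  X[1 + seq_len(m)] <- complex(modulus = amp[seq_len(m)], argument = ph)
  if (n %% 2 == 0)                        # Nyquist bin must be real
    X[n / 2 + 1] <- amp[n / 2] * sign(stats::runif(1) - 0.5)
  X[n + 1 - seq_len(m)] <- Conj(X[1 + seq_len(m)])
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# 1/f^exponent power spectral density ("pink" at exponent 1), unit SD.
pink_noise <- function(n, exponent = 1) {
  k <- seq_len(n %/% 2)
  synth_noise(n, k^(-exponent / 2))
}

# Flat-spectrum noise restricted to [f_lo, f_hi] Hz, unit SD.
band_noise <- function(n, fs, f_lo, f_hi) {
  k <- seq_len(n %/% 2)
  f <- k * fs / n
  amp <- as.numeric(f >= f_lo & f <= f_hi)
  check_that(any(amp > 0), "`band` contains no frequency bin at this length")
  synth_noise(n, amp)
}

#' Generate physiological awake iEEG background
#'
#' Pink (1/f) noise plus a beta-band (13-30 Hz) oscillatory component whose
#' share of total variance is `beta_power`, emulating awake resting iEEG with
#' dominant beta activity. The result is normalized to SD = 1 so that event
#' amplitudes can be expressed as multiples of the background SD.
#'
#' @param duration Segment duration in seconds (> 0).
#' @param fs Sampling rate in Hz (>= 2000).
#' @param beta_power Fraction of total variance carried by the 13-30 Hz
#'   component, in `[0, 1]`.
#' @param seed Optional integer; if given the segment is a deterministic
#'   function of the arguments.
#' @param pink_exponent Spectral slope of the background (PSD proportional to
#'   `1/f^pink_exponent`).
#'
#' @return An [eeg_segment()] labeled `"physiological"` with no events.
#' @export
make_background <- function(duration, fs, beta_power = 0.3, seed = NULL,
                            pink_exponent = 1) {
  check_that(is_number(duration) && duration > 0, "`duration` must be > 0")
  check_that(is_number(fs) && fs >= 2000, "`fs` must be >= 2000 Hz")
  check_that(is_number(beta_power) && beta_power >= 0 && beta_power <= 1,
             "`beta_power` must lie in [0, 1]")
  n <- round(duration * fs)
  # One joint spectral synthesis: pink amplitudes outside 13-30 Hz, in-band
  # amplitudes rescaled so the band's share of total power equals beta_power
  # exactly (deterministic amplitudes, random phases).
  k <- seq_len(n %/% 2)
  f <- k * fs / n
  amp <- k^(-pink_exponent / 2)
  inb <- f >= 13 & f <= 30
  if (beta_power >= 1) {
    amp[!inb] <- 0
  } else {
    p_out <- sum(amp[!inb]^2)
    p_in <- sum(amp[inb]^2)
    amp[inb] <- amp[inb] * sqrt(beta_power / (1 - beta_power) * p_out / p_in)
  }
  x <- with_seed(seed, synth_noise(n, amp))
  x <- x / stats::sd(x)
  eeg_segment(x, fs, label = "physiological", source_id = "synthetic")
}

# Hann window (periodic convention), also used by the STFT.
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' Inject an interictal epileptiform spike with a superimposed HFO
#'
#' Adds a biphasic spike transient (derivative-of-Gaussian waveform whose main
#' deflection spans one third of the event duration) plus an amplitude-modulated
#' (Hann-windowed) sinusoidal burst at `hfo_freq` riding on the spike. The
#' event interval is recorded and the segment is relabeled `"pathological"`.
#' An amplitude of 0 returns the segment unchanged.
#'
#' @param segment An [eeg_segment()].
#' @param event An [event_spec()] with `kind = "spike_hfo"`.
#' @param hfo_rel_amp HFO burst amplitude relative to the spike amplitude.
#'
#' @return The modified [eeg_segment()].
#' @export
inject_spike_hfo <- function(segment, event, hfo_rel_amp = 0.4) {
  check_that(inherits(segment, "eeg_segment"), "`segment` must be an eeg_segment")
  check_that(inherits(event, "event_spec") && event$kind == "spike_hfo",
             "`event` must be an event_spec of kind spike_hfo")
  if (event$amplitude == 0) return(segment)
  iv <- event_interval(event, segment)
  fs <- segment$fs
  idx <- (iv[1] + 1):iv[2]                       # 1-based sample indices
  t <- (idx - 1) / fs
  tc <- event$onset + event$duration / 2
  sigma <- event$duration / 6                    # support ~ 6 sigma
  z <- (t - tc) / sigma
  spike <- -event$amplitude * z * exp(-z^2 / 2) / exp(-0.5)  # peak = amplitude

  burst_len <- max(8L, round(length(idx) / 2))   # HFO centered on the spike
  b0 <- round((length(idx) - burst_len) / 2)
  bidx <- seq_len(burst_len) + b0
  hfo <- numeric(length(idx))
  hfo[bidx] <- hfo_rel_amp * event$amplitude * hann_window(burst_len) *
    sin(2 * pi * event$hfo_freq * (t[bidx] - tc))

  segment$samples[idx] <- segment$samples[idx] + spike + hfo
  segment$events <- rbind(segment$events,
                          data.frame(onset_sample = unname(iv[1]),
                                     offset_sample = unname(iv[2]),
                                     kind = "spike_hfo"))
  segment$label <- "pathological"
  segment
}

#' Inject a muscle or powerline artifact
#'
#' Muscle (chewing) artifact: a broadband noise burst with its energy above
#' 100 Hz and raised-cosine on/off ramps. Powerline: a sustained sinusoid at
#' `line_freq` plus odd harmonics (relative amplitudes 0.2 and 0.05). The
#' event interval is recorded and the segment relabeled `"artifact"`.
#' An amplitude of 0 returns the segment unchanged.
#'
#' @param segment An [eeg_segment()].
#' @param event An [event_spec()] of kind `"muscle_artifact"` or `"powerline"`.
#' @param seed Optional seed for the muscle noise realization and powerline
#'   phase (deterministic injection when supplied).
#' @param muscle_band Frequency support of the muscle burst, Hz.
#'
#' @return The modified [eeg_segment()].
#' @export
inject_artifact <- function(segment, event, seed = NULL,
                            muscle_band = c(100, 1500)) {
  check_that(inherits(segment, "eeg_segment"), "`segment` must be an eeg_segment")
  check_that(inherits(event, "event_spec") &&
               event$kind %in% c("muscle_artifact", "powerline"),
             "`event` kind must be muscle_artifact or powerline")
  if (event$amplitude == 0) return(segment)
  iv <- event_interval(event, segment)
  fs <- segment$fs
  idx <- (iv[1] + 1):iv[2]
  len <- length(idx)

  wave <- with_seed(seed, {
    if (event$kind == "muscle_artifact") {
      hi <- min(muscle_band[2], 0.45 * fs)
      burst <- band_noise(len, fs, muscle_band[1], hi) * event$amplitude
      burst * tukey_ramp(len, 0.2)
    } else {
      phase <- stats::runif(3, 0, 2 * pi)
      h <- c(1, 0.2, 0.05)
      freqs <- event$line_freq * c(1, 3, 5)
      keep <- freqs < fs / 2
      t <- (idx - 1) / fs
      w <- numeric(len)
      for (j in which(keep))
        w <- w + h[j] * sin(2 * pi * freqs[j] * t + phase[j])
      event$amplitude * w
    }
  })

  segment$samples[idx] <- segment$samples[idx] + wave
  segment$events <- rbind(segment$events,
                          data.frame(onset_sample = unname(iv[1]),
                                     offset_sample = unname(iv[2]),
                                     kind = event$kind))
  segment$label <- "artifact"
  segment
}

# Tukey (cosine-tapered) window: flat top with raised-cosine ramps covering a
# fraction `alpha` of the length at each end combined.
tukey_ramp <- function(n, alpha = 0.2) {
  w <- rep(1, n)
  ramp <- max(1L, floor(alpha * n / 2))
  up <- 0.5 * (1 - cos(pi * (seq_len(ramp) - 1) / ramp))
  w[seq_len(ramp)] <- up
  w[n + 1 - seq_len(ramp)] <- rev(up)
  w
}

#' Largest-remainder apportionment of a total into class counts
#'
#' Rounds `total * ratios / sum(ratios)` to integers summing exactly to
#' `total`, assigning leftover units to the largest fractional remainders.
#'
#' @param total Positive integer total.
#' @param ratios Non-negative weights, one per class.
#' @return Integer vector of counts summing to `total`.
#' @export
ratio_counts <- function(total, ratios) {
  check_that(is_count(total) && total > 0, "`total` must be a positive integer")
  check_that(is.numeric(ratios) && all(ratios >= 0) && sum(ratios) > 0,
             "`ratios` must be non-negative with a positive sum")
  quota <- total * ratios / sum(ratios)
  counts <- floor(quota)
  left <- total - sum(counts)
  if (left > 0) {
    take <- order(quota - counts, decreasing = TRUE)[seq_len(left)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

#' Describe a synthetic iEEG dataset
#'
#' Parameter ranges below are drawn uniformly per segment. Amplitudes are in
#' background-SD units, durations/onsets in seconds, frequencies in Hz.
#'
#' @param n_per_class Named or ordered integer vector of segment counts for
#'   (physiological, pathological, artifact). Alternatively give `total` and
#'   `class_ratios`.
#' @param total,class_ratios Total segment count and class weights, apportioned
#'   by [ratio_counts()]; used when `n_per_class` is missing.
#' @param fs Sampling rate (default 5000 Hz).
#' @param segment_len Segment length in seconds (default 3).
#' @param beta_range Background beta variance fraction range.
#' @param spike_amp,spike_dur,hfo_freq_range Pathological event ranges.
#' @param muscle_amp,muscle_dur,powerline_amp,powerline_dur,line_freq Artifact
#'   event parameters.
#' @param p_mixed Fraction of artifact segments that also contain an earlier
#'   pathological event (mixed-class segments; the label follows the LAST
#'   event in time, matching final-timestamp classification).
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   full specification.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = NULL, total = NULL, class_ratios = NULL,
                           fs = 5000, segment_len = 3,
                           beta_range = c(0.15, 0.45),
                           spike_amp = c(4, 8), spike_dur = c(0.1, 0.2),
                           hfo_freq_range = c(120, 400),
                           muscle_amp = c(3, 6), muscle_dur = c(0.5, 1.5),
                           powerline_amp = c(2, 5), powerline_dur = c(1, 2.5),
                           line_freq = 50, p_mixed = 0, seed = 1) {
  if (is.null(n_per_class)) {
    check_that(!is.null(total) && !is.null(class_ratios),
               "give either `n_per_class` or both `total` and `class_ratios`")
    n_per_class <- ratio_counts(total, class_ratios)
  }
  check_that(length(n_per_class) == 3 && all(n_per_class >= 0) &&
               sum(n_per_class) > 0,
             "`n_per_class` must be 3 non-negative counts with a positive sum")
  check_that(is_number(fs) && fs > 2 * max(hfo_freq_range[2], 1500),
             "`fs` must exceed twice the highest synthesized frequency")
  check_that(is_number(p_mixed) && p_mixed >= 0 && p_mixed <= 1,
             "`p_mixed` must lie in [0, 1]")
  for (rg in list(beta_range, spike_amp, spike_dur, hfo_freq_range, muscle_amp,
                  muscle_dur, powerline_amp, powerline_dur))
    check_that(length(rg) == 2 && rg[1] <= rg[2], "parameter ranges must be (lo, hi)")
  n_per_class <- as.integer(n_per_class)
  names(n_per_class) <- ieeg_classes()
  structure(list(n_per_class = n_per_class, fs = fs, segment_len = segment_len,
                 beta_range = beta_range, spike_amp = spike_amp,
                 spike_dur = spike_dur, hfo_freq_range = hfo_freq_range,
                 muscle_amp = muscle_amp, muscle_dur = muscle_dur,
                 powerline_amp = powerline_amp, powerline_dur = powerline_dur,
                 line_freq = line_freq, p_mixed = p_mixed, seed = seed),
            class = "synthetic_spec")
}

runif1 <- function(rg) stats::runif(1, rg[1], rg[2])

# One pathological event spec drawn from the ranges, fitting the segment.
draw_spike_event <- function(spec) {
  dur <- runif1(spec$spike_dur)
  onset <- stats::runif(1, 0.25, spec$segment_len - 0.25 - dur)
  event_spec("spike_hfo", onset = onset, duration = dur,
             amplitude = runif1(spec$spike_amp),
             hfo_freq = runif1(spec$hfo_freq_range))
}

draw_artifact_event <- function(spec, kind) {
  if (kind == "muscle_artifact") {
    dur <- runif1(spec$muscle_dur)
    amp <- runif1(spec$muscle_amp)
  } else {
    dur <- runif1(spec$powerline_dur)
    amp <- runif1(spec$powerline_amp)
  }
  onset <- stats::runif(1, 0.1, spec$segment_len - 0.1 - dur)
  event_spec(kind, onset = onset, duration = dur, amplitude = amp,
             line_freq = if (kind == "powerline") spec$line_freq else NULL)
}

#' Generate a labeled synthetic iEEG dataset
#'
#' Produces the per-class segment counts of `spec`, shuffled, with exact
#' ground-truth event intervals. Every pathological or artifact segment
#' contains at least one recorded event; physiological segments contain none.
#' With `p_mixed > 0`, that fraction of artifact segments also contains an
#' earlier spike+HFO; the label follows the last event in time.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of [eeg_segment()] objects (class `eeg_dataset`) with the
#'   generating spec attached as attribute `"spec"`.
#' @export
generate_dataset <- function(spec) {
  check_that(inherits(spec, "synthetic_spec"), "`spec` must be a synthetic_spec")
  n <- spec$n_per_class
  segs <- with_seed(spec$seed, {
    out <- vector("list", sum(n))
    i <- 0
    mk_bg <- function() make_background(spec$segment_len, spec$fs,
                                        beta_power = runif1(spec$beta_range))
    for (j in seq_len(n[["physiological"]])) {
      i <- i + 1
      out[[i]] <- mk_bg()
    }
    for (j in seq_len(n[["pathological"]])) {
      i <- i + 1
      out[[i]] <- inject_spike_hfo(mk_bg(), draw_spike_event(spec))
    }
    for (j in seq_len(n[["artifact"]])) {
      i <- i + 1
      kind <- if (stats::runif(1) < 0.5) "muscle_artifact" else "powerline"
      seg <- mk_bg()
      mixed <- spec$p_mixed > 0 && stats::runif(1) < spec$p_mixed
      art <- draw_artifact_event(spec, kind)
      if (mixed) {
        # pathological event strictly before the artifact: label follows the
        # last event, so the segment stays "artifact"
        sp_dur <- runif1(spec$spike_dur)
        if (art$onset - 0.3 > sp_dur) {
          sp_on <- stats::runif(1, 0.1, art$onset - 0.1 - sp_dur)
          sp <- event_spec("spike_hfo", onset = sp_on, duration = sp_dur,
                           amplitude = runif1(spec$spike_amp),
                           hfo_freq = runif1(spec$hfo_freq_range))
          seg <- inject_spike_hfo(seg, sp)
        }
      }
      out[[i]] <- inject_artifact(seg, art)
    }
    out[sample(length(out))]
  })
  for (i in seq_along(segs)) segs[[i]]$source_id <- sprintf("synthetic_%04d", i)
  structure(segs, class = "eeg_dataset", spec = spec)
}

#' @export
print.eeg_dataset <- function(x, ...) {
  labs <- vapply(x, function(s) s$label, "")
  cat(sprintf("<eeg_dataset> %d segments: %s\n", length(x),
              paste(sprintf("%s=%d", ieeg_classes(),
                            tabulate(match(labs, ieeg_classes()), 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Extract segment labels
#' @param dataset A list of [eeg_segment()] objects.
#' @return Factor of labels with levels [ieeg_classes()].
#' @export
dataset_labels <- function(dataset) {
  factor(vapply(dataset, function(s) s$label, ""), levels = ieeg_classes())
}
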
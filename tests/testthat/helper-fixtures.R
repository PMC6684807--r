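# Shared in-code fixtures. Everything is generated at test time; seeds are
# fixed so expected values frozen in the tests are reproducible.

# Least-squares log-log PSD slope over [f_lo, f_hi], with octave-binned
# averaging of the periodogram to stabilize the fit.
psd_slope <- function(x, fs, f_lo = 1, f_hi = 500) {
  n <- length(x)
  spec <- Mod(stats::fft(x))[2:(n %/% 2)]^2
  f <- (1:(n %/% 2 - 1)) * fs / n
  keep <- f >= f_lo & f <= f_hi
  f <- f[keep]; spec <- spec[keep]
  bins <- cut(log2(f), breaks = seq(log2(f_lo), log2(f_hi), by = 0.25),
              include.lowest = TRUE)
  pf <- tapply(f, bins, mean)
  ps <- tapply(spec, bins, mean)
  ok <- !is.na(pf) & !is.na(ps) & ps > 0
  unname(stats::coef(stats::lm(log10(ps[ok]) ~ log10(pf[ok])))[2])
}

# Fraction of total periodogram power inside [f_lo, f_hi].
band_fraction <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  spec <- Mod(stats::fft(x))[2:(n %/% 2)]^2
  f <- (1:(n %/% 2 - 1)) * fs / n
  sum(spec[f >= f_lo & f <= f_hi]) / sum(spec)
}

hann_window_test <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

# A small labeled segment set for pipeline tests (not the A3 conditions).
toy_dataset <- function(n_per_class = c(5, 5, 5), seed = 77)
  generate_dataset(synthetic_spec(n_per_class = n_per_class, seed = seed))

# Reduced model trained once and cached across test files (used by the
# end-to-end recovery and localization acceptance checks).
trained_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      train_ds <- generate_dataset(synthetic_spec(n_per_class = c(80, 80, 80),
                                                  seed = 101))
      test_ds <- generate_dataset(synthetic_spec(n_per_class = c(20, 20, 20),
                                                 seed = 202))
      model <- build_model(model_spec(n_filters = 32, lstm_hidden = 16),
                           seed = 1)
      model <- train_many_to_one(model,
                                 preprocess_dataset(train_ds),
                                 desk_train_spec(seed = 2))
      cache <<- list(model = model, test_ds = test_ds,
                     test_batch = preprocess_dataset(test_ds))
    }
    cache
  }
})
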
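# Synthetic iEEG generator: spectral contracts, event injection, dataset
# assembly.

test_that("background segments have the documented length, scale and determinism", {
  seg <- make_background(3, 5000, beta_power = 0.3, seed = 42)
  expect_s3_class(seg, "eeg_segment")
  expect_length(seg$samples, 15000)
  expect_equal(sd(seg$samples), 1, tolerance = 1e-12)
  expect_identical(seg$label, "physiological")
  expect_identical(nrow(seg$events), 0L)

  again <- make_background(3, 5000, beta_power = 0.3, seed = 42)
  expect_identical(seg$samples, again$samples)

  expect_error(make_background(-1, 5000), "duration")
  expect_error(make_background(3, 100), "fs")
  expect_error(make_background(3, 5000, beta_power = 1.5), "beta_power")
})

test_that("pure background is pink: log-log PSD slope about -1 over 1-500 Hz", {
  slopes <- vapply(1:5, function(s)
    psd_slope(make_background(3, 5000, beta_power = 0, seed = s)$samples, 5000),
    0)
  expect_true(all(abs(slopes + 1) < 0.3))
})

test_that("beta_power sets the 13-30 Hz variance fraction", {
  for (bp in c(0.2, 0.5)) {
    fr <- vapply(1:4, function(s)
      band_fraction(make_background(3, 5000, beta_power = bp, seed = s)$samples,
                    5000, 13, 30), 0)
    expect_equal(fr, rep(bp, 4), tolerance = 0.02)
  }
})

test_that("spike+HFO injection records the interval, relabels, and peaks the HF envelope", {
  seg <- make_background(3, 5000, seed = 7)
  ev <- event_spec("spike_hfo", onset = 1.2, duration = 0.15, amplitude = 6,
                   hfo_freq = 250)
  out <- inject_spike_hfo(seg, ev)
  expect_identical(out$label, "pathological")
  expect_identical(out$events$onset_sample, 6000)          # 1.2 s * 5000 Hz
  expect_identical(out$events$offset_sample, 6750)

  # the spike deflection reaches >= 3x the background SD (= 1)
  delta <- out$samples - seg$samples
  expect_gte(max(abs(delta)), 3)

  # 200-600 Hz envelope peaks inside the event interval
  env <- bandpass_envelope(out)
  expect_true(which.max(env) >= 6000 && which.max(env) <= 6750)
})

test_that("zero-amplitude events are exact no-ops", {
  seg <- make_background(3, 5000, seed = 3)
  z1 <- inject_spike_hfo(seg, event_spec("spike_hfo", 1, 0.1, 0, hfo_freq = 200))
  z2 <- inject_artifact(seg, event_spec("muscle_artifact", 1, 0.5, 0))
  z3 <- inject_artifact(seg, event_spec("powerline", 0.5, 2, 0, line_freq = 50))
  expect_identical(z1, seg)
  expect_identical(z2, seg)
  expect_identical(z3, seg)
})

test_that("events outside the segment bounds are rejected", {
  seg <- make_background(3, 5000, seed = 3)
  expect_error(inject_spike_hfo(
    seg, event_spec("spike_hfo", 2.95, 0.2, 5, hfo_freq = 200)), "outside")
  expect_error(inject_artifact(
    seg, event_spec("muscle_artifact", -0.5, 0.2, 5)), "onset")
})

test_that("powerline injection puts a dominant periodogram peak at the line frequency", {
  seg <- make_background(3, 5000, seed = 11)
  out <- inject_artifact(seg, event_spec("powerline", 0, 3, 3, line_freq = 50),
                         seed = 1)
  expect_identical(out$label, "artifact")
  x <- out$samples * hann_window_test(length(out$samples))
  p <- Mod(fft(x))[2:7500]^2
  f <- (1:7499) * 5000 / 15000
  peak <- p[which.min(abs(f - 50))]
  neighbors <- p[(f > 40 & f < 48) | (f > 52 & f < 60)]
  expect_gte(10 * log10(peak / max(neighbors)), 20)
})

test_that("muscle burst energy is broadband, above 100 Hz, and localized", {
  seg <- make_background(3, 5000, seed = 13)
  out <- inject_artifact(seg, event_spec("muscle_artifact", 0.5, 1.0, 5),
                         seed = 2)
  expect_identical(out$label, "artifact")
  burst <- out$samples - seg$samples
  expect_gte(band_fraction(burst[burst != 0], 5000, 100, 2400), 0.95)

  env2 <- bandpass_envelope(out)^2
  inside <- sum(env2[2501:7500]) / sum(env2)
  expect_gte(inside, 0.8)
})

test_that("generate_dataset delivers exact counts, sound labels and determinism", {
  ds <- toy_dataset(c(10, 10, 10), seed = 5)
  labs <- dataset_labels(ds)
  expect_identical(as.vector(table(labs)), c(10L, 10L, 10L))

  # label soundness: non-physiological iff >= 1 recorded event
  for (s in ds) {
    if (s$label == "physiological") expect_identical(nrow(s$events), 0L)
    else expect_gte(nrow(s$events), 1L)
  }

  again <- toy_dataset(c(10, 10, 10), seed = 5)
  expect_identical(lapply(ds, `[[`, "samples"), lapply(again, `[[`, "samples"))
  expect_error(generate_dataset(synthetic_spec(n_per_class = c(0, 0, 0))),
               "positive")
})

test_that("largest-remainder apportionment reproduces the published class mix", {
  # class counts 66581 / 18184 / 13777 at a requested total of 100
  expect_identical(ratio_counts(100, c(66581, 18184, 13777)),
                   c(68L, 18L, 14L))
  expect_identical(sum(ratio_counts(37, c(1, 1, 1))), 37L)
  spec <- synthetic_spec(total = 100, class_ratios = c(66581, 18184, 13777))
  expect_identical(unname(spec$n_per_class), c(68L, 18L, 14L))
})

test_that("mixed-class segments are labeled by the last event in time", {
  ds <- generate_dataset(synthetic_spec(n_per_class = c(0, 0, 30),
                                        p_mixed = 1, seed = 9))
  mixed <- Filter(function(s) nrow(s$events) >= 2, ds)
  expect_gt(length(mixed), 0)
  for (s in mixed) {
    last <- s$events[which.max(s$events$onset_sample), ]
    expect_true(last$kind %in% c("muscle_artifact", "powerline"))
    expect_identical(s$label, "artifact")
    expect_true(any(s$events$kind == "spike_hfo"))
  }
})

test_that("spectral contracts hold across generated pathological instances", {
  ds <- generate_dataset(synthetic_spec(n_per_class = c(0, 6, 0), seed = 21))
  for (s in ds) {
    ev <- s$events[1, ]
    env <- bandpass_envelope(s, low = 80, high = 600)  # covers all HFO rates
    pk <- which.max(env) - 1                    # 0-based
    expect_true(pk >= ev$onset_sample - 100 && pk <= ev$offset_sample + 100)
  }
})
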
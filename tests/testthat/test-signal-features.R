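fs <- 2000
tt <- (0:(10 * fs - 1)) / fs

test_that("band-pass keeps the EMG band and rejects out-of-band power", {
  lowtone <- emg_trace(sin(2 * pi * 10 * tt), fs)
  expect_lt(sqrt(mean(bandpass(lowtone)$samples^2)),
            0.05 * sqrt(mean(lowtone$samples^2)))

  midtone <- emg_trace(sin(2 * pi * 100 * tt), fs)
  expect_equal(sqrt(mean(bandpass(midtone)$samples^2)),
               sqrt(mean(midtone$samples^2)), tolerance = 0.05)

  set.seed(1)
  wn <- emg_trace(rnorm(10 * fs), fs)
  y <- bandpass(wn)$samples
  p <- Mod(fft(y)[2:(5 * fs)])^2          # one-sided periodogram
  f <- (1:(5 * fs - 1)) * fs / length(y)
  expect_lt(sum(p[f < 10]) / sum(p), 0.02)
  expect_lt(sum(p[f > 600]) / sum(p), 0.02)
  expect_error(bandpass(emg_trace(rnorm(100), 30)), "unusable")
})

test_that("cycle segmentation follows the half-open heel-strike intervals", {
  tr <- emg_trace(seq_len(7 * fs), fs, "TA", "left")
  ev <- gait_events(left = 0:6, right = 0:6 + 0.5)
  cycles <- segment_cycles(tr, ev, "left")
  expect_length(cycles, 6)
  expect_true(all(vapply(cycles, function(c) length(c$samples), 1L) == fs))
  # half-open: first sample of cycle 2 is the strike-time sample itself
  expect_identical(cycles[[2]]$samples[1], tr$samples[fs + 1])

  ev8 <- gait_events(left = 0:7, right = 0:7 + 0.5)
  tr8 <- emg_trace(seq_len(8 * fs), fs, "TA", "left")
  expect_length(segment_cycles(tr8, ev8, "left"), 6)

  short <- gait_events(left = c(0, 1), right = c(0.5, 1.5))
  expect_error(segment_cycles(tr, short, "left"), "TA left")
  expect_error(segment_cycles(tr, short, "left"),
               class = "semgait_insufficient_data")
})

test_that("windowed RMS matches closed forms and the loop oracle", {
  const <- rep(2, fs)
  env <- rms_envelope(const, fs)
  expect_identical(nrow(env), 49L)              # floor((2000-60)/40)+1
  expect_true(all(abs(env$rms - 2) < 1e-12))

  sine <- sin(2 * pi * 100 * tt[1:fs])
  expect_true(all(abs(rms_envelope(sine, fs)$rms - 1 / sqrt(2)) <
                    0.02 / sqrt(2)))

  set.seed(2)
  x <- rnorm(3111)
  expect_equal(rms_envelope(x, fs), rms_envelope_loop(x, fs),
               tolerance = 1e-12)
  expect_error(rms_envelope(rnorm(10), fs), "window")
})

test_that("envelope normalization interpolates onto the 101-point grid", {
  env <- normalize_envelope(c(0.1, 0.3, 0.5), rep(2, 3), 0, 1)
  expect_length(env, 101)
  expect_true(all(env == 2))

  two <- normalize_envelope(c(0.25, 0.75), c(1, 3), 0, 1)
  expect_equal(as.numeric(two[51]), 2)          # value at 50 %
  expect_equal(as.numeric(two[1]), 1)           # held at nearest
  expect_equal(as.numeric(two[101]), 3)
  expect_error(normalize_envelope(0.5, 1, 0, 1), "windows")
})

test_that("envelope averaging is a pointwise mean of exactly six cycles", {
  e <- structure(seq(0, 3, length.out = 101), class = "cycle_envelope")
  same <- mean_envelope(rep(list(e), 6))
  expect_equal(as.numeric(same), as.numeric(e))

  flip <- structure(3 - as.numeric(e), class = "cycle_envelope")
  mixed <- mean_envelope(c(rep(list(e), 3), rep(list(flip), 3)))
  expect_true(all(abs(mixed - 1.5) < 1e-12))
  expect_error(mean_envelope(rep(list(e), 5)), "exactly 6")
})

test_that("peak extraction takes the global maximum, first occurrence on ties", {
  env <- numeric(101); env[36] <- 55
  expect_identical(peak_features(structure(env, class = "cycle_envelope")),
                   list(rms_peak = 55, rms_peak_time = 35))

  flat <- structure(rep(1.5, 101), class = "cycle_envelope")
  expect_identical(peak_features(flat)$rms_peak_time, 0)

  bimod <- numeric(101); bimod[28] <- 50; bimod[45] <- 40
  expect_identical(peak_features(structure(bimod, class = "cycle_envelope"))$
                     rms_peak_time, 27)
})

test_that("spectral features match line spectra and the flat-band midpoint", {
  sine <- sin(2 * pi * 100 * tt[1:(1.1 * fs)])
  sf <- spectral_features(sine, fs)
  expect_equal(sf$mpf, 100, tolerance = 0.02)
  expect_equal(sf$mf, 100, tolerance = 0.02)

  # equal-amplitude comb across 20-500 Hz approximates a flat band spectrum
  set.seed(3)
  freqs <- seq(20, 500, by = 2)
  comb <- rowSums(vapply(freqs,
                         function(f0) cos(2 * pi * f0 * tt[1:(2 * fs)] +
                                            runif(1, 0, 2 * pi)),
                         numeric(2 * fs)))
  cf <- spectral_features(comb, fs)
  expect_equal(cf$mpf, 260, tolerance = 0.05)
  expect_equal(cf$mf, 260, tolerance = 0.05)

  expect_error(spectral_features(numeric(fs), fs), "all-zero")
  expect_error(spectral_features(rnorm(100), fs), "0.25")
})

test_that("median frequency splits band power in half (cumulative oracle)", {
  sp <- emg_spectrum(40, 100)
  x <- bandpass(shaped_noise(1.1, fs, sp, seed = 13))$samples
  sf <- spectral_features(x, fs)
  n <- length(x)
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  X <- Mod(fft(x * taper)[2:(floor(n / 2) + 1)])^2
  f <- (1:floor(n / 2)) * fs / n
  fb <- f[f >= 20 & f <= 500]; pb <- X[f >= 20 & f <= 500]
  half <- sum(pb) / 2
  k <- sum(fb <= sf$mf)                          # last bin at or below MF
  # the half-power point lies inside the bin straddling MF
  expect_lte(sum(pb[seq_len(k)]), half + 1e-9 * sum(pb))
  expect_gte(sum(pb[seq_len(k + 1)]), half - 1e-9 * sum(pb))
  expect_gt(sf$mpf, sf$mf)                      # right-skewed EMG spectrum
})

test_that("per-cycle spectral averaging is arithmetic and names bad cycles", {
  cyc <- sin(2 * pi * 100 * tt[1:fs])
  same <- per_cycle_spectral_mean(rep(list(cyc), 6), fs)
  expect_equal(same, spectral_features(cyc, fs), tolerance = 1e-12)

  mix <- c(rep(list(sin(2 * pi * 60 * tt[1:fs])), 3),
           rep(list(sin(2 * pi * 80 * tt[1:fs])), 3))
  expect_equal(per_cycle_spectral_mean(mix, fs)$mpf, 70, tolerance = 0.02)

  bad <- c(rep(list(cyc), 4), list(numeric(fs)), list(cyc))
  expect_error(per_cycle_spectral_mean(bad, fs), "cycle 5")
  expect_error(per_cycle_spectral_mean(rep(list(cyc), 4), fs), "exactly 6")
})

test_that("extracted features obey sign-flip and scaling invariances", {
  rec <- simulate_subject(default_subject_profile("L5"), seed = 31)
  base <- extract_subject(rec)$features

  flipped <- rec
  flipped$traces <- lapply(rec$traces, function(t) { t$samples <- -t$samples; t })
  expect_equal(extract_subject(flipped)$features, base, tolerance = 1e-9)

  scaled <- rec
  scaled$traces <- lapply(rec$traces, function(t) { t$samples <- 3 * t$samples; t })
  sf <- extract_subject(scaled)$features
  expect_equal(sf$rms_peak, 3 * base$rms_peak, tolerance = 1e-9)
  expect_equal(sf$rms_peak_time, base$rms_peak_time)
  expect_equal(sf$mpf, base$mpf, tolerance = 1e-9)
  expect_equal(sf$mf, base$mf, tolerance = 1e-9)
})

test_that("a silent recording is rejected with the failing channels named", {
  rec <- simulate_subject(default_subject_profile("healthy"), seed = 32)
  rec$traces <- lapply(rec$traces, function(t) { t$samples[] <- 0; t })
  expect_error(extract_subject(rec), "TA_left.*undefined spectrum")
})
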
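# Envelope extraction from spectrograms.

test_that("a single tone collapses all three envelopes to its velocity", {
  bin <- 600 / 128 * 2.998e8 / (2 * 24e9)  # one velocity bin, ~0.0293 m/s
  # bin-centered tone: envelopes within one bin of the true velocity
  v_c <- 34 * bin
  tone <- make_tone(34 * 600 / 128, duration = 2)
  env <- extract_envelopes(stft_spectrogram(tone, one_sided = TRUE))
  tol <- bin * (1 + 1e-9)
  expect_true(all(abs(env$v_u - v_c) <= tol))
  expect_true(all(abs(env$v_l - v_c) <= tol))
  expect_true(all(abs(env$v_m - v_c) <= tol))
  # off-center tone at exactly 1.0 m/s: mainlobe leakage can put the
  # lower edge at the far neighbor, so allow 1.5 bins
  v <- 1.0
  env2 <- extract_envelopes(stft_spectrogram(
    make_tone(velocity_to_doppler(v), duration = 2), one_sided = TRUE))
  expect_true(all(abs(env2$v_u - v) <= 1.5 * bin))
  expect_true(all(abs(env2$v_l - v) <= 1.5 * bin))
  expect_true(all(abs(env2$v_m - v) <= 1.5 * bin))
})

test_that("two equal-power tones give the expected envelope triplet", {
  tt <- seq(0, 2 - 1 / 600, by = 1 / 600)
  x <- exp(2i * pi * velocity_to_doppler(0.5) * tt) +
    exp(2i * pi * velocity_to_doppler(1.5) * tt)
  sp <- stft_spectrogram(iq_signal(x, fs = 600), one_sided = TRUE)
  env <- extract_envelopes(sp)
  expect_equal(mean(env$v_u), 1.5, tolerance = 0.05)
  expect_equal(mean(env$v_l), 0.5, tolerance = 0.08)
  expect_equal(mean(env$v_m), 1.0, tolerance = 0.05)
})

test_that("noise-free walk: upper envelope reaches the commanded peak", {
  prof <- gait_profile("non-faller", body_speed = 1.0, cadence = 105,
                       swing_peak_ratio = 2.5, stride_variability = 0)
  cfg <- quick_config(duration = 6, noise_power = 0)
  tracks <- simulate_walk_kinematics(prof, cfg)
  sig <- synthesize_iq(tracks, cfg)
  env <- extract_envelopes(stft_spectrogram(highpass_filter(sig),
                                            one_sided = TRUE))
  expect_equal(max(env$v_u), 2.5, tolerance = 0.1)
})

test_that("envelope ordering holds on every frame of simulated subjects", {
  for (seed in 1:10) {
    grp <- if (seed %% 2 == 0) "faller" else "non-faller"
    sig <- simulate_subject(grp, rng_seed = seed, config = quick_config())
    env <- extract_envelopes(stft_spectrogram(highpass_filter(sig),
                                              one_sided = TRUE))
    expect_true(all(env$v_l <= env$v_m & env$v_m <= env$v_u))
  }
})

test_that("loosening the threshold widens (never narrows) the envelopes", {
  sig <- simulate_subject("non-faller", rng_seed = 77,
                          config = quick_config())
  sp <- stft_spectrogram(highpass_filter(sig), one_sided = TRUE)
  tight <- extract_envelopes(sp, threshold_db = -12)
  loose <- extract_envelopes(sp, threshold_db = -25)
  shared <- intersect(which(!tight$gap), which(!loose$gap))
  expect_true(all(loose$v_u[shared] >= tight$v_u[shared] - 1e-12))
  expect_true(all(loose$v_l[shared] <= tight$v_l[shared] + 1e-12))
})

test_that("envelopes are invariant to power rescaling", {
  sig <- simulate_subject("faller", rng_seed = 5, config = quick_config())
  sp <- stft_spectrogram(highpass_filter(sig), one_sided = TRUE)
  env1 <- extract_envelopes(sp)
  sp$power <- sp$power * 73.5
  env2 <- extract_envelopes(sp)
  expect_equal(env1$v_u, env2$v_u)
  expect_equal(env1$v_l, env2$v_l)
  expect_equal(env1$v_m, env2$v_m)
})

test_that("upper envelope oscillates at the step frequency", {
  prof <- gait_profile("non-faller", body_speed = 1.0, cadence = 105,
                       swing_peak_ratio = 3, stride_variability = 0)
  cfg <- radar_config(duration = 8, noise_power = 0, initial_range = 16)
  tracks <- simulate_walk_kinematics(prof, cfg)
  sig <- synthesize_iq(tracks, cfg)
  env <- extract_envelopes(stft_spectrogram(highpass_filter(sig),
                                            one_sided = TRUE))
  x <- env$v_u - mean(env$v_u)
  n <- length(x)
  spec <- Mod(fft(x))^2
  freqs <- (seq_len(n) - 1) * 600 / n
  half <- 2:floor(n / 2)
  peak_f <- freqs[half][which.max(spec[half])]
  step_f <- 105 / 60
  expect_lt(abs(peak_f - step_f), 600 / n + 0.05)
})

test_that("gap frames are interpolated and edge gaps dropped", {
  v <- 1.0
  tone <- make_tone(velocity_to_doppler(v), duration = 1)
  sp <- stft_spectrogram(tone, one_sided = TRUE)
  # silence a leading frame and an interior frame
  sp$power[1, ] <- 0
  sp$power[100, ] <- 0
  env <- extract_envelopes(sp)
  expect_equal(length(env$frame_times), nrow(sp$power) - 1)
  expect_true(all(is.finite(env$v_u)))
  expect_true(env$gap[99])  # interior gap survives, flagged
  expect_equal(env$v_u[99], v, tolerance = 0.05)
})

test_that("degenerate spectrograms are rejected", {
  tone <- make_tone(200, duration = 1)
  sp <- stft_spectrogram(tone, one_sided = TRUE)
  expect_error(extract_envelopes(sp, threshold_db = 3), "negative")
  expect_error(extract_envelopes(sp, min_velocity = 10), "min_velocity")
  empty <- sp
  empty$power <- sp$power[0, , drop = FALSE]
  expect_error(extract_envelopes(empty), "empty")
})
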
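# Gait-profile sampling, walking kinematics and I/Q synthesis.

test_that("profile sampling matches the group body-speed law", {
  draws <- vapply(1:1000, function(i) {
    sample_gait_profile("faller", rng_seed = 1000 + i)$body_speed
  }, numeric(1))
  se <- 0.281 / sqrt(1000)
  expect_lt(abs(mean(draws) - 0.787), 3 * se)

  draws_nf <- vapply(1:1000, function(i) {
    sample_gait_profile("non-faller", rng_seed = 5000 + i)$body_speed
  }, numeric(1))
  expect_lt(abs(sd(draws_nf) - 0.293), 0.1 * 0.293)
  expect_true(all(c(draws, draws_nf) >= 0.2))
})

test_that("profile sampling is deterministic and validates the group", {
  a <- sample_gait_profile("faller", rng_seed = 7, stride_variability = 0)
  b <- sample_gait_profile("faller", rng_seed = 7, stride_variability = 0)
  expect_identical(a, b)
  expect_error(sample_gait_profile("sometimes-faller", 1), "arg")
})

test_that("rigid-body limit gives constant tracks at body speed", {
  prof <- gait_profile("faller", body_speed = 1.0, cadence = 100,
                       swing_peak_ratio = 1, stance_speed_ratio = 1,
                       torso_oscillation_amplitude = 0,
                       stride_variability = 0)
  tracks <- simulate_walk_kinematics(prof, quick_config(duration = 5))
  for (tr in tracks) {
    expect_equal(unique(tr$radial_velocity), 1.0)
  }
  # distance = speed x time: torso range decreases by 5 m
  torso <- tracks$torso
  expect_equal(torso$range[1] - torso$range[length(torso$range)],
               5.0 - 1 / 600, tolerance = 1e-9)
})

test_that("range is the integral of radial velocity (per track)", {
  prof <- sample_gait_profile("non-faller", rng_seed = 3)
  tracks <- simulate_walk_kinematics(prof, quick_config(), rng_seed = 4)
  dt <- 1 / 600
  for (tr in tracks) {
    expect_equal(length(tr$range), length(tr$radial_velocity))
    v <- tr$radial_velocity
    n <- length(v)
    # trapezoidal consistency: diff(range)/dt = -(midpoint average of v)
    resid <- diff(tr$range) / dt + (v[-1] + v[-n]) / 2
    expect_lt(max(abs(resid)) / max(abs(v)), 1e-6)
    expect_true(all(tr$range > 0))
  }
})

test_that("toe velocity is periodic at the commanded cadence", {
  prof <- gait_profile("non-faller", body_speed = 1.0, cadence = 100,
                       swing_peak_ratio = 3, stride_variability = 0)
  tracks <- simulate_walk_kinematics(prof, quick_config(duration = 6))
  fs <- 600
  # peak-picking oracle on the autocorrelation of one toe's velocity:
  # the same foot repeats once per stride = 2 x 60/cadence = 1.2 s
  v <- tracks$left_toe$radial_velocity - mean(tracks$left_toe$radial_velocity)
  ac <- stats::acf(v, lag.max = 1000, plot = FALSE)$acf[, 1, 1]
  search <- 540:900  # 0.9 .. 1.5 s
  stride_lag <- search[which.max(ac[search])] - 1
  expect_equal(stride_lag / fs, 1.2, tolerance = 0.02)
  # both feet together repeat every step = 0.6 s
  v2 <- tracks$left_toe$radial_velocity + tracks$right_toe$radial_velocity
  v2 <- v2 - mean(v2)
  ac2 <- stats::acf(v2, lag.max = 600, plot = FALSE)$acf[, 1, 1]
  search2 <- 270:450  # 0.45 .. 0.75 s
  step_lag <- search2[which.max(ac2[search2])] - 1
  expect_equal(step_lag / fs, 0.6, tolerance = 0.02)
})

test_that("kinematics rejects impossible geometries", {
  prof <- gait_profile("faller", body_speed = 1.0, cadence = 100,
                       swing_peak_ratio = 3, stride_variability = 0)
  cfg <- radar_config(duration = 8, initial_range = 3)
  expect_error(simulate_walk_kinematics(prof, cfg), "initial_range")
  expect_error(
    simulate_walk_kinematics(prof, radar_config(duration = 1)),
    "4 steps")
})

test_that("synthesis implements the CW phase model", {
  cfg <- quick_config(duration = 2, noise_power = 0)
  tt <- (0:(2 * 600 - 1)) / 600
  static <- structure(
    list(body_part = "torso", time = tt,
         radial_velocity = rep(0, length(tt)),
         range = rep(5, length(tt)), amplitude = 1),
    class = "scatterer_track")
  sig <- synthesize_iq(list(static), cfg)
  expect_equal(unique(round(Mod(sig$samples), 12)), 1)
  spec <- Mod(fft(sig$samples))^2
  expect_equal(which.max(spec), 1)  # all power at 0 Hz

  # constant radial velocity v -> dominant DFT bin at 2 v f0 / c
  v <- 1.0
  moving <- static
  moving$radial_velocity <- rep(v, length(tt))
  moving$range <- 8 - v * tt
  sig2 <- synthesize_iq(list(moving), cfg)
  spec2 <- Mod(fft(sig2$samples))^2
  freqs <- (seq_along(spec2) - 1) * 600 / length(spec2)
  f_d <- velocity_to_doppler(v)
  expect_lt(abs(freqs[which.max(spec2)] - f_d), 600 / length(spec2))

  bad <- static
  bad$time <- tt + 1
  expect_error(synthesize_iq(list(static, bad), cfg), "time grid")
})

test_that("instantaneous frequency tracks the torso kinematics", {
  prof <- gait_profile("non-faller", body_speed = 1.0, cadence = 105,
                       swing_peak_ratio = 3, stride_variability = 0)
  cfg <- quick_config(duration = 4, noise_power = 0)
  tracks <- simulate_walk_kinematics(prof, cfg)
  sig <- synthesize_iq(tracks["torso"], cfg)
  # phase-difference oracle
  ph <- Arg(sig$samples[-1] * Conj(sig$samples[-length(sig$samples)]))
  f_inst <- ph * 600 / (2 * pi)
  f_true <- velocity_to_doppler(tracks$torso$radial_velocity)
  err <- abs(f_inst - (f_true[-1] + f_true[-length(f_true)]) / 2)
  expect_lt(max(err), 600 / 128)
})

test_that("zero-noise signal power equals the sum of scatterer powers", {
  prof <- sample_gait_profile("non-faller", rng_seed = 11)
  cfg <- quick_config(duration = 6, noise_power = 0)
  tracks <- simulate_walk_kinematics(prof, cfg, rng_seed = 2)
  sig <- synthesize_iq(tracks, cfg)
  expect_equal(mean(Mod(sig$samples)^2),
               sum(prof$scatterer_amplitudes^2), tolerance = 0.1)
})

test_that("cohort generation is labeled, sized and reproducible", {
  cfg <- quick_config()
  cohort <- generate_cohort(14, 19, cfg, rng_seed = 42)
  expect_length(cohort, 33)
  man <- attr(cohort, "manifest")
  expect_equal(sum(man$label == "faller"), 14)
  expect_equal(sum(man$label == "non-faller"), 19)
  expect_identical(man$label[1], cohort[[1]]$label)

  expect_length(generate_cohort(0, 0, cfg, rng_seed = 1), 0)

  again <- generate_cohort(14, 19, cfg, rng_seed = 42)
  expect_identical(cohort[[5]]$samples, again[[5]]$samples)
  expect_identical(cohort[[33]]$samples, again[[33]]$samples)
  # different master seed changes the data
  other <- generate_cohort(14, 19, cfg, rng_seed = 43)
  expect_false(identical(cohort[[5]]$samples, other[[5]]$samples))
})
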
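# Shared fixtures: all built in code, nothing on disk.

# Complex tone at Doppler frequency f_hz (positive = approaching).
make_tone <- function(f_hz, fs = 600, duration = 2, amplitude = 1) {
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  iq_signal(amplitude * exp(2i * pi * f_hz * tt), fs = fs)
}

# Doppler frequency of a radial velocity at the default 24 GHz carrier.
velocity_to_doppler <- function(v, f0 = 24e9) 2 * v * f0 / 2.998e8

# Hand-built envelope_set on a uniform time grid.
make_envelopes <- function(t, v_u, v_l, v_m, label = NULL) {
  structure(
    list(frame_times = t, v_u = v_u, v_l = v_l, v_m = v_m,
         gap = rep(FALSE, length(t)), subject_id = "fixture", label = label),
    class = "envelope_set"
  )
}

# Feature table of two well-separated Gaussian clusters in the four
# gait-parameter columns.
make_cluster_features <- function(n_per_class, sep = 4, seed = 1, sd = 0.3) {
  set.seed(seed)
  n <- 2 * n_per_class
  lab <- rep(c("faller", "non-faller"), each = n_per_class)
  shift <- ifelse(lab == "faller", 0, sep)
  data.frame(
    subject_id = sprintf("C%03d", seq_len(n)),
    label = lab,
    v_m_mean = rnorm(n, 1 + shift, sd),
    v_u_mean = rnorm(n, 2 + shift, sd),
    v_u_std = rnorm(n, 0.6 + shift, sd),
    v_l_std = rnorm(n, 0.2 + shift, sd),
    stringsAsFactors = FALSE
  )
}

# Quick radar config for fast simulator tests.
quick_config <- function(duration = 4, noise_power = 1e-3) {
  radar_config(duration = duration, noise_power = noise_power,
               initial_range = 11)
}
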
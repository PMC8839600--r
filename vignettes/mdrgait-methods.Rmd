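---
title: "Radar gait measurement, simulation and faller classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radar gait measurement, simulation and faller classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdrgait)
```

## The measurement model

A continuous-wave radar at carrier `f0` = 24 GHz illuminates a subject
walking toward it. After synchronous detection, the complex baseband
signal is modeled as a sum over scattering centers,

$$ s(t) = \sum_i A_i \exp\!\left(-j \frac{4\pi f_0}{c} R_i(t)\right) + n(t), $$

where `R_i(t)` is the radial range of center `i`, `A_i` its echo
amplitude, and `n(t)` circular complex Gaussian receiver noise. A center
moving at radial velocity `v` produces a Doppler line at
`f_d = 2 v f0 / c`; the inverse map `doppler_to_velocity()` implements
`v_d = c f_d / (2 f0)`. Sampling is at `fs` = 600 Hz.

### Frequency-axis convention

Complex sampling at 600 Hz gives an unambiguous band of width 600 Hz.
Two labelings of the same FFT bins are possible: two-sided
(−300..300 Hz, ±1.875 m/s) or one-sided (0..600 Hz, 0..3.75 m/s). Since
the subject approaches the radar, all true Doppler shifts are positive,
and the one-sided reading extends the usable velocity axis to 3.75 m/s —
enough to cover toe velocities during leg swing. `stft_spectrogram()`
returns the two-sided axis by default and the one-sided axis with
`one_sided = TRUE`; the feature pipeline uses the one-sided convention.
The simulator caps peak toe speed at 3.5 m/s, safely inside the axis and
clear of the band near the wrap where the high-pass filter's image
response would attenuate genuine motion.

## Processing chain and its parameters

1. **Clutter removal** — `highpass_filter()`: order-4 Butterworth
   high-pass, cutoff 20 Hz (0.125 m/s at 24 GHz), applied forward and
   backward. The zero-phase two-pass application preserves envelope
   timing; its gain at the cutoff is |H|⁴ = 0.25. The order is a knob;
   4 is standard biomechanics practice. The design uses the bilinear
   transform with prewarping, so the −3 dB point lands exactly on the
   cutoff; forward–backward filtering uses odd signal extension with
   steady-state initial conditions (no startup transient).
2. **Spectrogram** — `stft_spectrogram()`: Hamming window of 128 samples
   (213 ms at 600 Hz), 127-sample overlap (one-sample hop), FFT length =
   window length (no zero padding), so the velocity resolution is
   600/128 Hz ≈ 0.029 m/s at 24 GHz. Frames are stamped at window
   centers and only full windows produce frames — no padded edge frames,
   which would fabricate envelope values that the steady-state trim
   removes anyway. The *periodic* (DFT-even) Hamming variant is used: a
   bin-centered tone then concentrates into exactly three DFT lines,
   which keeps the envelope of a pure tone within one bin of its true
   velocity.
3. **Envelopes** — `extract_envelopes()`: per frame, bins with
   `v ≥ min_velocity` (default 0.125 m/s, matching the high-pass cutoff
   so the lower envelope is not pinned to filter-edge noise) are
   eligible; bins within `threshold_db` (default −20 dB) of the frame
   maximum are *significant*. `v_u`/`v_l` are the largest/smallest
   significant velocities, `v_m` the power-weighted mean over
   significant bins, so `v_l ≤ v_m ≤ v_u` by construction. The
   frame-relative threshold makes all three envelopes invariant to
   overall power rescaling. Frames with no eligible bin are gaps:
   interior gaps are linearly interpolated, edge gaps dropped.
4. **Gait parameters** — `steady_state_window()` removes 1 s from each
   end (a time-based stand-in for the spatial acceleration /
   deceleration gates of a real walkway), then `compute_parameters()`
   takes means and sample (n−1) standard deviations: `v_m_mean`,
   `v_u_mean`, `v_u_std`, `v_l_std`.
5. **Classification** — `train_svm()`: features z-scored with
   training-set statistics only (a Gaussian kernel with one width
   cannot sensibly span raw features ranging from 0.1 to 2.5 m/s);
   soft-margin RBF SVM fitted per grid point (`C` ∈ 10^(−2..3), kernel
   width parameter γ ∈ 10^(−3..2), one point per decade); the point
   maximizing validation accuracy or sensitivity wins, ties preferring
   smaller `C` then smaller γ (smoother models). No class weighting:
   the sensitivity-tuned variant arises purely from hyperparameter
   selection. The dual problem is solved by sequential minimal
   optimization with maximal-violating-pair selection (stopping
   tolerance 1e−3), cross-checked during development against an
   independent reference implementation.

## The synthetic cohort generator

No public recordings exist, so cohorts are simulated.
`sample_gait_profile()` states the world:

* **Body speed** ~ Normal with the published group mean/SD of `v_m_mean`
  (fallers 0.787 ± 0.281 m/s, non-fallers 0.982 ± 0.293), truncated at
  0.2 m/s.
* **Cadence** ~ Normal(100, 8) steps/min for fallers, Normal(110, 8) for
  non-fallers (typical elderly values; slower cadence accompanies slower
  gait), floored at 60.
* **Torso** advances at body speed with a ±20% sinusoidal oscillation at
  step frequency.
* **Feet**: each foot's velocity is continuous, passing through body
  speed at phase transitions, dipping to `stance_speed_ratio` × body
  speed (default 0.25) mid-stance — the slow heel-to-toe roll of a foot
  in floor contact — and peaking at `swing_peak_ratio` × body speed
  mid-swing, with a tapered-cosine pulse occupying 40% of the stride
  (50% plateau). Shanks follow the toes at 60% of the modulation.
  Per-step durations are jittered with a 3% coefficient of variation.
* **Echo amplitudes**: torso 1, toes 0.28, shanks 0.15 — the torso
  dominates by ~10 dB, arms are omitted entirely (their echoes are weak
  and carry little envelope information).
* **Noise**: receiver noise power 10⁻³ of a unit scatterer (≈30 dB SNR
  per sample against the torso), typical of a short-range CW link.

Each subject's record is clipped so that no scatterer comes within 1 m
of the radar; one master seed hashes into per-subject seeds, making
every cohort a pure function of (arguments, seed).

### Calibration

`swing_peak_ratio` is the one calibration constant, chosen per group so
that the *extracted* `v_u_mean` matches the published group mean.  A
closed-form inversion of the kinematic envelope
(`calibrate_swing_ratio()`) is insufficient, because two opposing
pipeline effects move the extracted value by up to ±0.3 m/s: the 213 ms
window acts as a running maximum on the envelope (inflating it), while
the −20 dB threshold intermittently hides the spectrally spread,
accelerating toe (deflating it). `calibrate_group_swing_ratio()`
therefore inverts the pipeline itself: deterministic probe subjects at
five quantiles of the group's speed law are run through the full default
chain, and the ratio is solved so their mean `v_u_mean` hits the target.
The result is deterministic, cached per session, and documented here
rather than hidden: fallers ≈ 2.8, non-fallers ≈ 3.2 (peak toe speeds
≈ 2.2 and 3.1 m/s at the group mean speeds — physiologically sensible,
about 3× walking speed).

Two stated design choices were revised when implementation proved them
wrong, and are recorded in the generator's interface:

* A *pure raised-cosine* swing pulse cannot reach the published
  `v_u_mean`/`v_m_mean` ratio (≈2.1–2.2) without peak speeds beyond the
  3.75 m/s axis; the tapered-cosine pulse achieves it at ≈3× body speed.
* *Stance velocity exactly 0* (filtered out entirely) leaves swing legs
  as the only leg contribution, biasing the power-weighted `v_m_mean`
  up by ≈0.1 m/s; the slow stance roll balances it and gives the lower
  envelope the floor-contact interpretation the measurement literature
  describes.

### What the generator does and does not emulate

It reproduces: the group means and dispersions of body speed, the
published `v_u_mean` targets, the faller < non-faller ordering of all
four parameters, periodic envelope morphology at the step frequency,
and CW radar phase physics with receiver noise. It does **not** model:
arms, range-dependent amplitude decay (the measurement area is short;
amplitudes are constant per scatterer), multipath or clutter, lateral
walking directions, or the empirical within-record variances — the
simulated `v_u_std` (≈0.63/0.88 m/s) exceeds the published 0.605/0.647,
so only the *ordering* of the dispersion parameters is claimed, not
their magnitudes. A green calibration test therefore establishes that
the pipeline recovers what the generator encodes, not that the
generator equals field data; the published test accuracy on real
subjects (78.8%) is *not* a reproduction target, and the synthetic
end-to-end experiment is held only to beating the 19/33 majority rate.
In practice the synthetic cohorts are cleaner than field data and the
SVM separates them more easily (~90% test accuracy).

## Numerical choices

* Sample standard deviations use the n−1 denominator (the convention is
  unstated in the source material).
* Grid-search ties break toward smaller `C`, then smaller γ.
* The training pool is balanced (240/240) before the 70/30 stratified
  split; the published 480-point pool's composition is unstated.
* Degenerate inputs error loudly: cutoff ≥ Nyquist, windows longer than
  the signal, empty spectrograms, single-class training sets, groups of
  size < 2 in the Welch test, subjects that would reach the radar.
* Standard definitions of specificity (`tn/(tn+fp)`) and precision
  (`tp/(tp+fp)`) are used. On the embedded test confusion matrices these
  give (89.5%, 81.8%) and (73.7%, 66.7%) — the pairs printed alongside
  the source tables appear transposed, so only accuracy and sensitivity
  are used for verification.
* Model JSON artifacts serialize doubles at 17 significant digits, so a
  restored model predicts bit-identically.

## Known limitations

* The kinematic model is a parametric stand-in, not motion-capture
  replay; simulated-data classification figures are sanity bands.
* Welch p-values of the published cohort comparison depend on the
  unavailable field data and are not reproduced.
* Foot tracks do not integrate to exactly the torso displacement (the
  peak and stance constraints are both honored instead); ranges remain
  positive and velocities are what the spectrogram sees.
* Only walking straight toward the radar is modeled.
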
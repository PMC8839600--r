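# STFT spectrogram with a Doppler-velocity axis.

#' Convert Doppler frequency to radial velocity
#'
#' `v_d = c * f_d / (2 * f0)` for a CW radar at carrier `f0`.  At 24 GHz,
#' 20 Hz corresponds to 0.125 m/s and 600 Hz to 3.75 m/s.
#'
#' @param f_d Doppler frequency or frequencies, Hz.
#' @param f0 carrier frequency, Hz (> 0).
#' @return radial velocity in m/s (sign preserved).
#' @examples
#' doppler_to_velocity(20, 24e9)
#' @export
doppler_to_velocity <- function(f_d, f0) {
  if (!is.numeric(f0) || length(f0) != 1 || f0 <= 0) {
    stop("f0 must be a positive carrier frequency")
  }
  .SPEED_OF_LIGHT * f_d / (2 * f0)
}

#' Hamming window
#'
#' Periodic (DFT-even) Hamming window `0.54 - 0.46 cos(2 pi k / N)`, the
#' variant appropriate for spectral analysis: a bin-centered tone
#' concentrates into exactly three DFT lines.
#'
#' @param n window length in samples.
#' @return numeric vector of length `n`.
#' @export
hamming_window <- function(n) {
  if (n == 1) return(1)
  k <- seq(0, n - 1)
  0.54 - 0.46 * cos(2 * pi * k / n)
}

#' STFT spectrogram of an I/Q signal
#'
#' Computes `|S(t, f_d)|^2` with a Hamming window of `window_length`
#' samples and `overlap` overlapping samples (default 128 / 127, i.e. a
#' one-sample hop; at 600 Hz the window spans 213 ms).  Only full
#' windows produce frames and each frame is stamped at its window
#' center.  With `one_sided = FALSE` (the default) bins run monotonically
#' from -fs/2 to +fs/2.  With `one_sided = TRUE` the same bins are
#' relabeled 0 .. fs (N-1)/N, the convention appropriate for a subject
#' walking toward the radar where all true Doppler shifts are positive:
#' it extends the unambiguous velocity axis to ~3.75 m/s at 24 GHz.
#'
#' @param signal an [iq_signal()].
#' @param window_length analysis window length, samples.
#' @param overlap overlapping samples between consecutive windows
#'   (`overlap < window_length`).
#' @param one_sided use the 0..fs axis instead of -fs/2..fs/2.
#' @return an `mdr_spectrogram`: list with `power`
#'   (frames x bins matrix), `frame_times`, `doppler_frequencies`,
#'   `doppler_velocities`, and a `window` descriptor.
#' @export
stft_spectrogram <- function(signal, window_length = 128, overlap = 127,
                             one_sided = FALSE) {
  stopifnot(inherits(signal, "iq_signal"))
  if (overlap >= window_length) stop("overlap must be less than window_length")
  if (overlap < 0) stop("overlap must be >= 0")
  n <- length(signal$samples)
  if (n < window_length) {
    stop("signal shorter than the analysis window")
  }
  hop <- window_length - overlap
  w <- hamming_window(window_length)
  power <- stft_power_cpp(signal$samples, w, hop, shift = !one_sided)
  n_frames <- nrow(power)
  starts <- (seq_len(n_frames) - 1) * hop
  frame_times <- (starts + (window_length - 1) / 2) / signal$fs
  if (one_sided) {
    f_d <- (seq_len(window_length) - 1) * signal$fs / window_length
  } else {
    f_d <- (seq_len(window_length) - 1 - window_length %/% 2) *
      signal$fs / window_length
  }
  structure(
    list(power = power,
         frame_times = frame_times,
         doppler_frequencies = f_d,
         doppler_velocities = doppler_to_velocity(f_d, signal$f0),
         window = list(shape = "hamming", length = window_length,
                       overlap = overlap),
         fs = signal$fs, f0 = signal$f0, one_sided = one_sided,
         subject_id = signal$subject_id, label = signal$label),
    class = "mdr_spectrogram"
  )
}

#' @export
print.mdr_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<mdr_spectrogram> %d frames x %d bins, %s axis, window %d/%d\n",
    nrow(x$power), ncol(x$power),
    if (x$one_sided) "one-sided" else "two-sided",
    x$window$length, x$window$overlap))
  invisible(x)
}
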
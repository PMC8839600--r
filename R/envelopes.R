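# Velocity-envelope extraction from a spectrogram.

#' Extract upper, lower and power-weighted mean velocity envelopes
#'
#' Per frame, bins with Doppler velocity at least `min_velocity` are
#' considered (the subject approaches the radar, and velocities below
#' the high-pass cutoff's 0.125 m/s are filter-edge noise), and a bin is
#' "significant" when its power is within `threshold_db` of the frame's
#' maximum power.  Then `v_u` is the largest significant velocity, `v_l`
#' the smallest, and `v_m` the power-weighted mean over significant
#' bins.  Frames with no eligible bin are gaps: interior gaps are filled
#' by linear interpolation and leading/trailing gaps are dropped.
#'
#' @param spec an `mdr_spectrogram` from [stft_spectrogram()].
#' @param threshold_db frame-relative power threshold in dB (< 0,
#'   default -20).
#' @param min_velocity smallest velocity considered, m/s (default 0.125,
#'   the velocity matching the 20 Hz high-pass cutoff at 24 GHz).
#' @return an `envelope_set`: list with `frame_times`, `v_u`, `v_l`,
#'   `v_m`, and a logical `gap` marking interpolated frames.  For every
#'   frame `v_l <= v_m <= v_u`.
#' @export
extract_envelopes <- function(spec, threshold_db = -20, min_velocity = 0.125) {
  stopifnot(inherits(spec, "mdr_spectrogram"))
  if (nrow(spec$power) == 0 || ncol(spec$power) == 0) {
    stop("empty spectrogram")
  }
  if (threshold_db >= 0) stop("threshold_db must be negative")
  keep <- spec$doppler_velocities >= min_velocity
  if (!any(keep)) stop("no spectrogram bins at or above min_velocity")
  vels <- spec$doppler_velocities[keep]
  ord <- order(vels)
  vels <- vels[ord]
  P <- spec$power[, keep, drop = FALSE][, ord, drop = FALSE]

  scan <- envelope_scan_cpp(P, vels, 10^(threshold_db / 10))
  gap <- scan$iu == 0
  v_u <- ifelse(gap, NA_real_, vels[pmax(scan$iu, 1L)])
  v_l <- ifelse(gap, NA_real_, vels[pmax(scan$il, 1L)])
  v_m <- scan$v_m

  tt <- spec$frame_times
  if (any(gap)) {
    ok <- !gap
    if (sum(ok) < 2) stop("too few frames with significant power")
    fill <- function(v) approx(tt[ok], v[ok], xout = tt, rule = 1)$y
    v_u <- fill(v_u); v_l <- fill(v_l); v_m <- fill(v_m)
    keep_frames <- !is.na(v_u)              # drops leading/trailing gaps
    tt <- tt[keep_frames]
    v_u <- v_u[keep_frames]; v_l <- v_l[keep_frames]; v_m <- v_m[keep_frames]
    gap <- gap[keep_frames]
  }

  structure(
    list(frame_times = tt, v_u = v_u, v_l = v_l, v_m = v_m, gap = gap,
         subject_id = spec$subject_id, label = spec$label),
    class = "envelope_set"
  )
}

#' @export
print.envelope_set <- function(x, ...) {
  cat(sprintf(
    "<envelope_set> %d frames, t in [%.3f, %.3f] s, v_u mean %.3f m/s\n",
    length(x$frame_times), min(x$frame_times), max(x$frame_times),
    mean(x$v_u)))
  invisible(x)
}
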
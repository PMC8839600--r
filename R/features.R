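# The four fall-risk gait parameters and supporting statistics.

#' Restrict envelopes to the steady-state walking window
#'
#' Drops `trim_seconds` from each end of the envelope record, removing
#' the acceleration and deceleration phases so the parameters describe
#' steady-state walking.
#'
#' @param env an `envelope_set`.
#' @param trim_seconds seconds removed from each end (default 1).
#' @return the trimmed `envelope_set`.
#' @export
steady_state_window <- function(env, trim_seconds = 1.0) {
  stopifnot(inherits(env, "envelope_set"))
  if (trim_seconds < 0) stop("trim_seconds must be >= 0")
  if (trim_seconds == 0) return(env)
  t0 <- min(env$frame_times); t1 <- max(env$frame_times)
  if (t1 - t0 <= 2 * trim_seconds) {
    stop("record too short: envelopes span less than 2 * trim_seconds")
  }
  keep <- env$frame_times >= t0 + trim_seconds &
    env$frame_times <= t1 - trim_seconds
  out <- env
  for (f in c("frame_times", "v_u", "v_l", "v_m", "gap")) {
    out[[f]] <- env[[f]][keep]
  }
  out
}

#' Compute the four gait parameters from an envelope set
#'
#' Returns the time mean of the power-weighted mean envelope
#' (`v_m_mean`, a walking-speed proxy), the time mean and sample
#' standard deviation of the upper envelope (`v_u_mean`, `v_u_std`,
#' describing the leg-forward motion), and the sample standard deviation
#' of the lower envelope (`v_l_std`, variation of the legs in floor
#' contact).  Standard deviations use the n - 1 denominator.
#'
#' @param env an `envelope_set` with at least 2 frames.
#' @return a `gait_parameters` object (named list with an
#'   `as.data.frame` method).
#' @export
compute_parameters <- function(env) {
  stopifnot(inherits(env, "envelope_set"))
  if (length(env$frame_times) < 2) {
    stop("need at least 2 frames to compute standard deviations")
  }
  res <- structure(
    list(v_m_mean = mean(env$v_m),
         v_u_mean = mean(env$v_u),
         v_u_std = sd(env$v_u),
         v_l_std = sd(env$v_l),
         subject_id = env$subject_id,
         label = env$label),
    class = "gait_parameters"
  )
  if (res$v_u_mean < res$v_m_mean) {
    warning("v_u_mean below v_m_mean: envelopes look physically implausible")
  }
  res
}

#' @export
as.data.frame.gait_parameters <- function(x, ...) {
  data.frame(subject_id = x$subject_id %||% NA_character_,
             label = if (is.null(x$label)) NA_character_ else x$label,
             v_m_mean = x$v_m_mean, v_u_mean = x$v_u_mean,
             v_u_std = x$v_u_std, v_l_std = x$v_l_std,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gait_parameters <- function(x, ...) {
  cat(sprintf(
    "<gait_parameters> v_m_mean %.3f, v_u_mean %.3f, v_u_std %.3f, v_l_std %.3f (m/s)\n",
    x$v_m_mean, x$v_u_mean, x$v_u_std, x$v_l_std))
  invisible(x)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Welch-Satterthwaite degrees of freedom,
#' as used to compare gait parameters between fallers and non-fallers.
#'
#' @param group_a,group_b numeric vectors (each n >= 2; at least one
#'   group with nonzero variance).
#' @return a list with `t`, `df`, and two-sided `p`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  va <- stats::var(group_a); vb <- stats::var(group_b)
  na <- length(group_a); nb <- length(group_b)
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = na + nb - 2, p = 1))
    }
    stop("both groups have zero variance with different means")
  }
  se2 <- va / na + vb / nb
  t_stat <- (mean(group_a) - mean(group_b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

#' Full feature-extraction pipeline for one I/Q signal
#'
#' High-pass filtering, one-sided STFT spectrogram, envelope extraction,
#' steady-state trimming and gait-parameter computation with the
#' standard settings (20 Hz cutoff, order 4; 128/127 Hamming STFT;
#' -20 dB envelope threshold; 1 s trim).
#'
#' @param signal an [iq_signal()].
#' @param cutoff,order high-pass settings.
#' @param window_length,overlap STFT settings.
#' @param threshold_db,min_velocity envelope settings.
#' @param trim_seconds steady-state trim.
#' @return a `gait_parameters` object.
#' @export
extract_gait_features <- function(signal, cutoff = 20, order = 4,
                                  window_length = 128, overlap = 127,
                                  threshold_db = -20, min_velocity = 0.125,
                                  trim_seconds = 1.0) {
  filtered <- highpass_filter(signal, cutoff = cutoff, order = order)
  spec <- stft_spectrogram(filtered, window_length = window_length,
                           overlap = overlap, one_sided = TRUE)
  env <- extract_envelopes(spec, threshold_db = threshold_db,
                           min_velocity = min_velocity)
  env <- steady_state_window(env, trim_seconds = trim_seconds)
  compute_parameters(env)
}

#' Feature table for a cohort of signals
#'
#' Runs [extract_gait_features()] on every signal and stacks the results.
#'
#' @param signals list of [iq_signal()] objects (e.g. from
#'   [generate_cohort()]).
#' @param ... passed to [extract_gait_features()].
#' @return a data.frame with columns subject_id, label, v_m_mean,
#'   v_u_mean, v_u_std, v_l_std.
#' @export
cohort_features <- function(signals, ...) {
  rows <- lapply(signals, function(s) as.data.frame(extract_gait_features(s, ...)))
  do.call(rbind, rows)
}
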
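#' Radar and acquisition configuration
#'
#' Describes the CW radar and the recording: 24 GHz carrier, 600 Hz
#' complex-baseband sampling of the synchronously detected signal, record
#' duration and the subject's starting range.  `noise_power` is the
#' variance of the circular complex Gaussian receiver noise relative to a
#' unit-amplitude scatterer.
#'
#' @param f0 carrier frequency in Hz (default 24 GHz).
#' @param fs sampling frequency of the demodulated signal in Hz (default 600).
#' @param noise_power receiver noise power relative to unit scatterer power.
#' @param duration record length in seconds.
#' @param initial_range distance from subject to radar at t = 0, in meters.
#'   Must exceed the total distance walked (the subject never passes the
#'   radar).
#' @return an object of class `radar_config`.
#' @examples
#' cfg <- radar_config()
#' cfg$f0
#' @export
radar_config <- function(f0 = 24e9, fs = 600, noise_power = 1e-3,
                         duration = 8, initial_range = 11) {
  if (!is.numeric(f0) || f0 <= 0) stop("f0 must be a positive frequency in Hz")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive frequency in Hz")
  if (!is.numeric(duration) || duration <= 0) stop("duration must be positive")
  if (!is.numeric(initial_range) || initial_range <= 0) {
    stop("initial_range must be positive")
  }
  if (!is.numeric(noise_power) || noise_power < 0) {
    stop("noise_power must be >= 0")
  }
  structure(
    list(f0 = f0, fs = fs, c = .SPEED_OF_LIGHT, noise_power = noise_power,
         duration = duration, initial_range = initial_range),
    class = "radar_config"
  )
}

#' @export
print.radar_config <- function(x, ...) {
  cat(sprintf(
    "<radar_config> f0 = %.3g GHz, fs = %g Hz, duration = %g s, R0 = %g m, noise = %g\n",
    x$f0 / 1e9, x$fs, x$duration, x$initial_range, x$noise_power))
  invisible(x)
}

# Group-level gait-parameter statistics (m/s) used to calibrate the
# simulator: mean and standard deviation of each of the four parameters
# for the faller and non-faller cohorts, plus the published Welch p-values.
GAIT_GROUP_STATS <- data.frame(
  parameter = c("v_m_mean", "v_u_mean", "v_u_std", "v_l_std"),
  faller_mean = c(0.787, 1.66, 0.605, 0.144),
  faller_sd = c(0.281, 0.578, 0.170, 0.0817),
  nonfaller_mean = c(0.982, 2.19, 0.647, 0.210),
  nonfaller_sd = c(0.293, 0.581, 0.178, 0.0854),
  p_welch = c(0.0630, 0.0151, 0.493, 0.0308),
  stringsAsFactors = FALSE
)

#' Gait-parameter calibration table
#'
#' Group means and standard deviations of the four gait parameters for
#' the faller and non-faller cohorts used as calibration targets by the
#' simulator, together with the associated Welch's t-test p-values.
#'
#' @return a data.frame with one row per gait parameter.
#' @export
gait_group_stats <- function() GAIT_GROUP_STATS

#' Walking-kinematics profile of one subject
#'
#' Parametric description of a subject's gait used by the radar
#' simulator.  The torso advances at `body_speed` with a sinusoidal
#' speed oscillation at step frequency; each toe alternates stance (a
#' slow floor-contact roll) and swing (a tapered-cosine velocity pulse
#' peaking at `swing_peak_ratio * body_speed`); shanks follow the toes
#' at a fixed fraction of the modulation.
#'
#' @param label `"faller"` or `"non-faller"`.
#' @param body_speed mean torso advance speed, m/s.
#' @param cadence step rate, steps/min.
#' @param swing_peak_ratio peak toe radial speed divided by `body_speed`.
#'   Sampled profiles always exceed 1; the value 1 is allowed as the
#'   rigid-body limit (no limb modulation).
#' @param torso_oscillation_amplitude amplitude of the torso speed
#'   oscillation, m/s.
#' @param stride_variability coefficient of variation of per-step
#'   duration (>= 0).
#' @param scatterer_amplitudes named numeric vector of relative echo
#'   amplitudes for `torso`, `left_toe`, `right_toe`, `left_shank`,
#'   `right_shank`; the torso must be the strongest (arm echoes are weak
#'   and are omitted altogether).
#' @param swing_plateau fraction of the swing pulse spent at peak
#'   velocity (tapered-cosine shape parameter in `[0, 1)`).
#' @param stance_speed_ratio mid-stance foot speed divided by
#'   `body_speed` (in `(0, 1]`; the foot rolls slowly while in floor
#'   contact, which is what the lower envelope tracks).
#' @return an object of class `gait_profile`.
#' @export
gait_profile <- function(label,
                         body_speed,
                         cadence,
                         swing_peak_ratio,
                         torso_oscillation_amplitude = 0.2 * body_speed,
                         stride_variability = 0.03,
                         scatterer_amplitudes = c(torso = 1, left_toe = 0.28,
                                                  right_toe = 0.28,
                                                  left_shank = 0.15,
                                                  right_shank = 0.15),
                         swing_plateau = 0.5,
                         stance_speed_ratio = 0.25) {
  label <- match.arg(label, c("faller", "non-faller"))
  if (!is.numeric(body_speed) || body_speed <= 0) {
    stop("body_speed must be positive")
  }
  if (!is.numeric(cadence) || cadence <= 0) stop("cadence must be positive")
  if (!is.numeric(swing_peak_ratio) || swing_peak_ratio < 1) {
    stop("swing_peak_ratio must be at least 1")
  }
  if (stance_speed_ratio <= 0 || stance_speed_ratio > 1) {
    stop("stance_speed_ratio must be in (0, 1]")
  }
  if (stride_variability < 0) stop("stride_variability must be >= 0")
  need <- c("torso", "left_toe", "right_toe", "left_shank", "right_shank")
  if (!all(need %in% names(scatterer_amplitudes))) {
    stop("scatterer_amplitudes must name: ", paste(need, collapse = ", "))
  }
  amp <- scatterer_amplitudes[need]
  if (any(amp <= 0)) stop("scatterer amplitudes must be positive")
  if (amp[["torso"]] < max(amp)) {
    stop("the torso must be the strongest scatterer")
  }
  if (swing_plateau < 0 || swing_plateau >= 1) {
    stop("swing_plateau must be in [0, 1)")
  }
  structure(
    list(label = label, body_speed = body_speed, cadence = cadence,
         swing_peak_ratio = swing_peak_ratio,
         torso_oscillation_amplitude = torso_oscillation_amplitude,
         stride_variability = stride_variability,
         scatterer_amplitudes = amp,
         swing_plateau = swing_plateau,
         stance_speed_ratio = stance_speed_ratio),
    class = "gait_profile"
  )
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf(
    "<gait_profile> %s: speed %.3f m/s, cadence %.1f steps/min, swing peak x%.2f\n",
    x$label, x$body_speed, x$cadence, x$swing_peak_ratio))
  invisible(x)
}
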
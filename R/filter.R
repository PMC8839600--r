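# Butterworth high-pass design (bilinear transform with prewarping) and
# zero-phase (forward-backward) filtering.  Implemented here because the
# design is small and must be exactly reproducible: the analog prototype
# poles are mapped lowpass -> highpass -> digital, giving the textbook
# -3 dB magnitude at the cutoff.

# complex polynomial from roots, leading coefficient 1
.poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rk in r) p <- c(p, 0) - c(0, p * rk)
  p
}

#' Design a digital Butterworth high-pass filter
#'
#' Order-`n` Butterworth high-pass with cutoff `cutoff` Hz at sampling
#' frequency `fs`, via the bilinear transform with frequency prewarping.
#' The squared magnitude response is `1 / (1 + (fc/f)^(2n))` in the
#' analog domain, i.e. -3 dB at the cutoff.
#'
#' @param cutoff cutoff frequency, Hz (0 < cutoff < fs/2).
#' @param fs sampling frequency, Hz.
#' @param order filter order (default 4).
#' @return a list with numerator `b` and denominator `a` coefficients.
#' @examples
#' flt <- butter_highpass(20, 600)
#' Mod(freq_response(flt, 20, 600))^2  # ~0.5
#' @export
butter_highpass <- function(cutoff, fs, order = 4) {
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency fs/2")
  }
  if (order < 1) stop("order must be >= 1")
  k <- seq_len(order)
  # analog lowpass prototype poles on the unit circle (left half plane)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  wc <- 2 * fs * tan(pi * cutoff / fs)  # prewarped cutoff (rad/s)
  q <- wc / p                            # highpass analog poles
  # bilinear transform: s = 2 fs (z-1)/(z+1)
  zp <- (2 * fs + q) / (2 * fs - q)      # digital poles
  gain <- prod(2 * fs / (2 * fs - q))    # matches |H| = 1 at z = -1 (Nyquist)
  b <- Re(gain * .poly_from_roots(rep(1 + 0i, order)))
  a <- Re(.poly_from_roots(zp))
  list(b = b, a = a, order = order, cutoff = cutoff, fs = fs)
}

#' Frequency response of a digital filter
#'
#' @param filt a list with `b` and `a` coefficients.
#' @param f frequencies, Hz.
#' @param fs sampling frequency, Hz.
#' @return complex response H(e^{j 2 pi f / fs}).
#' @export
freq_response <- function(filt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  evalp <- function(cf) {
    acc <- 0 + 0i
    zk <- rep(1 + 0i, length(z))
    for (c_k in cf) { acc <- acc + c_k * zk; zk <- zk * z }
    acc
  }
  evalp(filt$b) / evalp(filt$a)
}

# Steady-state initial filter state for a unit-amplitude input (the
# standard companion-matrix construction), so forward-backward filtering
# has no startup transient on the padded ends.
.lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b)) - 1
  bb <- c(b, numeric(nf + 1 - length(b)))
  aa <- c(a, numeric(nf + 1 - length(a)))
  if (nf == 0) return(numeric(0))
  A <- matrix(0, nf, nf)
  A[, 1] <- -aa[-1]
  if (nf > 1) A[cbind(seq_len(nf - 1), seq_len(nf - 1) + 1)] <- 1
  B <- bb[-1] - bb[1] * aa[-1]
  solve(diag(nf) - A, B)
}

.filtfilt_real <- function(b, a, x) {
  pad <- 3 * max(length(a), length(b))
  n <- length(x)
  if (n <= pad) stop("signal too short for zero-phase filtering")
  zi <- .lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- iir_filter_cpp(b, a, y, zi * y[1])
  y <- rev(y)
  y[(pad + 1):(pad + n)]
}

#' High-pass filter an I/Q signal (clutter removal)
#'
#' Applies an order-`order` Butterworth high-pass forward and backward
#' (zero phase) to the real and imaginary parts of the baseband signal,
#' removing the static-target echo at 0 Hz.  At 24 GHz the default
#' 20 Hz cutoff corresponds to a Doppler velocity of 0.125 m/s.
#'
#' @param signal an [iq_signal()].
#' @param cutoff cutoff frequency, Hz (default 20).
#' @param order Butterworth order (default 4; the two-pass response is
#'   the squared magnitude, -6 dB at the cutoff).
#' @return the filtered `iq_signal`, same length as the input.
#' @export
highpass_filter <- function(signal, cutoff = 20, order = 4) {
  stopifnot(inherits(signal, "iq_signal"))
  if (cutoff >= signal$fs / 2) {
    stop("cutoff must be below the Nyquist frequency fs/2")
  }
  if (length(signal$samples) <= 3 * order) {
    stop("signal too short for the requested filter order")
  }
  flt <- butter_highpass(cutoff, signal$fs, order)
  re <- .filtfilt_real(flt$b, flt$a, Re(signal$samples))
  im <- .filtfilt_real(flt$b, flt$a, Im(signal$samples))
  out <- signal
  out$samples <- complex(real = re, imaginary = im)
  out
}
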
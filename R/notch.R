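# 50-Hz line-interference removal.

# Biquad (constrained direct-form II) notch design: unit-circle zeros at
# +-f0, poles pulled inside to set the -3 dB bandwidth `bw`.
notch_biquad <- function(f0, bw, rate) {
  w0 <- 2 * pi * f0 / rate
  q <- f0 / bw
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  list(b = c(1, -2 * cos(w0), 1) / a0,
       a = c(1, -2 * cos(w0) / a0, (1 - alpha) / a0))
}

# Complex frequency response of a biquad at frequencies f (Hz).
biquad_response <- function(flt, f, rate) {
  z <- exp(-1i * 2 * pi * f / rate)
  (flt$b[1] + flt$b[2] * z + flt$b[3] * z^2) /
    (1 + flt$a[2] * z + flt$a[3] * z^2)
}

#' Zero-phase notch filter for line interference
#'
#' Applies the magnitude-squared (two-pass, forward-backward equivalent)
#' response of a narrow biquad notch centred at `f0` on the segment's DFT
#' grid. This realises the steady-state zero-phase filter directly: a
#' running forward-backward IIR pass on a short segment leaves an onset
#' transient that dominates the residual of an on-notch tone, whereas the
#' spectral application removes an on-grid line component to machine
#' precision and is the identity (up to the sub-0.1% passband ripple)
#' everywhere outside the notch band. Attenuation at `f0` exceeds 30 dB;
#' passband ripple outside `f0` +- 2 Hz is below 1 dB; the output has the
#' input's length and no phase shift.
#'
#' @param x numeric vector, a single-channel EEG segment.
#' @param rate sampling rate (Hz); must exceed `2 * f0`.
#' @param f0 notch centre frequency (Hz); 50 Hz mains by default.
#' @param bw -3 dB bandwidth of the underlying single-pass notch (Hz).
#' @return filtered vector, same length as `x`.
#' @export
notch_filter <- function(x, rate, f0 = 50, bw = 1) {
  check_scalar(rate, "rate", lower = 0, strict_lower = TRUE)
  check_scalar(f0, "f0", lower = 0, strict_lower = TRUE)
  if (rate <= 2 * f0)
    stop_param("sampling rate must exceed twice the notch frequency")
  if (!is.numeric(x) || length(x) < 2L)
    stop_param("`x` must be a numeric vector of length >= 2")
  flt <- notch_biquad(f0, bw, rate)
  n <- length(x)
  f <- (seq_len(n) - 1) / n * rate
  gain2 <- Mod(biquad_response(flt, f, rate))^2
  Re(stats::fft(stats::fft(x) * gain2, inverse = TRUE)) / n
}
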
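#' EEG recording container
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in Hz (the recording hardware modelled here runs
#'   at 250 Hz).
#' @param channel_labels character vector of 10/20 channel names; the EFP
#'   pipeline requires `Pz` to be present.
#' @param markers data.frame with columns `time` (s) and `label`; condition
#'   annotations, sorted by time and within the record duration.
#' @param t0 start time (s); sample `k` of a channel is at `t0 + k / rate`,
#'   i.e. sample times are the right edges of the sampling intervals.
#' @return An object of class `efp_eeg`.
#' @export
eeg_recording <- function(data, rate = 250, channel_labels = rownames(data),
                          markers = NULL, t0 = 0) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data))
  check_scalar(rate, "rate", lower = 0, strict_lower = TRUE)
  if (is.null(channel_labels))
    stop_param("`channel_labels` must be provided")
  if (length(channel_labels) != nrow(data))
    stop_param("one channel label per data row is required")
  if (!"Pz" %in% channel_labels)
    stop_param("channel Pz must be present")
  dur <- ncol(data) / rate
  if (is.null(markers))
    markers <- data.frame(time = numeric(0), label = character(0))
  stopifnot(all(c("time", "label") %in% names(markers)))
  if (nrow(markers)) {
    if (is.unsorted(markers$time)) stop_param("markers must be sorted by time")
    if (any(markers$time < t0 - 1e-9 | markers$time > t0 + dur + 1e-9))
      stop_param("markers must lie within the record duration")
  }
  rownames(data) <- channel_labels
  structure(list(data = data, rate = rate, channel_labels = channel_labels,
                 markers = markers, t0 = t0),
            class = "efp_eeg")
}

#' @export
print.efp_eeg <- function(x, ...) {
  cat(sprintf("<efp_eeg> %d ch x %d samples @ %g Hz (%.1f s), %d markers\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              nrow(x$markers)))
  invisible(x)
}

eeg_duration <- function(rec) ncol(rec$data) / rec$rate

eeg_channel <- function(rec, label = "Pz") {
  i <- match(label, rec$channel_labels)
  if (is.na(i)) stop_param("channel ", label, " not found")
  rec$data[i, ]
}

#' Band coupling specification for synthetic EEG
#'
#' Describes one oscillatory component whose instantaneous amplitude is
#' affine in the latent arousal value: `amp(t) = base_amp + coupling *
#' latent(t)`, carried by a narrow-band oscillation centred in
#' `(f_lo, f_hi)`.
#'
#' @param f_lo,f_hi band edges in Hz (0 < f_lo < f_hi < Nyquist).
#' @param base_amp baseline amplitude (microvolts, >= 0).
#' @param coupling amplitude change per latent unit (may be negative).
#' @return a list with class `efp_band_coupling`.
#' @export
band_coupling <- function(f_lo, f_hi, base_amp, coupling) {
  check_scalar(f_lo, "f_lo", lower = 0, strict_lower = TRUE)
  check_scalar(f_hi, "f_hi", lower = f_lo, strict_lower = TRUE)
  check_scalar(base_amp, "base_amp", lower = 0)
  check_scalar(coupling, "coupling")
  structure(list(f_lo = f_lo, f_hi = f_hi, base_amp = base_amp,
                 coupling = coupling), class = "efp_band_coupling")
}

#' Default EEG generator couplings
#'
#' Theta (4-8 Hz) amplitude increases with latent arousal and beta
#' (13-30 Hz) amplitude decreases. The signs are an arbitrary but fixed
#' ground-truth convention of the generator; nothing downstream assumes them.
#'
#' @return list of [band_coupling()] objects.
#' @export
default_couplings <- function() {
  list(theta = band_coupling(4, 8, base_amp = 1.0, coupling = 0.5),
       beta = band_coupling(13, 30, base_amp = 0.8, coupling = -0.3))
}

# 1/f (power) background noise of unit RMS via spectral synthesis.
pink_noise <- function(n, rate) {
  nf <- floor(n / 2)
  f <- (1:nf) * rate / n
  amp <- 1 / sqrt(f)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = amp[nf] * cos(phase[nf]))
    full[seq(n, nf + 2)] <- Conj(spec[1:(nf - 1)])
  } else {
    full[seq(n, nf + 1)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Narrow-band unit-amplitude carrier: a sinusoid at the band centre with a
# slow random-walk phase, giving an approximately Lorentzian line of width
# ~(f_hi - f_lo)/4 that stays inside the band.
band_carrier <- function(n, rate, f_lo, f_hi) {
  fc <- (f_lo + f_hi) / 2
  linewidth <- (f_hi - f_lo) / 4
  sd_step <- sqrt(2 * pi * linewidth / rate)
  phase <- cumsum(stats::rnorm(n, 0, sd_step))
  t <- (1:n) / rate
  cos(2 * pi * fc * t + phase)
}

#' Synthesize a single-session EEG recording coupled to a latent process
#'
#' The Pz channel is a sum of 1/f background noise, 50-Hz line interference,
#' white sensor noise and one narrow-band oscillation per coupling whose
#' instantaneous amplitude is affine in the latent arousal (upsampled to the
#' EEG rate by linear interpolation) within the operating range; amplitudes
#' are clipped at zero since an oscillation cannot have negative amplitude.
#' Other channels, if requested, carry
#' white noise only. The couplings used are attached as attribute
#' `ground_truth` for later parameter-recovery checks.
#'
#' @param latent an [latent_series()]; must cover the requested duration.
#' @param couplings list of [band_coupling()] objects (see
#'   [default_couplings()]).
#' @param pink_amp RMS amplitude of the 1/f background (microvolts).
#' @param line_amp amplitude of the 50-Hz line component (microvolts).
#' @param white_sd SD of the white sensor noise (microvolts).
#' @param rate EEG sampling rate (Hz); 250 by default.
#' @param channel_labels channels to generate; must include `"Pz"`.
#' @param markers optional marker data.frame (`time`, `label`).
#' @param seed optional integer seed.
#' @param duration length of the recording (s); defaults to the latent
#'   duration.
#' @return an [eeg_recording()] with attribute `ground_truth`.
#' @export
synthesize_eeg <- function(latent, couplings = default_couplings(),
                           pink_amp = 1, line_amp = 0.5, white_sd = 0.2,
                           rate = 250, channel_labels = "Pz",
                           markers = NULL, seed = NULL, duration = NULL) {
  stopifnot(inherits(latent, "efp_latent"))
  check_scalar(pink_amp, "pink_amp", lower = 0)
  check_scalar(line_amp, "line_amp", lower = 0)
  check_scalar(white_sd, "white_sd", lower = 0)
  if (is.null(duration)) duration <- latent_duration(latent)
  if (duration > latent_duration(latent) + 1e-9)
    stop_param("latent series does not cover the requested duration")
  nyq <- rate / 2
  for (cp in couplings) {
    if (!inherits(cp, "efp_band_coupling"))
      stop_param("couplings must be band_coupling objects")
    if (cp$f_hi >= nyq)
      stop_param("coupling band must lie strictly below the Nyquist ",
                 "frequency (", nyq, " Hz)")
  }
  n <- round(duration * rate)
  t <- latent$t0 + (1:n) / rate
  lat <- latent_at(latent, t)
  eval_with_seed(seed, function() {
    pz <- numeric(n)
    if (pink_amp > 0) pz <- pz + pink_amp * pink_noise(n, rate)
    if (line_amp > 0) pz <- pz + line_amp * sin(2 * pi * 50 * t)
    if (white_sd > 0) pz <- pz + stats::rnorm(n, 0, white_sd)
    for (cp in couplings) {
      carrier <- band_carrier(n, rate, cp$f_lo, cp$f_hi)
      pz <- pz + pmax(0, cp$base_amp + cp$coupling * lat) * carrier
    }
    k <- length(channel_labels)
    data <- matrix(0, k, n)
    for (i in seq_len(k)) {
      if (channel_labels[i] == "Pz") data[i, ] <- pz
      else if (white_sd > 0) data[i, ] <- stats::rnorm(n, 0, white_sd)
    }
    rec <- eeg_recording(data, rate = rate, channel_labels = channel_labels,
                         markers = markers, t0 = latent$t0)
    attr(rec, "ground_truth") <- list(couplings = couplings,
                                      pink_amp = pink_amp,
                                      line_amp = line_amp,
                                      white_sd = white_sd)
    rec
  })
}
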
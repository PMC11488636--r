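# Energy-uniform frequency banding of the EEG spectrum.

#' Band definition
#'
#' A partition of a frequency range into contiguous bands chosen so that each
#' band carries an equal share of the calibration recording's spectral
#' energy.
#'
#' @param edges strictly increasing band-edge frequencies (Hz);
#'   `n_bands + 1` values.
#' @param calibration_energy per-band total energy of the calibration data;
#'   must be equal across bands within 1% relative.
#' @return object of class `efp_bands`.
#' @export
band_definition <- function(edges, calibration_energy) {
  if (any(diff(edges) <= 0)) stop_param("band edges must strictly increase")
  if (any(edges <= 0)) stop_param("band edges must be positive")
  n_bands <- length(edges) - 1L
  if (length(calibration_energy) != n_bands)
    stop_param("one calibration energy per band is required")
  dev <- max(abs(calibration_energy / mean(calibration_energy) - 1))
  if (dev > 0.01)
    stop_param("calibration band energies differ by more than 1% ",
               "(max relative deviation ", signif(dev, 3), ")")
  structure(list(edges = as.numeric(edges),
                 calibration_energy = as.numeric(calibration_energy)),
            class = "efp_bands")
}

n_bands <- function(bands) length(bands$edges) - 1L

#' @export
print.efp_bands <- function(x, ...) {
  cat(sprintf("<efp_bands> %d energy-uniform bands over %.2f-%.2f Hz\n",
              n_bands(x), x$edges[1], x$edges[length(x$edges)]))
  invisible(x)
}

#' Energy-uniform band edges from a calibration recording
#'
#' Notch-filters the calibration Pz channel, computes its periodogram, and
#' places band edges at the `k / n_bands` quantiles of cumulative spectral
#' energy over `f_range` (linear interpolation between DFT bins). Each band
#' then holds an equal fraction of the calibration energy, re-measured here
#' by fractional-bin integration.
#'
#' @param calibration an [eeg_recording()] (its Pz channel is used) or a
#'   numeric vector; at least 60 s of data is required.
#' @param n_bands number of bands (10 for the EFP model).
#' @param f_range `c(f_lo, f_hi)` in Hz, `0 < f_lo < f_hi <= Nyquist`. The
#'   default 0.5-40 Hz covers the physiological EEG range and keeps clear of
#'   the 50-Hz notch region.
#' @param rate sampling rate; taken from the recording when one is given.
#' @param notch apply the 50-Hz notch before measuring energy (default TRUE;
#'   disabled automatically when the notch frequency exceeds Nyquist).
#' @return an [band_definition()].
#' @export
band_edges_energy_uniform <- function(calibration, n_bands = 10,
                                      f_range = c(0.5, 40), rate = NULL,
                                      notch = TRUE) {
  if (inherits(calibration, "efp_eeg")) {
    x <- eeg_channel(calibration, "Pz")
    rate <- calibration$rate
  } else {
    x <- as.numeric(calibration)
    if (is.null(rate)) stop_param("`rate` is required for a plain vector")
  }
  check_scalar(n_bands, "n_bands", lower = 1)
  if (length(x) / rate < 60)
    stop_param("insufficient calibration data: at least 60 s are required")
  nyq <- rate / 2
  if (!(f_range[1] > 0 && f_range[1] < f_range[2] && f_range[2] <= nyq))
    stop_param("`f_range` must satisfy 0 < f_lo < f_hi <= Nyquist")
  if (notch && rate > 100) x <- notch_filter(x, rate)
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  k <- 0:floor(n / 2)
  f <- k * rate / n
  keep <- f >= f_range[1] & f <= f_range[2]
  f <- f[keep]
  p <- p[k + 1][keep]
  if (length(f) < 2 * n_bands)
    stop_param("calibration spectrum has too few bins in `f_range`")
  # piecewise-linear cumulative energy (trapezoid between bins)
  cum <- c(0, cumsum((p[-1] + p[-length(p)]) / 2 * diff(f)))
  total <- cum[length(cum)]
  if (total <= 0) stop_param("calibration data has no energy in `f_range`")
  inner <- if (n_bands > 1) {
    targets <- total * seq_len(n_bands - 1) / n_bands
    cum_m <- cummax(cum)  # guard: strictly non-decreasing for inversion
    stats::approx(cum_m, f, xout = targets, ties = "ordered")$y
  } else numeric(0)
  edges <- c(f_range[1], inner, f_range[2])
  energies <- diff(stats::approx(f, cum, xout = edges)$y)
  band_definition(edges, energies)
}

# Map frequencies to band index 1..n (edges half-open (e_k, e_{k+1}], the
# first band closed below); NA outside the range.
band_index <- function(bands, freqs) {
  e <- bands$edges
  idx <- findInterval(freqs, e, left.open = TRUE, rightmost.closed = FALSE)
  idx[freqs >= e[1] - 1e-9 & idx == 0L] <- 1L
  idx[idx < 1L | idx > n_bands(bands)] <- NA_integer_
  idx
}
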
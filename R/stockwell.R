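# Stockwell (S-) transform: time-frequency analysis with a Gaussian window
# whose width scales inversely with frequency (sigma_t = 1/f).

# Cache of per-geometry constants (Gaussian voice windows and shift indices),
# keyed by segment length and frequency-row set. The closed-loop engine calls
# the transform with identical geometry hundreds of times per session.
.st_cache <- new.env(parent = emptyenv())

st_geometry <- function(n, rows) {
  key <- paste0(n, ":", rows[1], "-", rows[length(rows)], ":", length(rows))
  got <- .st_cache[[key]]
  if (!is.null(got)) return(got)
  ms <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)  # signed, FFT order
  w <- matrix(0, n, length(rows))
  idx <- matrix(0L, n, length(rows))
  for (j in seq_along(rows)) {
    v <- rows[j]
    if (v == 0) next
    # Gaussian voice in the frequency domain, with +-2 spectral aliases so
    # that the FFT path matches the periodised time-domain definition to
    # machine precision.
    acc <- 0
    for (p in -2:2) acc <- acc + exp(-2 * pi^2 * (ms + p * n)^2 / v^2)
    w[, j] <- acc
    idx[, j] <- ((ms + v) %% n) + 1L
  }
  got <- list(w = w, idx = idx)
  if (length(ls(.st_cache)) > 32L) rm(list = ls(.st_cache), envir = .st_cache)
  .st_cache[[key]] <- got
  got
}

#' Stockwell transform of a signal segment
#'
#' Computes the S-transform via its FFT identity: for frequency voice `v`
#' (cycles per segment) the time course is the inverse DFT of the shifted
#' spectrum multiplied by the sampled Gaussian `exp(-2 pi^2 m^2 / v^2)`. The
#' zero-frequency row is the segment mean. Magnitudes are returned.
#'
#' @param segment numeric vector (even length >= 16). The EFP pipeline uses
#'   12-s segments at 250 Hz (3000 samples).
#' @param rate sampling rate (Hz).
#' @param f_range optional `c(f_lo, f_hi)` restricting the returned frequency
#'   rows; by default all DFT bins from 0 to Nyquist are returned.
#' @return object of class `efp_tf`: list with `amplitudes` (frequency bins x
#'   time points, non-negative), `freqs` (Hz) and `times` (s, right edges of
#'   the sampling intervals).
#' @export
stockwell_transform <- function(segment, rate, f_range = NULL) {
  if (!is.numeric(segment) || length(segment) < 16L)
    stop_param("`segment` must be a numeric vector of length >= 16")
  check_scalar(rate, "rate", lower = 0, strict_lower = TRUE)
  n <- length(segment)
  if (n %% 2L != 0L) stop_param("segment length must be even")
  rows <- 0:(n / 2)
  if (!is.null(f_range)) {
    stopifnot(length(f_range) == 2, f_range[1] <= f_range[2])
    rows <- rows[rows * rate / n >= f_range[1] - 1e-9 &
                 rows * rate / n <= f_range[2] + 1e-9]
    if (!length(rows)) stop_param("f_range selects no frequency rows")
  }
  geo <- st_geometry(n, rows)
  h <- stats::fft(segment) / n
  a <- matrix(h[pmax(geo$idx, 1L)], n, length(rows)) * geo$w
  s <- Mod(stats::mvfft(a, inverse = TRUE))
  if (rows[1] == 0L) s[, 1] <- abs(mean(segment))
  structure(list(amplitudes = t(s),
                 freqs = rows * rate / n,
                 times = (1:n) / rate),
            class = "efp_tf")
}
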
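# Independent oracles and shared fixtures.

# Direct double-sum Stockwell transform: time-domain sum with the
# frequency-proportional Gaussian window periodised over the segment
# (wrap terms r in -10..10). O(N^2) per frequency row; magnitudes returned
# with rows 0..N/2 like the package implementation.
stockwell_direct <- function(h) {
  n <- length(h)
  k <- 0:(n - 1)
  rows <- 0:(n / 2)
  out <- matrix(0, length(rows), n)
  for (j in seq_along(rows)) {
    v <- rows[j]
    if (v == 0) {
      out[j, ] <- abs(mean(h))
      next
    }
    d <- outer(0:(n - 1), k, "-")
    w <- 0
    for (r in -10:10) w <- w + exp(-(d + r * n)^2 * v^2 / (2 * n^2))
    w <- w * v / (n * sqrt(2 * pi))
    out[j, ] <- Mod(as.vector(w %*% (h * exp(-2i * pi * v * k / n))))
  }
  list(amplitudes = out, freqs = rows)
}

# Analytic signal envelope via the FFT Hilbert transform.
hilbert_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# FFT band-pass (ideal brick wall), adequate as a test oracle.
bandpass_fft <- function(x, rate, f_lo, f_hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)
  keep <- f >= f_lo & f <= f_hi
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE) / n)
}

# Welch-style averaged periodogram (plain segment averaging).
welch_psd <- function(x, rate, seg = 1024) {
  n_seg <- floor(length(x) / seg)
  p <- 0
  for (i in seq_len(n_seg)) {
    s <- x[((i - 1) * seg + 1):(i * seg)]
    p <- p + Mod(stats::fft(s - mean(s)))^2 / seg
  }
  list(freq = (0:(seg / 2)) * rate / seg,
       power = (p / n_seg)[1:(seg / 2 + 1)])
}

# Synthesize a signal whose periodogram is exactly proportional to the
# requested spectral amplitude profile (random phases, fixed moduli).
shaped_noise <- function(n, rate, amp_fn) {
  nf <- floor(n / 2)
  f <- (1:nf) * rate / n
  amp <- amp_fn(f)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = amp[nf])
    full[seq(n, nf + 2)] <- Conj(spec[1:(nf - 1)])
  } else {
    full[seq(n, nf + 1)] <- Conj(spec)
  }
  Re(stats::fft(full, inverse = TRUE)) / n
}

# Shared heavyweight fixture: one default-SNR calibration (7 min) and its
# fitted EFP model, built on first use and reused across test files.
shared_cal <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- calibrate_efp_model(duration = 420, seed = 7001)
    cache
  }
})

# A reduced two-cycle schedule for closed-loop unit tests.
small_schedule <- function() {
  nf_schedule(data.frame(
    label = c("Rest", "Watch", "Regulate", "Watch", "Regulate"),
    onset = c(0, 60, 120, 240, 300),
    duration = c(60, 60, 120, 60, 120)), protocol_name = "efp_nf_small")
}
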
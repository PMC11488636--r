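#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style double-gamma impulse response: a gamma density peaking about 5 s
#' after the event minus a later undershoot gamma scaled by
#' `1 / undershoot_ratio`, sampled on a uniform grid and normalised so its
#' maximum is 1.
#'
#' @param tr sampling interval of the kernel (s, > 0).
#' @param duration kernel length (s); 32 s by default.
#' @param peak_delay shape parameter of the response gamma (rate 1); the mode
#'   of the response is at `peak_delay - 1` seconds.
#' @param undershoot_delay shape parameter of the undershoot gamma.
#' @param undershoot_ratio response-to-undershoot amplitude ratio.
#' @return numeric vector of kernel samples at times
#'   `seq(0, duration, by = tr)`.
#' @examples
#' h <- canonical_hrf(0.1)
#' (which.max(h) - 1) * 0.1  # ~5 s
#' @export
canonical_hrf <- function(tr, duration = 32, peak_delay = 6,
                          undershoot_delay = 16, undershoot_ratio = 6) {
  check_scalar(tr, "tr", lower = 0, strict_lower = TRUE)
  check_scalar(duration, "duration", lower = tr)
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    stats::dgamma(t, shape = undershoot_delay, rate = 1) / undershoot_ratio
  h / max(h)
}

#' BOLD time-series container
#'
#' @param values ROI-average BOLD values (arbitrary units).
#' @param tr repetition time (s, > 0).
#' @param onset acquisition start time (s).
#' @return object of class `efp_bold`.
#' @export
bold_series <- function(values, tr, onset = 0) {
  if (!all(is.finite(values))) stop_param("BOLD values must be finite")
  check_scalar(tr, "tr", lower = 0, strict_lower = TRUE)
  check_scalar(onset, "onset")
  structure(list(values = as.numeric(values), tr = tr, onset = onset),
            class = "efp_bold")
}

bold_times <- function(bold) bold$onset + (seq_along(bold$values) - 1) * bold$tr

#' Synthesize a BOLD series from a latent process
#'
#' Convolves the latent series (at its own rate) with the canonical
#' double-gamma HRF and samples the result at the scanner's repetition time,
#' adding white measurement noise. A unit impulse in the latent therefore
#' reproduces the HRF kernel itself.
#'
#' @param latent an [latent_series()].
#' @param tr repetition time (s).
#' @param noise_sd SD of additive white noise.
#' @param seed optional integer seed.
#' @param hrf_params optional list overriding [canonical_hrf()] arguments
#'   (`duration`, `peak_delay`, `undershoot_delay`, `undershoot_ratio`).
#' @return an [bold_series()] covering the latent duration.
#' @export
synthesize_bold <- function(latent, tr = 3, noise_sd = 0, seed = NULL,
                            hrf_params = list()) {
  stopifnot(inherits(latent, "efp_latent"))
  check_scalar(tr, "tr", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  h <- do.call(canonical_hrf, c(list(tr = 1 / latent$rate), hrf_params))
  x <- latent$values
  n <- length(x)
  conv <- stats::convolve(x, rev(h), type = "open")[seq_len(n)]
  # sample at volume times (nearest latent grid index)
  n_vol <- floor((n - 1) / (tr * latent$rate)) + 1
  idx <- round((seq_len(n_vol) - 1) * tr * latent$rate) + 1
  vals <- conv[idx]
  vals <- eval_with_seed(seed, function() {
    if (noise_sd == 0) vals else vals + stats::rnorm(length(vals), 0, noise_sd)
  })
  bold_series(vals, tr = tr, onset = latent$t0)
}
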
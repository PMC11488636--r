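#' Latent arousal series
#'
#' Container for a ground-truth latent arousal process sampled on a uniform
#' grid. The latent process stands in for the (unobserved) amygdala activity
#' that drives both the synthetic EEG band-power modulation and the synthetic
#' BOLD signal.
#'
#' @param values numeric vector of arousal levels (arbitrary units).
#' @param rate sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @return An object of class `efp_latent`: a list with elements `values`,
#'   `rate` and `t0`. Sample `k` is at time `t0 + (k - 1) / rate`.
#' @export
latent_series <- function(values, rate, t0 = 0) {
  if (length(values) < 1L || !all(is.finite(values)))
    stop_param("latent `values` must be non-empty and finite")
  check_scalar(rate, "rate", lower = 0, strict_lower = TRUE)
  check_scalar(t0, "t0")
  structure(list(values = as.numeric(values), rate = rate, t0 = t0),
            class = "efp_latent")
}

#' @export
print.efp_latent <- function(x, ...) {
  cat(sprintf("<efp_latent> %d samples @ %g Hz, %.1f s, mean %.3f\n",
              length(x$values), x$rate,
              length(x$values) / x$rate, mean(x$values)))
  invisible(x)
}

latent_times <- function(latent) {
  latent$t0 + (seq_along(latent$values) - 1) / latent$rate
}

latent_duration <- function(latent) length(latent$values) / latent$rate

#' Sample a latent series at arbitrary times
#'
#' Linear interpolation (constant extrapolation at the edges). Used to
#' upsample the 4-Hz latent grid to the 250-Hz EEG grid.
#'
#' @param latent an [latent_series()] object.
#' @param times numeric vector of times (s).
#' @return numeric vector of interpolated values.
#' @export
latent_at <- function(latent, times) {
  resample_linear(latent_times(latent), latent$values, times)
}

#' Generate a latent arousal process (Ornstein-Uhlenbeck)
#'
#' Simulates a stationary Ornstein-Uhlenbeck process
#' `dX = -theta (X - mean) dt + sigma dW` by its exact discretisation at the
#' requested rate, starting from a draw of the stationary distribution
#' (variance `sigma^2 / (2 theta)`). With `sigma = 0` the path is constant at
#' `mean`.
#'
#' @param theta mean-reversion rate (1/s, > 0).
#' @param sigma diffusion coefficient (units / sqrt(s), >= 0).
#' @param mean long-run mean level.
#' @param rate sampling rate in Hz; the default 4 Hz matches the time grid of
#'   the EFP feature pipeline.
#' @param duration length of the path in seconds (> 0).
#' @param seed optional integer seed; the same seed gives an identical path.
#' @param t0 start time (s).
#' @return An [latent_series()] object of `round(duration * rate)` samples.
#' @examples
#' x <- generate_latent_arousal(theta = 1, sigma = 1, duration = 60, seed = 1)
#' var(x$values)  # approaches sigma^2 / (2 theta) = 0.5 for long runs
#' @export
generate_latent_arousal <- function(theta, sigma, mean = 0, rate = 4,
                                    duration, seed = NULL, t0 = 0) {
  check_scalar(theta, "theta", lower = 0, strict_lower = TRUE)
  check_scalar(sigma, "sigma", lower = 0)
  check_scalar(mean, "mean")
  check_scalar(rate, "rate", lower = 0, strict_lower = TRUE)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  n <- round(duration * rate)
  if (n < 1L) stop_param("duration too short for the requested rate")
  dt <- 1 / rate
  phi <- exp(-theta * dt)
  innov_sd <- sigma * sqrt((1 - phi^2) / (2 * theta))
  stat_sd <- sigma / sqrt(2 * theta)
  vals <- eval_with_seed(seed, function() {
    if (sigma == 0) return(rep(mean, n))
    e <- c(stats::rnorm(1, 0, stat_sd), stats::rnorm(n - 1, 0, innov_sd))
    mean + as.numeric(stats::filter(e, phi, method = "recursive"))
  })
  latent_series(vals, rate = rate, t0 = t0)
}
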
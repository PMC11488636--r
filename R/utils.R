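# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `fn()` under a fixed RNG seed without disturbing the caller's
# random-number stream. `seed = NULL` means: use the current stream.
eval_with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  fn()
}

stop_param <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param("`", name, "` must be a single finite number")
  if (strict_lower && x <= lower)
    stop_param("`", name, "` must be > ", lower)
  if (!strict_lower && x < lower)
    stop_param("`", name, "` must be >= ", lower)
  if (x > upper)
    stop_param("`", name, "` must be <= ", upper)
  invisible(x)
}

# Round half away from zero (half-up for positive values), matching the
# behaviour expected of the 1-10 feedback mapping.
round_half_up <- function(x) floor(x + 0.5)

# Linear interpolation of a series onto a new uniform grid.
resample_linear <- function(times, values, new_times) {
  stats::approx(times, values, xout = new_times, rule = 2)$y
}
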
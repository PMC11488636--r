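# The amygdala electrical-fingerprint model: a linear read-out of the
# 10 x 48 time-frequency feature window predicting amygdala BOLD activity.

#' EFP model container
#'
#' @param bands an [band_definition()].
#' @param weights numeric matrix (bands x time blocks) of regression weights.
#' @param intercept scalar intercept.
#' @param ridge_lambda the L2 penalty the weights were fitted with.
#' @param fit_report list with the cross-validation results
#'   (`lambda_grid`, `heldout_r`, `best_lambda`, `best_r`).
#' @return object of class `efp_model`.
#' @export
efp_model <- function(bands, weights, intercept = 0, ridge_lambda = 0,
                      fit_report = list()) {
  stopifnot(inherits(bands, "efp_bands"), is.matrix(weights))
  if (!all(is.finite(weights)) || !is.finite(intercept))
    stop_param("model weights and intercept must be finite")
  if (nrow(weights) != n_bands(bands))
    stop_param("weight rows must match the number of bands")
  if (length(fit_report$heldout_r) &&
      any(abs(fit_report$heldout_r) > 1 + 1e-9, na.rm = TRUE))
    stop_param("held-out correlations must lie in [-1, 1]")
  structure(list(bands = bands, weights = weights, intercept = intercept,
                 ridge_lambda = ridge_lambda, fit_report = fit_report),
            class = "efp_model")
}

#' @export
print.efp_model <- function(x, ...) {
  r <- x$fit_report$best_r
  cat(sprintf(
    "<efp_model> %d x %d weights, lambda = %g%s\n",
    nrow(x$weights), ncol(x$weights), x$ridge_lambda,
    if (length(r)) sprintf(", held-out r = %.3f", r) else ""))
  invisible(x)
}

ridge_solve <- function(xc, yc, lambdas) {
  sv <- svd(xc, nu = min(dim(xc)), nv = min(dim(xc)))
  uty <- crossprod(sv$u, yc)
  lapply(lambdas, function(l)
    sv$v %*% (sv$d / (sv$d^2 + l) * uty))
}

#' Fit EFP weights by ridge regression with blocked cross-validation
#'
#' Regresses the target (amygdala activity aligned per window; the caller
#' handles hemodynamic lag, see [efp_training_target()]) on the flattened
#' feature windows. The L2 penalty is chosen from a logarithmic grid by
#' blocked cross-validation over contiguous segments, which respects the
#' strong temporal autocorrelation of both features and target; the held-out
#' Pearson correlation per candidate penalty is kept in the fit report.
#'
#' @param windows list of [feature_window()] objects, or a numeric matrix
#'   with one flattened (band-fastest) window per row.
#' @param target numeric vector of per-window target values.
#' @param bands the [band_definition()] the windows were extracted with.
#' @param lambda_grid candidate penalties; logarithmic 1e-3 to 1e3 by
#'   default.
#' @param n_cv_blocks number of contiguous cross-validation blocks.
#' @param min_windows minimum number of training windows.
#' @return an [efp_model()].
#' @export
fit_efp_weights <- function(windows, target, bands,
                            lambda_grid = 10^seq(-3, 3, length.out = 13),
                            n_cv_blocks = 3, min_windows = 100) {
  if (is.list(windows) && !is.matrix(windows)) {
    dims <- dim(windows[[1]]$values)
    x <- do.call(rbind, lapply(windows, function(w) as.vector(w$values)))
  } else {
    x <- windows
    dims <- c(n_bands(bands), ncol(x) / n_bands(bands))
  }
  n <- nrow(x)
  if (length(target) != n)
    stop_param("windows and target must be aligned (one value per window)")
  if (!all(is.finite(target))) stop_param("target must be finite")
  if (n < max(2 * n_cv_blocks, min_windows))
    stop_param("too few windows (", n, ") for ", n_cv_blocks,
               "-block cross-validation; need at least ",
               max(2 * n_cv_blocks, min_windows))
  fold <- ceiling(seq_len(n) / (n / n_cv_blocks))
  preds <- matrix(NA_real_, n, length(lambda_grid))
  for (fb in unique(fold)) {
    tr <- fold != fb
    xb <- scale(x[tr, , drop = FALSE], scale = FALSE)
    yb <- target[tr] - mean(target[tr])
    betas <- ridge_solve(xb, yb, lambda_grid)
    xt <- sweep(x[!tr, , drop = FALSE], 2, attr(xb, "scaled:center"))
    for (j in seq_along(lambda_grid))
      preds[!tr, j] <- mean(target[tr]) + xt %*% betas[[j]]
  }
  heldout_r <- apply(preds, 2, function(p)
    if (stats::sd(p) == 0 || stats::sd(target) == 0) NA_real_
    else stats::cor(p, target))
  best <- if (all(is.na(heldout_r))) length(lambda_grid)
          else which.max(heldout_r)
  xc <- scale(x, scale = FALSE)
  yc <- target - mean(target)
  beta <- ridge_solve(xc, yc, lambda_grid[best])[[1]]
  intercept <- mean(target) - sum(attr(xc, "scaled:center") * beta)
  efp_model(bands,
            weights = matrix(beta, dims[1], dims[2]),
            intercept = intercept,
            ridge_lambda = lambda_grid[best],
            fit_report = list(lambda_grid = lambda_grid,
                              heldout_r = heldout_r,
                              best_lambda = lambda_grid[best],
                              best_r = heldout_r[best]))
}

#' Hemodynamically lagged training target
#'
#' The EFP weights predict "current fMRI activity", which trails neural
#' activity by the hemodynamic response. This helper convolves the latent
#' series with the canonical HRF and samples it at the feature-window end
#' times (the default), or simply lags the raw latent by a fixed delay.
#'
#' @param latent an [latent_series()].
#' @param times feature-window end times (s).
#' @param method `"hrf"` (convolve, default) or `"lag"`.
#' @param lag fixed delay in seconds for `method = "lag"`.
#' @return numeric vector, one target value per time.
#' @export
efp_training_target <- function(latent, times, method = c("hrf", "lag"),
                                lag = 6) {
  method <- match.arg(method)
  if (method == "hrf") {
    h <- canonical_hrf(1 / latent$rate)
    conv <- stats::convolve(latent$values, rev(h),
                            type = "open")[seq_along(latent$values)]
    resample_linear(latent_times(latent), conv, times)
  } else {
    latent_at(latent, times - lag)
  }
}

#' Predict the EFP series from an EEG recording
#'
#' Applies the model causally: the estimate at time `t` uses only the 12-s
#' feature window ending at `t` (samples at or before `t`). Times lacking
#' 12 s of history are flagged (`ok = FALSE`) rather than silently dropped.
#'
#' @param model an [efp_model()].
#' @param recording an [eeg_recording()].
#' @param times requested estimate times (s), normally a 3-s grid.
#' @param labels optional per-time condition labels (or an [nf_schedule()]
#'   to look them up from).
#' @return object of class `efp_samples`: data.frame with columns `time`,
#'   `value`, `label`, `ok`.
#' @export
predict_efp <- function(model, recording, times, labels = NULL) {
  stopifnot(inherits(model, "efp_model"), inherits(recording, "efp_eeg"))
  if (inherits(labels, "efp_schedule"))
    labels <- schedule_label_at(labels, times)
  if (is.null(labels)) labels <- rep(NA_character_, length(times))
  vals <- numeric(length(times))
  ok <- logical(length(times))
  for (i in seq_along(times)) {
    fw <- try(extract_features(recording, model$bands, times[i]),
              silent = TRUE)
    if (inherits(fw, "try-error")) {
      vals[i] <- NA_real_
      ok[i] <- FALSE
    } else {
      vals[i] <- model$intercept + sum(model$weights * fw$values)
      ok[i] <- TRUE
    }
  }
  structure(data.frame(time = times, value = vals, label = labels, ok = ok,
                       stringsAsFactors = FALSE),
            class = c("efp_samples", "data.frame"))
}

#' Serialize an EFP model to JSON
#'
#' @param model an [efp_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_efp_model <- function(model, path) {
  obj <- list(format = "efpnf-model-1",
              edges = model$bands$edges,
              calibration_energy = model$bands$calibration_energy,
              weights = as.vector(t(model$weights)),  # row-major
              n_bands = nrow(model$weights),
              n_blocks = ncol(model$weights),
              intercept = model$intercept,
              ridge_lambda = model$ridge_lambda,
              fit_report = model$fit_report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EFP model from JSON
#'
#' @param path file written by [write_efp_model()].
#' @return an [efp_model()].
#' @export
read_efp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "efpnf-model-1"))
    stop_param("unrecognised model file format: ", obj$format)
  bands <- band_definition(obj$edges, obj$calibration_energy)
  w <- matrix(obj$weights, obj$n_bands, obj$n_blocks, byrow = TRUE)
  efp_model(bands, w, obj$intercept, obj$ridge_lambda,
            fit_report = as.list(obj$fit_report))
}
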
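# Offline single-ROI fMRI analysis: HRF-convolved condition regressors,
# nuisance terms, OLS fit and the Watch-Regulate contrast.

#' Build a GLM design matrix for an fMRI neurofeedback run
#'
#' Condition regressors (Watch, Regulate and, when present in the schedule,
#' Washout) are unit boxcars convolved with the canonical double-gamma HRF on
#' a fine time grid and sampled at the volume acquisition times. Nuisance
#' regressors follow the usual motion model: the six realignment parameters
#' (mean-centred), their temporal derivatives (first differences) and
#' quadratic terms (squares of the centred columns), plus one unit spike
#' column per motion outlier volume. An intercept column closes the matrix.
#'
#' @param schedule an [nf_schedule()]; must fit within `n_volumes * tr`.
#' @param n_volumes number of acquired volumes.
#' @param tr repetition time (s); defaults to 3.
#' @param motion optional `n_volumes` x 6 matrix of realignment parameters.
#' @param outliers integer indices (1-based volumes) of motion outliers.
#' @param hrf_dt internal convolution grid step (s).
#' @return object of class `efp_design`: list with `values` (volumes x
#'   regressors matrix with named columns), `tr`, and `condition_cols`.
#' @export
build_design_matrix <- function(schedule, n_volumes, tr = 3, motion = NULL,
                                outliers = integer(0), hrf_dt = 0.1) {
  stopifnot(inherits(schedule, "efp_schedule"))
  check_scalar(tr, "tr", lower = 0, strict_lower = TRUE)
  check_scalar(n_volumes, "n_volumes", lower = 2)
  if (schedule_duration(schedule) > n_volumes * tr + 1e-9)
    stop_param("schedule does not fit within n_volumes * tr")
  conds <- intersect(c("Watch", "Regulate", "Washout"),
                     unique(schedule$label))
  t_fine <- seq(0, n_volumes * tr, by = hrf_dt)
  h <- canonical_hrf(hrf_dt)
  vol_t <- (seq_len(n_volumes) - 1) * tr
  cols <- list()
  for (cn in conds) {
    box <- as.numeric(schedule_label_at(schedule, t_fine) %in% cn)
    conv <- stats::convolve(box, rev(h), type = "open")[seq_along(t_fine)] *
      hrf_dt  # Riemann scaling: regressor amplitude independent of hrf_dt
    cols[[cn]] <- resample_linear(t_fine, conv, vol_t)
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_volumes)
      stop_param("motion must have one row per volume")
    for (j in seq_len(ncol(motion))) {
      m <- motion[, j] - mean(motion[, j])
      cols[[paste0("mot", j)]] <- m
      cols[[paste0("mot", j, "_d")]] <- c(0, diff(m))
      cols[[paste0("mot", j, "_sq")]] <- m^2
    }
  }
  for (oi in outliers) {
    if (oi < 1 || oi > n_volumes)
      stop_param("outlier volume index ", oi, " out of range")
    sp <- numeric(n_volumes)
    sp[oi] <- 1
    cols[[paste0("outlier_", oi)]] <- sp
  }
  cols[["intercept"]] <- rep(1, n_volumes)
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  structure(list(values = x, tr = tr, condition_cols = conds),
            class = "efp_design")
}

#' Fit the ROI GLM and form the Watch-Regulate contrast
#'
#' Ordinary least squares on the ROI-average BOLD series. The contrast is
#' `beta_Watch - beta_Regulate`; a positive value means lower activity
#' during Regulate, i.e. successful down-regulation, matching the sign
#' convention under which the EFP success index is negative.
#'
#' @param bold an [bold_series()] (or numeric vector) with one value per
#'   design row.
#' @param design an [efp_design()] from [build_design_matrix()].
#' @return object of class `efp_contrast`: list with `value`
#'   (Watch-Regulate), `betas` (named), `residual_var`, `df_residual`.
#' @export
fit_glm <- function(bold, design) {
  stopifnot(inherits(design, "efp_design"))
  y <- if (inherits(bold, "efp_bold")) bold$values else as.numeric(bold)
  x <- design$values
  if (length(y) != nrow(x))
    stop_param("BOLD length (", length(y), ") must equal design rows (",
               nrow(x), ")")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop_param("design matrix is rank deficient; collinear columns: ",
               paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qx, y)
  fitted <- as.numeric(x %*% betas)
  dfres <- length(y) - ncol(x)
  rvar <- if (dfres > 0) sum((y - fitted)^2) / dfres else NA_real_
  if (!all(c("Watch", "Regulate") %in% names(betas)))
    stop_param("design lacks Watch/Regulate condition columns")
  structure(list(value = unname(betas["Watch"] - betas["Regulate"]),
                 betas = betas, residual_var = rvar, df_residual = dfres),
            class = "efp_contrast")
}

#' @export
print.efp_contrast <- function(x, ...) {
  cat(sprintf("<efp_contrast> Watch-Regulate = %.4f (residual var %.4g)\n",
              x$value, x$residual_var))
  invisible(x)
}
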
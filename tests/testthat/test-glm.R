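test_that("the canonical HRF peaks near 5 s and integrates positively", {
  h <- canonical_hrf(0.1)
  expect_equal((which.max(h) - 1) * 0.1, 5, tolerance = 0.1 + 1e-9)
  expect_gt(sum(h), 0)
  expect_equal(max(h), 1)
})

test_that("HRF sampling is consistent across rates", {
  h1 <- canonical_hrf(1)
  h05 <- canonical_hrf(0.5)
  expect_equal(h1, h05[seq(1, length(h05), by = 2)], tolerance = 1e-9)
})

test_that("the design matrix has the documented columns", {
  sch <- build_schedule("fmri_nf")
  d0 <- build_design_matrix(sch, n_volumes = 120, tr = 3)
  expect_equal(colnames(d0$values),
               c("Watch", "Regulate", "Washout", "intercept"))
  mot <- matrix(rnorm(120 * 6), 120, 6)
  d1 <- build_design_matrix(sch, 120, 3, motion = mot, outliers = c(5, 50))
  expect_equal(ncol(d1$values), 3 + 18 + 2 + 1)
  expect_equal(sum(grepl("^mot", colnames(d1$values))), 18)
  spikes <- d1$values[, grepl("^outlier", colnames(d1$values))]
  expect_equal(colSums(spikes), c(outlier_5 = 1, outlier_50 = 1))
  expect_equal(unname(colSums(abs(d1$values[, "mot1", drop = FALSE]))) > 0,
               TRUE)
  expect_equal(mean(d1$values[, "mot1"]), 0, tolerance = 1e-12)
  expect_error(build_design_matrix(sch, 120, 3, outliers = 500),
               "out of range")
  expect_error(build_design_matrix(sch, 50, 3), "fit within")
})

test_that("noiseless forward-simulated BOLD recovers the betas exactly", {
  sch <- build_schedule("fmri_nf")
  mot <- matrix(rnorm(120 * 6), 120, 6)
  des <- build_design_matrix(sch, 120, 3, motion = mot)
  betas <- rnorm(ncol(des$values))
  y <- as.numeric(des$values %*% betas)
  fit <- fit_glm(y, des)
  expect_equal(unname(fit$betas), betas, tolerance = 1e-8)
  expect_equal(fit$value,
               betas[colnames(des$values) == "Watch"] -
                 betas[colnames(des$values) == "Regulate"],
               tolerance = 1e-8)
  expect_lt(fit$residual_var, 1e-16)
})

test_that("a down-regulating subject gives a positive contrast, sign-matched
           to its success index", {
  sch <- build_schedule("fmri_nf")
  # a trace of state noise keeps the first Watch baseline non-degenerate
  ag <- agent_params(regulate_gain = 0.02, noise_sd = 0.005)
  lat <- simulate_regulating_agent(ag, sch, session_index = 1, seed = 85)
  bold <- synthesize_bold(lat, tr = 3, noise_sd = 0)
  n_vol <- length(bold$values)
  des <- build_design_matrix(sch, n_vol, 3)
  fit <- fit_glm(bold, des)
  expect_gt(fit$value, 0)
  # same subject's latent-level success index is negative
  grid <- seq(3, efpnf:::schedule_duration(sch), by = 3)
  si <- efpnf:::cycle_success_indices(grid - 1.5,
                                      latent_at(lat, grid - 0.25), sch)
  expect_true(all(si < 0))
})

test_that("permuted BOLD gives a contrast distribution centred on zero", {
  set.seed(81)
  sch <- build_schedule("fmri_nf")
  ag <- agent_params(regulate_gain = 0.02, noise_sd = 0.2)
  lat <- simulate_regulating_agent(ag, sch, seed = 82)
  bold <- synthesize_bold(lat, tr = 3, noise_sd = 0.1, seed = 83)
  des <- build_design_matrix(sch, length(bold$values), 3)
  vals <- replicate(500, fit_glm(sample(bold$values), des)$value)
  expect_lt(abs(mean(vals)), 2 * stats::sd(vals) / sqrt(500))
})

test_that("orthogonal nuisance columns do not move the contrast", {
  sch <- build_schedule("fmri_nf")
  des <- build_design_matrix(sch, 120, 3)
  set.seed(84)
  y <- as.numeric(des$values %*% rnorm(4)) + rnorm(120)
  base <- fit_glm(y, des)
  # orthogonalize a random column against the existing design
  extra <- rnorm(120)
  extra <- extra - des$values %*% solve(crossprod(des$values),
                                        crossprod(des$values, extra))
  des2 <- des
  des2$values <- cbind(des$values, ortho = as.numeric(extra))
  expect_equal(fit_glm(y, des2)$value, base$value, tolerance = 1e-8)
})

test_that("rank-deficient designs fail loudly, naming the columns", {
  sch <- build_schedule("fmri_nf")
  des <- build_design_matrix(sch, 120, 3)
  des$values <- cbind(des$values, dup = des$values[, "Watch"])
  expect_error(fit_glm(rnorm(120), des), "collinear.*dup|dup.*collinear")
  des2 <- build_design_matrix(sch, 120, 3)
  expect_error(fit_glm(rnorm(60), des2), "must equal design rows")
})
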
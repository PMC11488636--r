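test_that("a no-change no-dropout cohort reproduces the pre means", {
  ins <- default_instruments()
  for (nm in names(ins)) ins[[nm]]$change[] <- 0
  p <- cohort_params(n_test = 200, n_control = 200, instruments = ins,
                     dropout_probs = c(pre = 0, post = 0, m1 = 0, m3 = 0,
                                       m6 = 0))
  coh <- generate_clinical_cohort(p, seed = 1)
  for (tp in c("pre", "post")) {
    d <- coh[coh$instrument == "CAPS5" & coh$timepoint == tp, ]
    se <- 9.92 / sqrt(200)
    expect_lt(abs(mean(d$score[d$group == "test"]) - 40.52), 2 * se)
    expect_lt(abs(mean(d$score[d$group == "control"]) - 43.06),
              2 * 10 / sqrt(200))
  }
})

test_that("diagnosis-loss probabilities imply the expected ARR and NNT", {
  # expectation arithmetic: p_test .40, p_control .15 => ARR .25, NNT 4
  p <- cohort_params()
  arr <- p$diagnosis_loss_probs["test"] - p$diagnosis_loss_probs["control"]
  expect_equal(unname(arr), 0.25)
  expect_equal(nnt_from_arr(arr), 4)
  # empirical loss rates converge to the configured probabilities
  big <- cohort_params(n_test = 2000, n_control = 2000)
  coh <- generate_clinical_cohort(big, seed = 2)
  post <- coh[coh$instrument == "CAPS5" & coh$timepoint == "post", ]
  expect_lt(abs(mean(!post$diagnosis[post$group == "test"]) - 0.40), 0.03)
  expect_lt(abs(mean(!post$diagnosis[post$group == "control"]) - 0.15),
            0.03)
})

test_that("zero dropout yields a complete long table with flags", {
  p <- cohort_params(dropout_probs = c(pre = 0, post = 0, m1 = 0, m3 = 0,
                                       m6 = 0))
  coh <- generate_clinical_cohort(p, seed = 3)
  expect_equal(nrow(coh), (40 + 15) * 5 * 3)
  expect_false(anyNA(coh$score))
  per_tp <- table(coh$timepoint[coh$instrument == "PCL5"])
  expect_true(all(per_tp == 55))
  expect_true(all(coh$diagnosis[coh$timepoint == "pre"]))
  expect_true(all(is.na(coh$diagnosis[coh$timepoint == "m3"])))
})

test_that("scores stay within instrument ranges", {
  ins <- default_instruments()
  ins$DES2$pre_mean[] <- c(5, 5)  # push against the floor
  p <- cohort_params(instruments = ins)
  coh <- generate_clinical_cohort(p, seed = 4)
  expect_true(all(coh$score[coh$instrument == "DES2"] >= 0, na.rm = TRUE))
  expect_true(all(coh$score[coh$instrument == "CAPS5"] <= 80, na.rm = TRUE))
})

test_that("cohort generation is deterministic and validates parameters", {
  a <- generate_clinical_cohort(cohort_params(), seed = 5)
  b <- generate_clinical_cohort(cohort_params(), seed = 5)
  expect_identical(a$score, b$score)
  bad <- default_instruments()
  bad$CAPS5$pre_sd[1] <- -1
  expect_error(cohort_params(instruments = bad), "pre_sd")
  expect_error(cohort_params(diagnosis_loss_probs = c(test = 1.2,
                                                      control = 0.1)),
               "\\[0, 1\\]")
})

test_that("large-cohort group means converge on the configured trajectory", {
  p <- cohort_params(n_test = 2000, n_control = 2000,
                     dropout_probs = c(pre = 0, post = 0, m1 = 0, m3 = 0,
                                       m6 = 0))
  coh <- generate_clinical_cohort(p, seed = 6)
  d <- coh[coh$instrument == "PCL5" & coh$timepoint == "m6", ]
  expect_equal(mean(d$score[d$group == "test"]), 42.97 - 14,
               tolerance = 3 * 16.83 / sqrt(2000) / (42.97 - 14))
  expect_equal(mean(d$score[d$group == "control"]), 44.86 - 2,
               tolerance = 3 * 19.05 / sqrt(2000) / (44.86 - 2))
})
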
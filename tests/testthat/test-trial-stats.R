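test_that("the published symptom reductions follow from the printed means", {
  # pre means from the group table; post means from the results text
  expect_equal(reduction_delta(40.52, 31.66), 8.86)
  expect_equal(reduction_delta(43.06, 39.78), 3.28)
  expect_equal(reduction_delta(12, 12), 0)
})

test_that("ANCOVA satisfies its partial eta-squared identity on real fits", {
  coh <- generate_clinical_cohort(cohort_params(), seed = 101)
  a <- ancova_immediate(coh)
  expect_lt(abs(a$partial_eta_sq -
                  a$F * a$df[1] / (a$F * a$df[1] + a$df[2])), 1e-9)
  expect_equal(a$df[1], 1)
  expect_equal(a$df[2], a$n - 3)
  expect_gte(a$F, 0)
  expect_named(a$adjusted_group_means, c("control", "test"))
})

test_that("a post identical to pre is fully absorbed by the covariate", {
  coh <- generate_clinical_cohort(
    cohort_params(dropout_probs = c(pre = 0, post = 0, m1 = 0, m3 = 0,
                                    m6 = 0)), seed = 102)
  w <- coh[coh$instrument == "CAPS5", ]
  pre <- w[w$timepoint == "pre", ]
  w$score[w$timepoint == "post"] <-
    pre$score[match(w$subject_id[w$timepoint == "post"], pre$subject_id)]
  a <- suppressWarnings(ancova_immediate(w))  # lm warns on a perfect fit
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
})

test_that("ANCOVA requires three complete cases per group", {
  coh <- generate_clinical_cohort(cohort_params(n_control = 3), seed = 103)
  drop <- coh
  drop$score[drop$group == "control" & drop$timepoint == "post"] <- NA
  expect_error(ancova_immediate(drop), "at least 3")
})

test_that("compound symmetry equals the random-intercept REML fit", {
  coh <- generate_clinical_cohort(
    cohort_params(dropout_probs = c(pre = 0, post = 0, m1 = 0, m3 = 0,
                                    m6 = 0)), seed = 104)
  m <- mixed_model_followup(coh, "PCL5")
  expect_true(m$converged)
  d <- coh[coh$instrument == "PCL5", ]
  d$time <- match(d$timepoint, c("pre", "post", "m1", "m3", "m6")) - 1
  d$group <- factor(d$group, levels = c("control", "test"))
  g <- nlme::gls(score ~ group * time, data = d,
                 correlation = nlme::corCompSymm(form = ~ 1 | subject_id),
                 method = "REML")
  expect_lt(abs(m$loglik_REML - as.numeric(stats::logLik(g))), 1e-6)
  expect_gte(m$sigma_between, 0)
  expect_gte(m$sigma_within, 0)
})

test_that("the mixed model reports the three fixed-effect tests", {
  coh <- generate_clinical_cohort(cohort_params(), seed = 105)
  m <- mixed_model_followup(coh, "DES2")
  expect_setequal(m$fixed$effect, c("group", "time", "group:time"))
  expect_true(all(is.finite(m$fixed$F)))
  expect_true(all(m$fixed$p >= 0 & m$fixed$p <= 1))
  mc <- mixed_model_followup(coh, "DES2", time_coding = "categorical")
  expect_equal(mc$fixed$numDF[mc$fixed$effect == "group:time"], 4)
})

test_that("rmANOVA reduces to the squared paired t on two conditions", {
  set.seed(106)
  n <- 14
  df <- expand.grid(subject = paste0("s", 1:n),
                    condition = c("Watch", "Regulate"), session = 1)
  df$value <- rnorm(nrow(df)) - 0.4 * (df$condition == "Regulate")
  r <- rm_anova_condition_session(df)
  w <- stats::reshape(df[c("subject", "condition", "value")],
                      idvar = "subject", timevar = "condition",
                      direction = "wide")
  tt <- stats::t.test(w$value.Watch, w$value.Regulate, paired = TRUE)
  expect_lt(abs(r$F_condition - unname(tt$statistic)^2), 1e-9)
  expect_equal(r$p_condition, tt$p.value, tolerance = 1e-12)
})

test_that("rmANOVA agrees with aov's within-subject error strata", {
  set.seed(107)
  df <- expand.grid(subject = paste0("s", 1:10),
                    condition = c("Watch", "Regulate"), session = 1:10)
  df$value <- rnorm(nrow(df)) - 0.3 * (df$condition == "Regulate") +
    0.05 * as.numeric(df$session) * (df$condition == "Regulate")
  r <- rm_anova_condition_session(df)
  av <- summary(stats::aov(
    value ~ condition * session + Error(subject / (condition * session)),
    data = transform(df, session = factor(session))))
  f_aov <- function(stratum, term)
    av[[stratum]][[1]][term, "F value"]
  expect_equal(r$F_condition,
               f_aov("Error: subject:condition", "condition"),
               tolerance = 1e-9)
  expect_equal(r$F_session, f_aov("Error: subject:session", "session"),
               tolerance = 1e-9)
  expect_equal(r$F_interaction,
               f_aov("Error: subject:condition:session",
                     "condition:session"), tolerance = 1e-9)
})

test_that("rmANOVA is invariant to adding a constant and drops incomplete
           subjects", {
  set.seed(108)
  df <- expand.grid(subject = paste0("s", 1:8),
                    condition = c("Watch", "Regulate"), session = 1:10)
  df$value <- rnorm(nrow(df))
  r1 <- rm_anova_condition_session(df)
  df2 <- df; df2$value <- df2$value + 100
  r2 <- rm_anova_condition_session(df2)
  expect_equal(r1$F_condition, r2$F_condition)
  expect_equal(r1$F_session, r2$F_session)
  expect_equal(r1$F_interaction, r2$F_interaction)
  df3 <- rbind(df, data.frame(subject = "s99", condition = "Watch",
                              session = 1, value = 1))
  r3 <- rm_anova_condition_session(df3)
  expect_equal(r3$n_dropped, 1)
  expect_equal(r3$F_condition, r1$F_condition)
})

test_that("the paired learning contrast handles its edge cases", {
  m <- matrix(rnorm(100), 10, 10)
  same <- cbind(m[, 1:5], m[, 1:5])
  r <- paired_learning_test(same)
  expect_equal(r$t, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)
  const <- cbind(matrix(0, 10, 5), matrix(-1, 10, 5))
  r2 <- paired_learning_test(const)
  expect_true(r2$degenerate)
  expect_equal(r2$mean_first5 - r2$mean_last5, 1)
  # a subject with an all-missing half is excluded and counted
  m2 <- m
  m2[3, 6:10] <- NA
  r3 <- paired_learning_test(m2)
  expect_equal(r3$n_excluded, 1)
  expect_equal(r3$n_subjects, 9)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(109)
  p <- runif(50)
  expect_true(all(bh_fdr(p) >= p))
  expect_true(all(bh_fdr(p) <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ARR and NNT follow the printed trial arithmetic", {
  r <- arr_and_nnt(20, 40, 0, 15)
  expect_equal(r$arr, 0.5)
  expect_equal(r$nnt, 2)
  # the published ARR of 24.7% corresponds to an NNT of 4.05, i.e. the
  # printed 4.04 within rounding of the ARR to three digits
  expect_equal(round(nnt_from_arr(0.247), 2), 4.05)
  expect_lt(abs(nnt_from_arr(0.247) - 4.04), 0.01)
  expect_equal(nnt_from_arr(0.5), 2)
  expect_equal(nnt_from_arr(0.25), 4)
  expect_error(nnt_from_arr(0), "positive")
  eq <- arr_and_nnt(5, 20, 5, 20)
  expect_false(eq$beneficial)
  expect_true(is.na(eq$nnt))
})

test_that("Newcombe intervals cover the ARR and behave sensibly", {
  r <- arr_and_nnt(16, 40, 2, 15)
  expect_lt(r$ci_arr["lower"], r$arr)
  expect_gt(r$ci_arr["upper"], r$arr)
  expect_true(r$ci_arr["lower"] >= -1 && r$ci_arr["upper"] <= 1)
  # the interval straddles zero here, so no reciprocal NNT interval exists
  expect_lt(r$ci_arr["lower"], 0)
  expect_true(all(is.na(r$ci_nnt)))
  w <- arr_and_nnt(16, 40, 2, 15, ci_method = "wald")
  expect_equal(unname(w$ci_arr["upper"] - w$ci_arr["lower"]),
               2 * stats::qnorm(0.975) *
                 sqrt(0.4 * 0.6 / 40 + (2 / 15) * (13 / 15) / 15),
               tolerance = 1e-9)
  # reciprocal interval when the ARR interval is strictly positive
  s <- arr_and_nnt(30, 40, 1, 15)
  expect_gt(s$ci_arr["lower"], 0)
  expect_equal(unname(s$ci_nnt), unname(sort(1 / s$ci_arr)))
})

test_that("the power utility reproduces a conventional a-priori analysis", {
  n <- required_sample_size(partial_eta_sq = 0.16, alpha = 0.05,
                            power = 0.8, n_groups = 2)
  expect_true(n >= 42 && n <= 45)
})
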